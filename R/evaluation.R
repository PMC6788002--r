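# Evaluation harness: balanced hold-out split, rank-based AUC, AUC versus
# training-sample-size sweeps comparing similarity-based and random
# training-subset selection, cubic trend fits and Mann-Whitney curve
# comparisons.

#' Balanced hold-out split
#'
#' Randomly splits a labeled cohort into a class-balanced training pool
#' (`train_per_class` patients per class) and a disjoint test set drawn
#' from the remainder (all of it, or `test_per_class` per class).
#' Reproducible under `seed`.
#'
#' @param x a labeled [cohort()].
#' @param train_per_class training patients per class.
#' @param test_per_class optional cap on test patients per class.
#' @param seed integer seed.
#' @return List with cohorts `train` and `test`.
#' @export
holdout_split <- function(x, train_per_class, test_per_class = NULL,
                          seed = 1) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(x$label)) stop_("hold-out split requires a labeled cohort")
  picks <- with_seed(seed, {
    lapply(c(0L, 1L), function(cl) {
      ids <- x$id[x$label == cl]
      if (length(ids) < train_per_class + 1)
        stop_("class %d has %d patients; need at least train_per_class + 1",
              cl, length(ids))
      tr <- sample(ids, train_per_class)
      rest <- setdiff(ids, tr)
      te <- if (is.null(test_per_class)) rest
            else sample(rest, min(test_per_class, length(rest)))
      list(train = tr, test = te)
    })
  })
  train_ids <- sort(c(picks[[1]]$train, picks[[2]]$train))
  test_ids <- sort(c(picks[[1]]$test, picks[[2]]$test))
  list(train = x[train_ids], test = x[test_ids])
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank treatment of tied scores.
#'
#' @param labels 0/1 outcome labels (both classes present).
#' @param scores numeric classifier scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) stop_("labels/scores length mismatch")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_("AUC requires both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Train on a fixed id subset and score a test feature matrix.  Feature
# rows come from a precomputed pool feature matrix so that identical id
# sets always yield the identical (id-sorted) training matrix.  Returns
# the probability vector; single-class subsets fall back to the class
# proportion.
.train_and_score <- function(pool_feat, ids, test_x, algorithm, knn_k,
                             rf_trees, seed, lr_ridge = 0) {
  ids <- sort(ids)
  x <- pool_feat$x[ids, , drop = FALSE]
  y <- pool_feat$y[ids]
  if (length(unique(y)) < 2) return(rep(mean(y), nrow(test_x)))
  spec <- model_spec(algorithm, knn_k = min(knn_k, length(ids)),
                     rf_trees = rf_trees,
                     ridge = if (algorithm == "lr") lr_ridge else 0)
  fit <- train_model(x, y, spec, seed = seed)
  predict(fit, test_x)
}

#' AUC versus training-sample-size sweep
#'
#' For every combination of algorithm, diagnosis-similarity scheme,
#' training-subset size `K` and replicate, evaluates two selection modes
#' over a labeled test set:
#' * `similar` — one personalized model per test patient, trained on that
#'   patient's top-K most similar pool patients;
#' * `random` — one traditional model per cell, trained on a fresh
#'   uniform random subset of size K.
#'
#' Test-set AUC is recorded per cell.  Every model fit within a cell uses
#' a seed derived deterministically from `seed` and the cell coordinates
#' (algorithm, scheme, K, replicate) -- shared between the two modes, so
#' that at `K = ` pool size the two modes train the identical model and
#' their predictions coincide exactly.  Identical training subsets inside
#' a cell are fitted once and cached.
#'
#' @param pool labeled training [cohort()].
#' @param test labeled test [cohort()].
#' @param k_grid strictly increasing vector of subset sizes within the
#'   pool size.
#' @param algorithms subset of `c("knn", "lr", "rf")`.
#' @param schemes subset of `c("ccs", "icd")`.
#' @param weights a [similarity_weights()].
#' @param ccs_map crosswalk for the CCS scheme.
#' @param replicates replicate seeds per cell (default 1, the single-split
#'   design; use more to give [compare_curves()] within-K samples).
#' @param seed master seed driving all cell seeds.
#' @param knn_k,rf_trees classifier parameters (see [model_spec()]).
#' @param lr_ridge L2 penalty applied to the logistic-regression fits in
#'   the sweep (default 0.01).  Per-query training subsets are routinely
#'   comparable in size to the feature count, where the unpenalized fit
#'   separates and its saturated 0/1 outputs are not rank-comparable
#'   across the per-query models; a weak ridge keeps the probabilities
#'   informative.  Set to 0 for plain maximum likelihood.
#' @param screen_exclude ICD-10 prefixes excluded from the diagnosis
#'   feature screen; defaults to the label-defining [dm_code_prefixes()].
#' @return A data.frame with columns `algorithm`, `scheme`, `mode`, `k`,
#'   `replicate`, `seed`, `auc` (one row per cell).
#' @export
sweep_training_size <- function(pool, test, k_grid,
                                algorithms = c("knn", "lr", "rf"),
                                schemes = "ccs",
                                weights = similarity_weights(),
                                ccs_map = default_ccs_map(),
                                replicates = 1, seed = 1,
                                knn_k = 50, rf_trees = 100, lr_ridge = 0.01,
                                screen_exclude = dm_code_prefixes()) {
  stopifnot(inherits(pool, "cohort"), inherits(test, "cohort"))
  if (is.null(pool$label) || is.null(test$label))
    stop_("sweep requires labeled pool and test cohorts")
  k_grid <- as.integer(k_grid)
  if (any(diff(k_grid) <= 0)) stop_("k_grid must be strictly increasing")
  if (any(k_grid < 1 | k_grid > cohort_size(pool)))
    stop_("k_grid must lie within 1..pool size")
  algorithms <- match.arg(algorithms, c("knn", "lr", "rf"), several.ok = TRUE)
  schemes <- match.arg(schemes, c("ccs", "icd"), several.ok = TRUE)

  lab_params <- normalize_labs(pool$labs)$params
  screened <- screen_diagnosis_features(pool, exclude_prefixes = screen_exclude)
  pool_feat <- build_feature_vectors(pool, screened = screened,
                                     lab_params = lab_params)
  names(pool_feat$y) <- rownames(pool_feat$x)
  test_feat <- build_feature_vectors(test, screened = screened,
                                     lab_params = lab_params)
  test_x <- test_feat$x[test$id, , drop = FALSE]  # original test order

  # ranked pool ids per test patient and scheme
  ranked <- lapply(schemes, function(sch) {
    ps <- .similarity_components(test, pool, weights, sch, ccs_map,
                                 lab_params)$ps
    lapply(seq_len(nrow(ps)), function(i)
      pool$id[order(-ps[i, ], pool$id)])
  })
  names(ranked) <- schemes

  out <- list()
  for (sch in schemes) {
    si <- match(sch, c("ccs", "icd"))
    for (alg in algorithms) {
      ai <- match(alg, c("knn", "lr", "rf"))
      for (k in k_grid) {
        for (rep_ in seq_len(replicates)) {
          cell_seed <- derive_seed(seed, si, ai, k, rep_)
          # personalized: one model per test patient, cached by subset
          cache <- new.env(parent = emptyenv())
          probs_sim <- vapply(seq_len(cohort_size(test)), function(i) {
            ids <- ranked[[sch]][[i]][seq_len(k)]
            key <- paste(sort(ids), collapse = "\r")
            if (is.null(cache[[key]]))
              cache[[key]] <- .train_and_score(pool_feat, ids, test_x,
                                               alg, knn_k, rf_trees,
                                               cell_seed, lr_ridge)
            cache[[key]][i]
          }, numeric(1))
          # traditional: one model on a random subset of the same size
          rand_ids <- select_random(pool$id, k, seed = cell_seed)
          probs_rand <- .train_and_score(pool_feat, rand_ids, test_x, alg,
                                         knn_k, rf_trees, cell_seed,
                                         lr_ridge)
          out[[length(out) + 1]] <- data.frame(
            algorithm = alg, scheme = sch,
            mode = c("similar", "random"), k = k, replicate = rep_,
            seed = cell_seed,
            auc = c(auc(test$label, probs_sim), auc(test$label, probs_rand)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare two AUC curves
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on two samples of
#' per-K AUC values, with a Bonferroni adjustment for the number of
#' comparisons performed in the enclosing analysis.  The exact null
#' distribution is enumerated when both samples have at most 12 values
#' and no ties; otherwise the normal approximation with continuity and
#' tie correction is used.
#'
#' @param auc_a,auc_b numeric AUC samples over paired K grids (equal
#'   length).
#' @param n_comparisons Bonferroni multiplier (default 1).
#' @return List with `statistic` (rank-sum W), `p_value` (raw) and
#'   `p_adjusted` (Bonferroni, capped at 1).
#' @export
compare_curves <- function(auc_a, auc_b, n_comparisons = 1) {
  if (length(auc_a) != length(auc_b))
    stop_("mismatched K grids: %d vs %d AUC values",
          length(auc_a), length(auc_b))
  exact <- length(auc_a) <= 12 && length(auc_b) <= 12 &&
    !anyDuplicated(c(auc_a, auc_b))
  wt <- suppressWarnings(stats::wilcox.test(auc_a, auc_b, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       p_adjusted = min(1, wt$p.value * n_comparisons))
}

#' Cubic polynomial trend of an AUC curve
#'
#' Least-squares cubic fit describing how predictive performance changes
#' with training-sample size.
#'
#' @param k training-sample sizes (at least 4 distinct values).
#' @param aucs AUC values, same length as `k`.
#' @return List with `coefficients` (named `b0`..`b3`) and `fitted`
#'   values.
#' @export
fit_trend <- function(k, aucs) {
  if (length(unique(k)) < 4)
    stop_("cubic trend fit needs at least 4 distinct K values")
  if (length(k) != length(aucs)) stop_("k/aucs length mismatch")
  fit <- stats::lm(aucs ~ k + I(k^2) + I(k^3))
  co <- unname(stats::coef(fit))
  list(coefficients = c(b0 = co[1], b1 = co[2], b2 = co[3], b3 = co[4]),
       fitted = unname(stats::fitted(fit)))
}
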