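# Personalized predictive modeling: training-subset selection (top-K
# similar or random-K), feature-vector construction, and the three
# probability-scoring classifiers (kNN, logistic regression, random
# forest).

#' Classifier specification
#'
#' @param algorithm `"knn"`, `"lr"` or `"rf"`.
#' @param knn_k neighbor count for kNN (default 50).  When a training
#'   subset is smaller than `knn_k`, the effective neighbor count is
#'   capped at the subset size.
#' @param rf_trees number of random-forest trees (default 100).
#' @param ridge optional L2 penalty for logistic regression, on the
#'   per-observation scale (the intercept is not penalized; the absolute
#'   penalty is `nrow(x) * ridge / 2 * sum(beta^2)`).  0 (default) fits
#'   plain maximum likelihood.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(algorithm = c("knn", "lr", "rf"), knn_k = 50,
                       rf_trees = 100, ridge = 0) {
  algorithm <- match.arg(algorithm)
  if (!is_count(knn_k) || !is_count(rf_trees))
    stop_("knn_k and rf_trees must be positive integers")
  if (ridge < 0) stop_("ridge must be non-negative")
  structure(list(algorithm = algorithm, knn_k = as.integer(knn_k),
                 rf_trees = as.integer(rf_trees), ridge = ridge),
            class = "model_spec")
}

#' Select the top-K most similar patients
#'
#' First `k` entries of a ranked [similarity_profile()] (deterministic
#' given the profile's id tie-break).
#'
#' @param profile a [similarity_profile()].
#' @param k number of patients to select, `1 <= k <=` pool size.
#' @return Character vector of `k` pool patient ids.
#' @export
select_top_k <- function(profile, k) {
  stopifnot(inherits(profile, "similarity_profile"))
  if (!is_count(k) || k > nrow(profile))
    stop_("k must lie in 1..%d", nrow(profile))
  profile$id[seq_len(k)]
}

#' Select a random training subset
#'
#' Uniform sample without replacement, reproducible under `seed`; the
#' caller's RNG state is left untouched.
#'
#' @param ids character vector of pool patient ids.
#' @param k subset size, `1 <= k <= length(ids)`.
#' @param seed integer seed.
#' @return Character vector of `k` ids.
#' @export
select_random <- function(ids, k, seed) {
  if (!is_count(k) || k > length(ids))
    stop_("k must lie in 1..%d", length(ids))
  with_seed(seed, sample(ids, k))
}

#' Build model feature vectors
#'
#' Assembles the classifier input matrix for a set of patients: age, a
#' male-sex indicator, one binary presence indicator per screened
#' diagnosis code, and the standardized laboratory panel.  Column order is
#' fixed (`age`, `sex_male`, sorted screened codes, lab items) and rows
#' are sorted by patient id, so any selection of the same id set yields
#' the identical matrix.  Diagnoses outside the screened set are simply
#' absent (indicator 0).
#'
#' @param x a [cohort()].
#' @param ids patient ids to include (default: all).
#' @param screened character vector of screened diagnosis codes (see
#'   [screen_diagnosis_features()]).
#' @param lab_params lab standardization parameters fitted on the training
#'   pool (see [normalize_labs()]).
#' @return List with `x` (numeric feature matrix, rownames = ids) and `y`
#'   (integer labels, or `NULL` for unlabeled cohorts).
#' @export
build_feature_vectors <- function(x, ids = NULL, screened, lab_params) {
  stopifnot(inherits(x, "cohort"))
  ids <- sort(ids %||% x$id)
  sub <- x[ids]
  screened <- sort(screened)
  diag_block <- .presence_matrix(sub, universe = screened)
  labs <- normalize_labs(sub$labs, lab_params)$labs
  m <- cbind(age = sub$age, sex_male = as.numeric(sub$sex == "male"),
             diag_block, labs)
  rownames(m) <- sub$id
  list(x = m, y = sub$label)
}

# Ridge-penalized logistic regression by Newton/IRLS: minimizes
# -loglik + lambda/2 * sum(beta^2) with an unpenalized intercept.
# Deterministic; the penalty keeps the optimum finite under separation
# and well-defined for p > n or extreme class imbalance.
.fit_ridge_logistic <- function(x, y, lambda, maxit = 100, tol = 1e-10) {
  X <- cbind(`(Intercept)` = 1, x)
  p <- ncol(X)
  pen <- c(0, rep(lambda, p - 1))
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w)
    diag(H) <- diag(H) + pen
    step <- solve(H, crossprod(X, y - mu) - pen * beta)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  list(coefficients = stats::setNames(drop(beta), colnames(X)))
}

#' k-nearest-neighbor class probability
#'
#' The probability of the positive class for each query is the proportion
#' of positive labels among its `k` nearest training rows by Euclidean
#' distance.  Distance ties at the k-th rank are broken by ascending
#' training row name, so predictions are deterministic.
#'
#' @param train_x numeric training matrix with row names.
#' @param train_y 0/1 training labels.
#' @param query_x numeric query matrix (or single vector).
#' @param k neighbor count, `1 <= k <= nrow(train_x)`.
#' @return Numeric vector of probabilities, one per query row.
#' @export
knn_predict_proba <- function(train_x, train_y, query_x, k) {
  if (is.null(dim(query_x))) query_x <- matrix(query_x, nrow = 1)
  if (!is_count(k) || k > nrow(train_x))
    stop_("k must lie in 1..%d", nrow(train_x))
  ord_ids <- rownames(train_x) %||% as.character(seq_len(nrow(train_x)))
  apply(query_x, 1, function(q) {
    d <- sqrt(rowSums(sweep(train_x, 2, q, "-")^2))
    nn <- order(d, ord_ids)[seq_len(k)]
    mean(train_y[nn])
  })
}

#' Train a probability-scoring classifier
#'
#' Fits one of the three supported classifiers on a feature matrix:
#' * `knn` — lazy learner wrapping [knn_predict_proba()];
#' * `lr`  — binomial GLM with logit link fitted by maximum likelihood,
#'   or by ridge-penalized Newton iterations when `spec$ridge > 0`
#'   (the penalized fit is defined for any class balance, including a
#'   single minority observation);
#' * `rf`  — [randomForest::randomForest()] with `spec$rf_trees` trees;
#'   the predicted probability is the fraction of tree votes.
#'
#' Training labels must contain both classes; callers that may encounter
#' single-class subsets (tiny top-K selections) should handle that case
#' upstream (see [personalized_predict()]).
#'
#' @param x numeric feature matrix.
#' @param y 0/1 labels.
#' @param spec a [model_spec()].
#' @param seed integer seed for the stochastic fit (random forest); the
#'   caller's RNG state is preserved.
#' @return An object of class `ps_model` with a [predict()] method
#'   returning positive-class probabilities.
#' @export
train_model <- function(x, y, spec, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop_("training labels contain a single class; cannot fit %s",
          spec$algorithm)
  fit <- switch(spec$algorithm,
    knn = list(train_x = x, train_y = y, k = min(spec$knn_k, nrow(x))),
    lr = if (spec$ridge > 0) {
      .fit_ridge_logistic(x, y, lambda = nrow(x) * spec$ridge)
    } else {
      # plain ML; rank deficiency (p > n) and perfect separation are
      # expected at small K and handled by the pivoted fit
      suppressWarnings(stats::glm.fit(cbind(`(Intercept)` = 1, x), y,
                                      family = stats::binomial()))
    },
    rf = with_seed(seed,
      randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                 ntree = spec$rf_trees)))
  structure(list(spec = spec, fit = fit, columns = colnames(x)),
            class = "ps_model")
}

#' Predict positive-class probabilities
#'
#' @param object a fitted [train_model()] object.
#' @param newx numeric feature matrix (or single vector) with the training
#'   column layout.
#' @param ... unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.ps_model <- function(object, newx, ...) {
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1,
                                         dimnames = list(NULL, object$columns))
  spec <- object$spec
  p <- switch(spec$algorithm,
    knn = knn_predict_proba(object$fit$train_x, object$fit$train_y, newx,
                            object$fit$k),
    lr = {
      beta <- object$fit$coefficients
      beta[is.na(beta)] <- 0  # aliased columns from rank-deficient fits
      eta <- drop(cbind(1, newx) %*% beta)
      stats::plogis(eta)
    },
    rf = unname(stats::predict(object$fit, newx, type = "prob")[, "1"]))
  as.numeric(p)
}

#' Personalized prediction for an index patient
#'
#' The core individualized-modeling step: rank the training pool by
#' patient similarity to the query, keep the top `k` most similar
#' patients, train the requested classifier on them, and score the query.
#' One model is (conceptually) fitted per index patient.
#'
#' If the selected subset contains a single class -- possible at very
#' small `k` when the neighborhood is pure -- the subset's class
#' proportion (0 or 1) is returned directly and a message is logged,
#' rather than failing.
#'
#' @param query a [cohort()] of exactly one patient.
#' @param pool a labeled training [cohort()].
#' @param k number of similar patients to train on.
#' @param spec a [model_spec()].
#' @param weights a [similarity_weights()].
#' @param scheme diagnosis-similarity scheme, `"ccs"` or `"icd"`.
#' @param ccs_map crosswalk for the CCS scheme.
#' @param screened screened diagnosis feature codes; computed from `pool`
#'   with the default screen (excluding [dm_code_prefixes()]) when `NULL`.
#' @param lab_params lab standardization parameters; fitted on `pool`
#'   when `NULL`.
#' @param seed integer seed for stochastic fits.
#' @return Positive-class probability for the query patient.
#' @export
personalized_predict <- function(query, pool, k, spec = model_spec("rf"),
                                 weights = similarity_weights(),
                                 scheme = c("ccs", "icd"),
                                 ccs_map = default_ccs_map(),
                                 screened = NULL, lab_params = NULL,
                                 seed = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(pool$label)) stop_("training pool must be labeled")
  lab_params <- lab_params %||% normalize_labs(pool$labs)$params
  screened <- screened %||% screen_diagnosis_features(
    pool, exclude_prefixes = dm_code_prefixes())
  prof <- similarity_profile(query, pool, weights, scheme, ccs_map,
                             lab_params)
  ids <- select_top_k(prof, k)
  train <- build_feature_vectors(pool, ids, screened, lab_params)
  qx <- build_feature_vectors(query, screened = screened,
                              lab_params = lab_params)$x
  if (length(unique(train$y)) < 2) {
    message(sprintf("single-class top-%d subset for query %s; returning class proportion",
                    k, query$id))
    return(mean(train$y))
  }
  fit <- train_model(train$x, train$y, spec, seed = seed)
  predict(fit, qx)
}
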