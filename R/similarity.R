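# Feature-level similarities and their weighted combination into the
# patient similarity PS.  Four components: diagnosis similarity (ICD-10
# hierarchical set measure or CCS cosine), laboratory similarity
# (1 - min-max-normalized Euclidean distance over the standardized lab
# panel), age ratio, and sex agreement.

#' Similarity weights
#'
#' The convex weights combining the four feature similarities into the
#' patient similarity: diagnosis, laboratory, age, sex.  Defaults 0.4,
#' 0.4, 0.1, 0.1.  Weights must lie in `[0, 1]` and sum to 1 (tolerance
#' 1e-9).
#'
#' @param w_diag,w_lab,w_age,w_sex component weights.
#' @return An object of class `similarity_weights`.
#' @export
similarity_weights <- function(w_diag = 0.4, w_lab = 0.4, w_age = 0.1,
                               w_sex = 0.1) {
  w <- c(diag = w_diag, lab = w_lab, age = w_age, sex = w_sex)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop_("similarity weights must lie in [0, 1]")
  if (abs(sum(w) - 1) > 1e-9)
    stop_("similarity weights must sum to 1 (got %.12g)", sum(w))
  structure(as.list(w), class = "similarity_weights")
}

#' @export
print.similarity_weights <- function(x, ...) {
  cat(sprintf("similarity weights: diag=%.3g lab=%.3g age=%.3g sex=%.3g\n",
              x$diag, x$lab, x$age, x$sex))
  invisible(x)
}

#' Age similarity
#'
#' Ratio of the smaller to the larger age; 1 for equal ages.  Vectorised.
#'
#' @param age_i,age_j ages in years, strictly positive.
#' @return Numeric vector in `(0, 1]`.
#' @export
fs_age <- function(age_i, age_j) {
  if (any(!is.finite(age_i)) || any(!is.finite(age_j)) ||
      any(age_i <= 0) || any(age_j <= 0))
    stop_("ages must be positive and finite")
  pmin(age_i, age_j) / pmax(age_i, age_j)
}

#' Sex similarity
#'
#' Indicator of matching sex: 1 if equal, 0 otherwise.  Vectorised.
#'
#' @param sex_i,sex_j sex categories, `"male"` or `"female"`.
#' @return Numeric vector of 0/1.
#' @export
fs_sex <- function(sex_i, sex_j) {
  ok <- c("male", "female")
  if (!all(sex_i %in% ok) || !all(sex_j %in% ok))
    stop_("sex must be 'male' or 'female'")
  as.numeric(sex_i == sex_j)
}

#' Standardize a laboratory matrix
#'
#' Column-wise z-scoring.  When `params` is `NULL` the means and standard
#' deviations are estimated from `labs` (the training pool) and returned,
#' so that test patients can be transformed with the training statistics.
#'
#' @param labs numeric matrix, one row per patient, one column per lab item.
#' @param params optional list with elements `center` and `scale` from a
#'   previous fit.
#' @return List with `labs` (standardized matrix) and `params`
#'   (`list(center, scale)`).
#' @export
normalize_labs <- function(labs, params = NULL) {
  labs <- as.matrix(labs)
  if (anyNA(labs)) stop_("lab matrix contains missing values")
  if (is.null(params)) {
    center <- colMeans(labs)
    scale_ <- apply(labs, 2, stats::sd)
    zero <- scale_ <= 0 | !is.finite(scale_)
    if (any(zero))
      stop_("zero-variance lab column(s): %s",
            paste(colnames(labs)[zero] %||% which(zero), collapse = ", "))
    params <- list(center = center, scale = scale_)
  } else {
    if (length(params$center) != ncol(labs))
      stop_("lab standardization parameters do not match the lab panel width")
  }
  z <- sweep(sweep(labs, 2, params$center, "-"), 2, params$scale, "/")
  list(labs = z, params = params)
}

#' Euclidean distance between two lab vectors
#'
#' @param labs_i,labs_j standardized lab vectors of equal length.
#' @return Non-negative number.
#' @export
lab_distance <- function(labs_i, labs_j) {
  if (length(labs_i) != length(labs_j))
    stop_("lab vectors differ in length (%d vs %d)",
          length(labs_i), length(labs_j))
  sqrt(sum((labs_i - labs_j)^2))
}

#' Laboratory similarity of a query against a pool
#'
#' Euclidean distances from the query to every pool patient are min-max
#' normalized over the batch and flipped: the closest pool patient scores
#' 1, the farthest 0.  The normalization is therefore relative to this
#' query/pool pairing, not an absolute metric.  When all distances are
#' equal (degenerate batch) every patient scores 1 and a message is
#' emitted.
#'
#' @param query_labs standardized lab vector of the query patient.
#' @param pool_labs matrix of standardized pool lab vectors (rows).
#' @return Numeric vector of similarities in `[0, 1]`, one per pool row.
#' @export
fs_lab_batch <- function(query_labs, pool_labs) {
  pool_labs <- as.matrix(pool_labs)
  if (ncol(pool_labs) != length(query_labs))
    stop_("query and pool lab widths differ")
  d <- sqrt(rowSums(sweep(pool_labs, 2, query_labs, "-")^2))
  rng <- range(d)
  if (diff(rng) == 0) {
    message("degenerate lab-distance batch (all distances equal); FS_L set to 1")
    return(rep(1, length(d)))
  }
  1 - (d - rng[1]) / (rng[2] - rng[1])
}

#' Hierarchical diagnosis-set similarity (ICD-10 scheme)
#'
#' Set similarity between two ICD-10 diagnosis sets built from the
#' pairwise hierarchical code distance `d(x, y) = 1 - S(x, y)` (see
#' [code_similarity()]): each code private to one set contributes its mean
#' distance to the other set, the contributions are averaged over the
#' union, and the result is flipped to a similarity.  Identical sets score
#' 1; sets from disjoint chapters score 0.
#'
#' @param x,y non-empty character vectors of canonical full-depth ICD-10
#'   codes (treated as sets).
#' @return Similarity in `[0, 1]`.
#' @export
fs_d1 <- function(x, y) {
  x <- unique(x); y <- unique(y)
  if (length(x) == 0 || length(y) == 0)
    stop_("diagnosis sets must be non-empty")
  .check_canonical(x); .check_canonical(y)
  u <- union(x, y)
  xd <- setdiff(x, y)
  yd <- setdiff(y, x)
  t1 <- if (length(xd)) sum(vapply(xd, function(a)
    mean(1 - code_similarity(rep(a, length(y)), y)), numeric(1))) else 0
  t2 <- if (length(yd)) sum(vapply(yd, function(b)
    mean(1 - code_similarity(rep(b, length(x)), x)), numeric(1))) else 0
  1 - (t1 + t2) / length(u)
}

# fs_d1 against many sets at once, with a precomputed distance matrix over
# the code universe (D = 1 - S, dimnames = universe).  x_idx / y_idx are
# integer index vectors into the universe.
.fs_d1_idx <- function(x_idx, y_idx, D) {
  xd <- setdiff(x_idx, y_idx)
  yd <- setdiff(y_idx, x_idx)
  nu <- length(union(x_idx, y_idx))
  t1 <- if (length(xd)) sum(rowMeans(D[xd, y_idx, drop = FALSE])) else 0
  t2 <- if (length(yd)) sum(rowMeans(D[yd, x_idx, drop = FALSE])) else 0
  1 - (t1 + t2) / nu
}

#' Cosine diagnosis similarity (CCS scheme)
#'
#' Cosine similarity between two 259-dimensional binary CCS category
#' vectors (see [ccs_vector()]).  An all-zero vector cannot be normalized;
#' the similarity is defined as 0 with a warning.
#'
#' @param vx,vy 0/1 vectors of length 259.
#' @return Similarity in `[0, 1]`.
#' @export
fs_d2 <- function(vx, vy) {
  if (length(vx) != 259 || length(vy) != 259)
    stop_("CCS vectors must have length 259")
  nx <- sqrt(sum(vx^2)); ny <- sqrt(sum(vy^2))
  if (nx == 0 || ny == 0) {
    warning("all-zero CCS vector; similarity defined as 0", call. = FALSE)
    return(0)
  }
  sum(vx * vy) / (nx * ny)
}

#' Combine feature similarities into the patient similarity
#'
#' Convex combination `w_diag*FS_D + w_lab*FS_L + w_age*FS_A + w_sex*FS_S`.
#' Vectorised over the feature-similarity arguments.
#'
#' @param fs_d,fs_l,fs_a,fs_s feature similarities in `[0, 1]`.
#' @param weights a [similarity_weights()] object.
#' @return Patient similarity in `[0, 1]`.
#' @export
patient_similarity <- function(fs_d, fs_l, fs_a, fs_s,
                               weights = similarity_weights()) {
  if (!inherits(weights, "similarity_weights"))
    stop_("weights must be created with similarity_weights()")
  comp <- c(fs_d, fs_l, fs_a, fs_s)
  if (any(!is.finite(comp)) || any(comp < -1e-12) || any(comp > 1 + 1e-12))
    stop_("feature similarities must lie in [0, 1]")
  weights$diag * fs_d + weights$lab * fs_l + weights$age * fs_a +
    weights$sex * fs_s
}

# Shared precomputation for query-vs-pool similarity: returns component
# matrices (queries x pool) and the PS matrix.  Lab standardization is
# fitted on the pool unless params are supplied.
.similarity_components <- function(queries, pool, weights, scheme, ccs_map,
                                   lab_params = NULL) {
  scheme <- match.arg(scheme, c("ccs", "icd"))
  nq <- cohort_size(queries); np <- cohort_size(pool)
  if (np == 0) stop_("similarity pool is empty")

  if (is.null(lab_params)) lab_params <- normalize_labs(pool$labs)$params
  pl <- normalize_labs(pool$labs, lab_params)$labs
  ql <- normalize_labs(queries$labs, lab_params)$labs

  # squared Euclidean distances via the Gram expansion, then per-query
  # min-max normalization of the batch
  d2 <- outer(rowSums(ql^2), rep(1, np)) +
    outer(rep(1, nq), rowSums(pl^2)) - 2 * tcrossprod(ql, pl)
  d <- sqrt(pmax(d2, 0))
  fsl <- t(apply(d, 1, function(row) {
    rng <- range(row)
    if (diff(rng) == 0) rep(1, length(row))
    else 1 - (row - rng[1]) / (rng[2] - rng[1])
  }))
  if (np == 1) fsl <- matrix(fsl, nrow = nq)

  fsa <- outer(queries$age, pool$age, function(a, b) pmin(a, b) / pmax(a, b))
  fss <- outer(queries$sex, pool$sex, "==") * 1

  if (scheme == "ccs") {
    qm <- do.call(rbind, lapply(queries$diagnoses, ccs_vector, mapping = ccs_map))
    pm <- do.call(rbind, lapply(pool$diagnoses, ccs_vector, mapping = ccs_map))
    qn <- sqrt(rowSums(qm^2)); pn <- sqrt(rowSums(pm^2))
    if (any(qn == 0) || any(pn == 0))
      warning("all-zero CCS vector; similarity defined as 0", call. = FALSE)
    denom <- outer(qn, pn)
    fsd <- tcrossprod(qm, pm)
    fsd <- ifelse(denom > 0, fsd / ifelse(denom > 0, denom, 1), 0)
  } else {
    universe <- sort(unique(c(unlist(queries$diagnoses), unlist(pool$diagnoses))))
    D <- 1 - .code_sim_matrix(universe)
    qi <- lapply(queries$diagnoses, match, table = universe)
    pi_ <- lapply(pool$diagnoses, match, table = universe)
    fsd <- matrix(0, nq, np)
    for (i in seq_len(nq))
      for (j in seq_len(np))
        fsd[i, j] <- .fs_d1_idx(qi[[i]], pi_[[j]], D)
  }

  ps <- weights$diag * fsd + weights$lab * fsl + weights$age * fsa +
    weights$sex * fss
  dimnames(ps) <- list(queries$id, pool$id)
  list(ps = ps, fsd = fsd, fsl = fsl, fsa = fsa, fss = fss)
}

#' Ranked similarity profile of a query patient against a pool
#'
#' Computes all four feature similarities of the query against every pool
#' patient, combines them with [patient_similarity()] weights, and returns
#' the pool ranked by decreasing patient similarity (ties broken by
#' ascending patient id, so top-K selection is reproducible).
#'
#' @param query a [cohort()] containing exactly one patient.
#' @param pool a [cohort()] of candidate similar patients.
#' @param weights a [similarity_weights()] object.
#' @param scheme diagnosis-similarity scheme, `"ccs"` (cosine over CCS
#'   categories) or `"icd"` (hierarchical ICD-10 set measure).
#' @param ccs_map crosswalk for the `"ccs"` scheme.
#' @param lab_params optional lab standardization parameters fitted on the
#'   training pool (fitted from `pool` when `NULL`).
#' @return A data.frame of class `similarity_profile` with columns `id`,
#'   `ps`, `fs_d`, `fs_l`, `fs_a`, `fs_s`, ordered by decreasing `ps`;
#'   attributes `query_id` and `scheme`.
#' @export
similarity_profile <- function(query, pool, weights = similarity_weights(),
                               scheme = c("ccs", "icd"),
                               ccs_map = default_ccs_map(),
                               lab_params = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(query, "cohort"), inherits(pool, "cohort"))
  if (cohort_size(query) != 1)
    stop_("query must be a cohort of exactly one patient")
  comp <- .similarity_components(query, pool, weights, scheme, ccs_map,
                                 lab_params)
  prof <- data.frame(id = pool$id, ps = comp$ps[1, ], fs_d = comp$fsd[1, ],
                     fs_l = comp$fsl[1, ], fs_a = comp$fsa[1, ],
                     fs_s = comp$fss[1, ], stringsAsFactors = FALSE,
                     row.names = NULL)
  prof <- prof[order(-prof$ps, prof$id), , drop = FALSE]
  rownames(prof) <- NULL
  structure(prof, class = c("similarity_profile", "data.frame"),
            query_id = query$id, scheme = scheme)
}

#' Patient-similarity matrix between two cohorts
#'
#' Patient similarity of every query against every pool patient, as a
#' dense matrix (rows = query ids, columns = pool ids).  Suitable for
#' export with [utils::write.csv()].
#'
#' @inheritParams similarity_profile
#' @param queries a [cohort()] of query patients.
#' @return Numeric matrix of patient similarities in `[0, 1]`.
#' @export
similarity_matrix <- function(queries, pool, weights = similarity_weights(),
                              scheme = c("ccs", "icd"),
                              ccs_map = default_ccs_map(),
                              lab_params = NULL) {
  scheme <- match.arg(scheme)
  .similarity_components(queries, pool, weights, scheme, ccs_map,
                         lab_params)$ps
}
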