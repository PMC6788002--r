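# Cohort container and delimited-text I/O.
#
# A cohort holds one row per de-identified patient: id, age (years), sex,
# a non-empty set of canonical ICD-10 diagnosis codes, a fixed-width panel
# of continuous laboratory values and an optional binary disease label.
# On disk a cohort is a CSV with header
#   id,age,sex,icd_codes[,label],<lab columns...>
# where icd_codes is a semicolon-separated code list.  Numeric fields are
# written with 17 significant digits so that write/read round-trips are
# exact.

#' Construct a patient cohort
#'
#' @param id character vector of unique patient identifiers.
#' @param age numeric vector of ages in years, strictly positive.
#' @param sex character vector, `"male"` or `"female"`.
#' @param diagnoses list of character vectors of ICD-10 codes (one
#'   non-empty set per patient; canonicalized via [parse_icd_code()]).
#' @param labs numeric matrix of laboratory values, one row per patient;
#'   column names are the lab item identifiers.  No missing values.
#' @param label optional 0/1 disease labels (1 = case).
#' @return An object of class `cohort`: a list with elements `id`, `age`,
#'   `sex`, `diagnoses`, `labs`, `lab_names`, `label`.
#' @export
cohort <- function(id, age, sex, diagnoses, labs, label = NULL) {
  id <- as.character(id)
  n <- length(id)
  labs <- as.matrix(labs)
  if (is.null(colnames(labs)))
    colnames(labs) <- sprintf("lab_%02d", seq_len(ncol(labs)))
  if (anyDuplicated(id))
    stop_("duplicate patient id(s): %s",
          paste(unique(id[duplicated(id)]), collapse = ", "))
  if (length(age) != n || length(sex) != n || length(diagnoses) != n ||
      nrow(labs) != n || (!is.null(label) && length(label) != n))
    stop_("cohort fields have inconsistent lengths")
  if (any(!is.finite(age) | age <= 0)) stop_("ages must be positive")
  if (!all(sex %in% c("male", "female")))
    stop_("sex must be 'male' or 'female'")
  if (anyNA(labs)) stop_("lab matrix contains missing values")
  diagnoses <- lapply(diagnoses, function(d) {
    if (length(d) == 0) stop_("empty diagnosis set")
    sort(unique(parse_icd_code(d)))
  })
  if (!is.null(label)) {
    label <- as.integer(label)
    if (any(is.na(label) | !label %in% c(0L, 1L)))
      stop_("labels must be 0/1")
  }
  rownames(labs) <- id
  names(diagnoses) <- id
  structure(list(id = id, age = as.numeric(age), sex = as.character(sex),
                 diagnoses = diagnoses, labs = labs,
                 lab_names = colnames(labs), label = label),
            class = "cohort")
}

#' Number of patients in a cohort
#' @param x a [cohort()].
#' @return Integer count.
#' @export
cohort_size <- function(x) length(x$id)

#' Subset a cohort by index or patient id
#'
#' @param x a [cohort()].
#' @param i integer/logical indices or character ids.
#' @param ... unused.
#' @return A [cohort()] with the selected patients, in the order of `i`.
#' @export
`[.cohort` <- function(x, i, ...) {
  if (is.character(i)) {
    j <- match(i, x$id)
    if (anyNA(j)) stop_("unknown patient id(s): %s",
                        paste(i[is.na(j)], collapse = ", "))
    i <- j
  }
  cohort(x$id[i], x$age[i], x$sex[i], x$diagnoses[i],
         x$labs[i, , drop = FALSE],
         label = if (!is.null(x$label)) x$label[i])
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("patient cohort: %d patients, %d lab items%s\n",
              cohort_size(x), length(x$lab_names),
              if (is.null(x$label)) " (unlabeled)"
              else sprintf(", %d cases / %d controls",
                           sum(x$label == 1), sum(x$label == 0))))
  invisible(x)
}

.fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Write a cohort as delimited text
#'
#' Inverse of [read_cohort()]; numeric columns use 17 significant digits
#' so the round-trip reproduces the cohort exactly.
#'
#' @param x a [cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  df <- data.frame(id = x$id, age = .fmt_num(x$age), sex = x$sex,
                   icd_codes = vapply(x$diagnoses, paste, character(1),
                                      collapse = ";"),
                   stringsAsFactors = FALSE)
  if (!is.null(x$label)) df$label <- x$label
  labs <- apply(x$labs, 2, .fmt_num)
  if (cohort_size(x) == 1) labs <- matrix(labs, nrow = 1,
                                          dimnames = list(NULL, x$lab_names))
  if (cohort_size(x) > 0) df <- cbind(df, as.data.frame(labs))
  else for (nm in x$lab_names) df[[nm]] <- character(0)
  utils::write.csv(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from delimited text
#'
#' Expects a CSV with columns `id`, `age`, `sex`, `icd_codes` (a
#' semicolon-separated ICD-10 code list), an optional `label` column and
#' one column per laboratory item.  Every violation (missing lab value,
#' duplicate id, unparsable code, non-positive age, empty diagnosis set)
#' is reported with its row number.
#'
#' @param path input file path.
#' @return A [cohort()].
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = c(id = "character"))
  need <- c("id", "age", "sex", "icd_codes")
  if (!all(need %in% names(df)))
    stop_("cohort file must have columns: %s", paste(need, collapse = ", "))
  lab_cols <- setdiff(names(df), c(need, "label"))
  if (length(lab_cols) == 0) stop_("cohort file has no lab columns")
  if (nrow(df) == 0)
    return(cohort(character(0), numeric(0), character(0), list(),
                  matrix(numeric(0), 0, length(lab_cols),
                         dimnames = list(NULL, lab_cols))))
  for (col in lab_cols) {
    v <- df[[col]]
    bad <- which(is.na(v) | (is.character(v) & !nzchar(v)))
    if (length(bad))
      stop_("missing lab value in column '%s' at row %d", col, bad[1])
    df[[col]] <- as.numeric(v)
    if (anyNA(df[[col]]))
      stop_("non-numeric lab value in column '%s' at row %d", col,
            which(is.na(df[[col]]))[1])
  }
  if (anyDuplicated(df$id))
    stop_("duplicate patient id at row %d", which(duplicated(df$id))[1])
  bad <- which(!is.finite(df$age) | df$age <= 0)
  if (length(bad)) stop_("non-positive age at row %d", bad[1])
  diagnoses <- vector("list", nrow(df))
  for (r in seq_len(nrow(df))) {
    raw <- strsplit(df$icd_codes[r], ";", fixed = TRUE)[[1]]
    raw <- raw[nzchar(trimws(raw))]
    if (length(raw) == 0) stop_("empty diagnosis set at row %d", r)
    diagnoses[[r]] <- tryCatch(parse_icd_code(raw), error = function(e)
      stop_("row %d: %s", r, conditionMessage(e)))
  }
  cohort(df$id, df$age, df$sex, diagnoses,
         as.matrix(df[, lab_cols, drop = FALSE]),
         label = df[["label"]])
}

#' Drop patients carrying blacklisted ICD-10 chapters
#'
#' Optional exclusion filter mirroring common EMR study designs that
#' remove obstetric (O), perinatal (P), injury/poisoning (S, T) and
#' supplementary-classification (V, Y) records.
#'
#' @param x a [cohort()].
#' @param chapters chapter letters to blacklist.
#' @return The filtered [cohort()].
#' @export
filter_chapters <- function(x, chapters = c("O", "P", "S", "T", "V", "Y")) {
  keep <- !vapply(x$diagnoses, function(d)
    any(substr(d, 1, 1) %in% chapters), logical(1))
  x[which(keep)]
}

# Binary presence matrix (patients x codes) over a code universe.
.presence_matrix <- function(x, universe = NULL) {
  universe <- universe %||% sort(unique(unlist(x$diagnoses)))
  m <- vapply(universe, function(code)
    vapply(x$diagnoses, function(d) code %in% d, logical(1)),
    logical(cohort_size(x)))
  m <- matrix(as.numeric(m), nrow = cohort_size(x),
              dimnames = list(x$id, universe))
  m
}

#' Screen diagnosis codes for use as model features
#'
#' Two-stage filter on a labeled cohort: codes observed in fewer than
#' `min_prevalence` of patients are dropped, and among the remainder only
#' codes whose presence differs between cases and controls (Pearson
#' chi-squared test on the 2x2 label-by-presence table, `P < alpha`) are
#' retained.  Codes matching `exclude_prefixes` are removed first; by
#' default nothing is excluded, but callers predicting a diagnosis-defined
#' label should exclude the label-defining code block (see
#' [dm_code_prefixes()]) to avoid target leakage.
#'
#' @param x a labeled [cohort()].
#' @param min_prevalence minimum fraction of patients carrying the code
#'   (default 0.01).
#' @param alpha significance level for the chi-squared screen (default 0.05).
#' @param exclude_prefixes character vector of ICD-10 prefixes to exclude
#'   from the candidate set.
#' @return Sorted character vector of retained codes.
#' @export
screen_diagnosis_features <- function(x, min_prevalence = 0.01, alpha = 0.05,
                                      exclude_prefixes = NULL) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(x$label)) stop_("feature screening requires a labeled cohort")
  pres <- .presence_matrix(x)
  if (length(exclude_prefixes)) {
    drop <- vapply(colnames(pres), function(code)
      any(startsWith(code, exclude_prefixes)), logical(1))
    pres <- pres[, !drop, drop = FALSE]
  }
  prev <- colMeans(pres)
  pres <- pres[, prev >= min_prevalence, drop = FALSE]
  keep <- vapply(colnames(pres), function(code) {
    tab <- table(factor(pres[, code], levels = c(0, 1)),
                 factor(x$label, levels = c(0, 1)))
    p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    is.finite(p) && p < alpha
  }, logical(1))
  sort(colnames(pres)[keep])
}

#' ICD-10 prefixes defining diabetes mellitus
#'
#' The E10-E14 block; the diagnosis-defined label of the synthetic
#' cohorts, and the default feature-screen exclusion in the evaluation
#' harness.
#'
#' @return Character vector of prefixes.
#' @export
dm_code_prefixes <- function() c("E10", "E11", "E12", "E13", "E14")
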