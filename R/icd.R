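# ICD-10 code handling: canonicalization, the 4-level truncated hierarchy,
# nearest common ancestors, pairwise hierarchical similarity, and the
# collapse onto Clinical Classifications Software (CCS) categories.
#
# Codes are kept as plain character vectors in canonical form: one chapter
# letter followed by up to three digits, no dot ("E10.9" -> "E109").  The
# hierarchy has four levels -- letter (1), letter+1 digit (2), letter+2
# digits (3), letter+3 digits (4) -- so a code's level is simply its number
# of characters.  Two codes from different chapters share only a virtual
# root, represented as the empty string "" at level 0.

#' Depth of the truncated ICD-10 hierarchy
#'
#' Constant number of levels used by [code_similarity()]: chapter letter,
#' then one, two and three digits.
#' @export
ICD10_DEPTH <- 4L

.icd_pattern <- "^[A-Z][0-9]{0,3}$"

#' Parse and canonicalize ICD-10 codes
#'
#' Truncates a raw diagnosis code to the statistical form used throughout
#' the package: the chapter letter plus the first three digits, with any
#' dot removed (`"E10.9"` becomes `"E109"`).  Characters beyond the third
#' digit are discarded.  The function is vectorised and idempotent on
#' canonical input.
#'
#' @param x character vector of raw ICD-10 code strings.
#' @return Character vector of canonical codes matching `[A-Z][0-9]{0,3}`.
#' @examples
#' parse_icd_code(c("E10.9", "E11.90x", "I25.1"))
#' @export
parse_icd_code <- function(x) {
  if (length(x) == 0) return(character(0))
  x <- toupper(trimws(as.character(x)))
  if (any(is.na(x) | !nzchar(x)))
    stop_("ICD-10 code is missing or empty")
  letter <- substr(x, 1, 1)
  bad <- !letter %in% LETTERS
  if (any(bad))
    stop_("ICD-10 code must start with a letter A-Z: %s",
          paste(unique(x[bad]), collapse = ", "))
  body <- gsub(".", "", substring(x, 2), fixed = TRUE)
  head3 <- substr(body, 1, 3)
  bad <- !grepl("^[0-9]*$", head3)
  if (any(bad))
    stop_("non-digit characters among the first three digits of ICD-10 code: %s",
          paste(unique(x[bad]), collapse = ", "))
  paste0(letter, head3)
}

.check_canonical <- function(x) {
  bad <- !grepl(.icd_pattern, x)
  if (any(bad))
    stop_("not a canonical ICD-10 code (use parse_icd_code): %s",
          paste(unique(x[bad]), collapse = ", "))
  invisible(x)
}

#' Hierarchy level of a canonical ICD-10 code
#'
#' Level 1 is the chapter letter; each digit adds one level, up to level 4
#' for a full truncated code.  The virtual root `""` has level 0.
#'
#' @param code character vector of canonical codes (or `""` for the root).
#' @return Integer vector of levels in `0:4`.
#' @examples
#' code_level(c("E109", "E1", "E"))
#' @export
code_level <- function(code) {
  root <- !nzchar(code)
  .check_canonical(code[!root])
  nchar(code)
}

# Length of the common prefix of two equal-length character vectors of
# canonical codes (vectorised; used to build code-similarity matrices).
.common_prefix_len <- function(x, y) {
  n <- pmin(nchar(x), nchar(y))
  out <- integer(length(x))
  active <- seq_along(x)
  for (k in 1:4) {
    active <- active[n[active] >= k &
      substr(x[active], k, k) == substr(y[active], k, k)]
    if (length(active) == 0) break
    out[active] <- k
  }
  out
}

#' Nearest common ancestor of two ICD-10 codes
#'
#' The deepest node of the truncated hierarchy that is an ancestor of both
#' codes, i.e. their longest common prefix.  Codes from different chapters
#' share only the virtual root, returned as `""` (level 0).
#'
#' @param x,y canonical ICD-10 codes (vectorised, recycled).
#' @return Character vector of ancestor codes (`""` for the root).
#' @examples
#' nearest_common_ancestor("E109", "E119")  # "E1"
#' @export
nearest_common_ancestor <- function(x, y) {
  .check_canonical(x); .check_canonical(y)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  substr(x, 1, .common_prefix_len(x, y))
}

#' Hierarchical similarity between two ICD-10 codes
#'
#' The level of the nearest common ancestor divided by the hierarchy depth
#' (4).  Symmetric and bounded in `[0, 1]`; codes from different chapters
#' score 0, identical full-depth codes score 1.
#'
#' @param x,y canonical ICD-10 codes (vectorised, recycled).
#' @return Numeric vector of similarities in `[0, 1]`.
#' @examples
#' code_similarity("E109", "E119")  # 2/4 = 0.5
#' @export
code_similarity <- function(x, y) {
  .check_canonical(x); .check_canonical(y)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  .common_prefix_len(x, y) / ICD10_DEPTH
}

# Dense pairwise similarity matrix over a code universe; rows/cols named.
.code_sim_matrix <- function(universe) {
  m <- length(universe)
  idx <- expand.grid(i = seq_len(m), j = seq_len(m))
  S <- matrix(.common_prefix_len(universe[idx$i], universe[idx$j]) / ICD10_DEPTH,
              m, m, dimnames = list(universe, universe))
  S
}

#' Construct an ICD-10 to CCS crosswalk
#'
#' A crosswalk maps ICD-10 code prefixes to single-level CCS diagnosis
#' categories (integers 1-259).  Lookups use longest-prefix matching, so a
#' specific entry (e.g. `E110 -> 50`) overrides a broader one (`E1 -> 49`).
#'
#' @param prefix character vector of canonical ICD-10 prefixes (unique).
#' @param ccs integer vector of CCS category numbers in `1:259`.
#' @return An object of class `ccs_map`.
#' @seealso [read_ccs_map()], [map_to_ccs()], [ccs_vector()]
#' @export
ccs_map <- function(prefix, ccs) {
  prefix <- parse_icd_code(prefix)
  ccs <- as.integer(ccs)
  if (length(prefix) != length(ccs))
    stop_("prefix and ccs must have the same length")
  if (anyDuplicated(prefix))
    stop_("duplicate prefixes in CCS crosswalk: %s",
          paste(unique(prefix[duplicated(prefix)]), collapse = ", "))
  if (any(is.na(ccs) | ccs < 1 | ccs > 259))
    stop_("CCS category numbers must lie in 1..259")
  structure(data.frame(prefix = prefix, ccs = ccs, stringsAsFactors = FALSE),
            class = c("ccs_map", "data.frame"))
}

#' Read a CCS crosswalk from tab-separated text
#'
#' Expects a header line `icd_prefix<TAB>ccs` and one prefix per row.
#'
#' @param path path to the crosswalk file.
#' @return A [ccs_map()] object.
#' @export
read_ccs_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("icd_prefix", "ccs") %in% names(df)))
    stop_("crosswalk must have columns 'icd_prefix' and 'ccs'")
  ccs_map(df$icd_prefix, df$ccs)
}

#' Packaged synthetic CCS crosswalk
#'
#' Crosswalk covering the synthetic code universe of [synthetic_config()];
#' a stand-in for a full crosswalk, suitable for the generated cohorts.
#'
#' @return A [ccs_map()] object.
#' @export
default_ccs_map <- function() {
  read_ccs_map(system.file("extdata", "ccs_crosswalk_synthetic.tsv",
                           package = "patsim", mustWork = TRUE))
}

#' Map ICD-10 codes to CCS categories
#'
#' Longest-prefix lookup against a crosswalk.  Codes with no matching
#' prefix yield `NA`; callers decide whether that is an error (see
#' [ccs_vector()]).
#'
#' @param codes character vector of canonical ICD-10 codes.
#' @param mapping a [ccs_map()].
#' @return Integer vector of CCS categories, `NA` where unmapped.
#' @export
map_to_ccs <- function(codes, mapping) {
  stopifnot(inherits(mapping, "ccs_map"))
  if (length(codes) == 0) return(integer(0))
  .check_canonical(codes)
  vapply(codes, function(code) {
    hit <- startsWith(code, mapping$prefix)
    if (!any(hit)) return(NA_integer_)
    cand <- mapping[hit, ]
    cand$ccs[which.max(nchar(cand$prefix))]
  }, integer(1), USE.NAMES = FALSE)
}

#' Binary CCS category vector for a diagnosis set
#'
#' Collapses a set of ICD-10 codes onto the 259 single-level CCS
#' categories as a 0/1 indicator vector (set semantics: repeated hits on a
#' category still give 1).
#'
#' @param codes character vector of canonical ICD-10 codes (a set).
#' @param mapping a [ccs_map()].
#' @param on_unmapped `"drop"` (default) drops unmapped codes with a
#'   warning; `"error"` fails instead.
#' @return Integer 0/1 vector of length 259.
#' @export
ccs_vector <- function(codes, mapping, on_unmapped = c("drop", "error")) {
  on_unmapped <- match.arg(on_unmapped)
  ks <- map_to_ccs(codes, mapping)
  if (anyNA(ks)) {
    missing <- unique(codes[is.na(ks)])
    if (on_unmapped == "error")
      stop_("ICD-10 codes not covered by the CCS crosswalk: %s",
            paste(missing, collapse = ", "))
    warning(sprintf("dropping ICD-10 codes not covered by the CCS crosswalk: %s",
                    paste(missing, collapse = ", ")), call. = FALSE)
    ks <- ks[!is.na(ks)]
  }
  v <- integer(259)
  v[unique(ks)] <- 1L
  v
}
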