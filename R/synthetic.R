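# Synthetic EMR cohort generator.  Emulates the statistical structure of
# a hospital diabetes case-control population: two balanced classes
# (DM / non-DM), class-specific age distributions and male proportions, a
# 77-item continuous laboratory panel with a small glucose-like
# informative subset, and diagnosis-code sets drawn from a compact ICD-10
# universe with class-dependent prevalence.  DM-class patients always
# carry at least one code from the label-defining E10-E14 block; controls
# never do.

#' Default synthetic ICD-10 code universe
#'
#' A 33-code universe spanning multiple chapters and all four hierarchy
#' levels of sharing, with per-class prevalences.  The E10-E14 block is
#' exclusive to the DM class (prevalence 0 among controls).  Several pairs
#' share deep ICD-10 ancestors but map to different CCS categories (e.g.
#' E119 vs E112 share level-3 ancestor E11, CCS 49 vs 50) and vice versa
#' (R739 and R810 share only the chapter letter but both collapse to CCS
#' 259), so the two diagnosis-similarity schemes genuinely differ.
#'
#' @return Data.frame with columns `code`, `prev_dm`, `prev_ctrl`.
#' @export
default_code_universe <- function() {
  u <- rbind(
    # label-defining diabetes block (E10-E14): DM class only
    c("E109", 0.30, 0), c("E110", 0.10, 0), c("E112", 0.12, 0),
    c("E119", 0.45, 0), c("E129", 0.03, 0), c("E139", 0.03, 0),
    c("E149", 0.12, 0),
    # comorbidities with class-skewed prevalence
    c("I109", 0.60, 0.48), c("I219", 0.08, 0.06), c("I251", 0.40, 0.28),
    c("I259", 0.10, 0.07), c("I509", 0.10, 0.06), c("J449", 0.04, 0.05),
    c("K769", 0.12, 0.13), c("N179", 0.06, 0.03), c("R739", 0.12, 0.02),
    c("R810", 0.10, 0.01),
    # background codes with equal prevalence in both classes
    c("A099", 0.03, 0.03), c("B181", 0.02, 0.02), c("C349", 0.02, 0.02),
    c("D509", 0.03, 0.03), c("F329", 0.02, 0.02), c("G459", 0.04, 0.04),
    c("H259", 0.05, 0.05), c("I639", 0.09, 0.09), c("J069", 0.08, 0.08),
    c("J189", 0.05, 0.05), c("K219", 0.06, 0.06), c("K297", 0.10, 0.10),
    c("L039", 0.01, 0.01), c("M171", 0.03, 0.03), c("M545", 0.07, 0.07),
    c("N390", 0.05, 0.05))
  data.frame(code = u[, 1], prev_dm = as.numeric(u[, 2]),
             prev_ctrl = as.numeric(u[, 3]), stringsAsFactors = FALSE)
}

#' Synthetic cohort configuration
#'
#' Distributional targets for [generate_cohort()].  The defaults emulate
#' the study population the package is designed around: DM-class ages
#' 63.0 +/- 11.6 years versus 57.2 +/- 17.1 among controls (truncated at
#' `age_min`), male fractions 62.6% versus 73.5%, a 77-item lab panel
#' whose first `n_informative_labs` items (serum/urine glucose and
#' companions) are shifted by `lab_effect_size` standard deviations in the
#' DM class, and the diagnosis universe of [default_code_universe()].
#'
#' @param n_per_class patients per class (default 500).
#' @param age_mean_dm,age_sd_dm,age_mean_ctrl,age_sd_ctrl class-specific
#'   age distributions in years.
#' @param age_min lower truncation of the age distributions (years).
#' @param male_frac_dm,male_frac_ctrl class-specific male proportions.
#' @param n_labs laboratory panel width (default 77).
#' @param n_informative_labs number of class-informative lab items.
#' @param lab_effect_size standardized mean difference planted in the
#'   informative items.
#' @param code_universe data.frame as in [default_code_universe()].
#' @param diagnoses_per_patient length-2 range for per-patient diagnosis
#'   counts (default 1..11).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_class = 500,
                             age_mean_dm = 63.0, age_sd_dm = 11.6,
                             age_mean_ctrl = 57.2, age_sd_ctrl = 17.1,
                             age_min = 18,
                             male_frac_dm = 0.626, male_frac_ctrl = 0.735,
                             n_labs = 77, n_informative_labs = 6,
                             lab_effect_size = 0.8,
                             code_universe = default_code_universe(),
                             diagnoses_per_patient = c(1, 11)) {
  if (!is_count(n_per_class)) stop_("n_per_class must be a positive integer")
  fr <- c(male_frac_dm, male_frac_ctrl)
  if (any(fr < 0 | fr > 1)) stop_("male fractions must lie in [0, 1]")
  if (age_sd_dm <= 0 || age_sd_ctrl <= 0) stop_("age SDs must be positive")
  if (n_informative_labs > n_labs)
    stop_("n_informative_labs cannot exceed n_labs")
  stopifnot(is.data.frame(code_universe),
            all(c("code", "prev_dm", "prev_ctrl") %in% names(code_universe)))
  code_universe$code <- parse_icd_code(code_universe$code)
  prev <- c(code_universe$prev_dm, code_universe$prev_ctrl)
  if (any(prev < 0 | prev > 1)) stop_("code prevalences must lie in [0, 1]")
  if (length(diagnoses_per_patient) != 2 ||
      diagnoses_per_patient[1] < 1 ||
      diagnoses_per_patient[1] > diagnoses_per_patient[2])
    stop_("diagnoses_per_patient must be a valid range with minimum >= 1")
  dm_block <- vapply(code_universe$code, function(cd)
    any(startsWith(cd, dm_code_prefixes())), logical(1))
  if (!any(dm_block))
    stop_("code universe must contain at least one E10-E14 code")
  if (any(code_universe$prev_ctrl[dm_block] > 0))
    stop_("controls cannot carry E10-E14 codes (the label-defining block)")
  if (sum(code_universe$prev_ctrl) == 0)
    stop_("control class has no available codes (all prevalences 0)")
  structure(list(n_per_class = as.integer(n_per_class),
                 age_mean_dm = age_mean_dm, age_sd_dm = age_sd_dm,
                 age_mean_ctrl = age_mean_ctrl, age_sd_ctrl = age_sd_ctrl,
                 age_min = age_min,
                 male_frac_dm = male_frac_dm, male_frac_ctrl = male_frac_ctrl,
                 n_labs = as.integer(n_labs),
                 n_informative_labs = as.integer(n_informative_labs),
                 lab_effect_size = lab_effect_size,
                 code_universe = code_universe,
                 diagnoses_per_patient = as.integer(diagnoses_per_patient),
                 dm_block = code_universe$code[dm_block]),
            class = "synthetic_config")
}

# Lab panel layout: informative items first, named after glucose-related
# chemistry; deterministic per-item raw means/SDs so labs arrive on an
# arbitrary (unstandardized) scale and exercise normalize_labs().
.lab_layout <- function(config) {
  informative <- c("glucose_serum", "glucose_urine", "hba1c",
                   "triglycerides", "chloride_serum", "creatinine")
  n <- config$n_labs
  ni <- config$n_informative_labs
  names_ <- c(utils::head(informative, ni),
              sprintf("lab_%02d", seq_len(max(0, n - min(ni, length(informative))))))
  names_ <- names_[seq_len(n)]
  list(names = names_,
       mu = 2 + 0.5 * (seq_len(n) %% 7),
       sd = 0.5 + (seq_len(n) %% 3))
}

# truncated normal via inverse-CDF sampling
.rtnorm <- function(n, mean, sd, lower) {
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

# One patient's diagnosis set: per-code Bernoulli draws at class
# prevalence, a guaranteed E10-E14 code for DM patients, and enforcement
# of the per-patient count range.
.draw_diagnoses <- function(config, is_dm) {
  u <- config$code_universe
  prev <- if (is_dm) u$prev_dm else u$prev_ctrl
  have <- u$code[stats::runif(nrow(u)) < prev]
  if (is_dm && !any(have %in% config$dm_block)) {
    w <- u$prev_dm[match(config$dm_block, u$code)]
    have <- c(have, sample(config$dm_block, 1, prob = w))
  }
  rng <- config$diagnoses_per_patient
  if (length(have) < rng[1]) {
    pool <- setdiff(u$code[prev > 0], have)
    extra <- sample(pool, min(rng[1] - length(have), length(pool)),
                    prob = prev[match(pool, u$code)])
    have <- c(have, extra)
  }
  if (length(have) > rng[2]) {
    keep_dm <- intersect(have, config$dm_block)
    others <- setdiff(have, keep_dm)
    have <- c(keep_dm, sample(others, rng[2] - length(keep_dm)))
  }
  sort(unique(have))
}

#' Generate a labeled synthetic EMR cohort
#'
#' Draws `2 * n_per_class` patients (classes interleaved in id order)
#' according to a [synthetic_config()]: truncated-normal ages, Bernoulli
#' sex, normal labs on an arbitrary raw scale with the informative items
#' shifted by the configured effect size in the DM class, and diagnosis
#' sets as described in [synthetic_config()].  Fully reproducible under
#' `seed`.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return A labeled [cohort()] (label 1 = DM).
#' @export
generate_cohort <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_per_class
  lay <- .lab_layout(config)
  with_seed(seed, {
    label <- rep(c(1L, 0L), each = n)
    id <- sprintf("p%05d", seq_len(2 * n))
    age <- numeric(2 * n); sex <- character(2 * n)
    dm <- label == 1L
    age[dm] <- .rtnorm(n, config$age_mean_dm, config$age_sd_dm, config$age_min)
    age[!dm] <- .rtnorm(n, config$age_mean_ctrl, config$age_sd_ctrl,
                        config$age_min)
    sex[dm] <- ifelse(stats::runif(n) < config$male_frac_dm, "male", "female")
    sex[!dm] <- ifelse(stats::runif(n) < config$male_frac_ctrl, "male", "female")
    labs <- matrix(stats::rnorm(2 * n * config$n_labs), 2 * n,
                   dimnames = list(NULL, lay$names))
    labs <- sweep(labs, 2, lay$sd, "*")
    labs <- sweep(labs, 2, lay$mu, "+")
    ni <- config$n_informative_labs
    if (ni > 0)
      labs[dm, seq_len(ni)] <- labs[dm, seq_len(ni)] +
        rep(config$lab_effect_size * lay$sd[seq_len(ni)], each = n)
    diagnoses <- lapply(seq_len(2 * n), function(i)
      .draw_diagnoses(config, dm[i]))
    cohort(id, age, sex, diagnoses, labs, label = label)
  })
}

#' Per-class summary of the planted cohort structure
#'
#' Descriptive table (one row per characteristic) of a labeled cohort:
#' class means and SDs for age, male proportions, per-lab means, and
#' per-code prevalences.  Used to verify that a generated cohort hit its
#' configured targets.
#'
#' @param x a labeled [cohort()].
#' @return Data.frame with columns `characteristic`, `type`, `dm`, `ctrl`.
#' @export
planted_structure_report <- function(x) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(x$label)) stop_("structure report requires a labeled cohort")
  dm <- x$label == 1L
  rows <- list(
    data.frame(characteristic = "age_mean", type = "moment",
               dm = mean(x$age[dm]), ctrl = mean(x$age[!dm])),
    data.frame(characteristic = "age_sd", type = "moment",
               dm = stats::sd(x$age[dm]), ctrl = stats::sd(x$age[!dm])),
    data.frame(characteristic = "male_frac", type = "proportion",
               dm = mean(x$sex[dm] == "male"),
               ctrl = mean(x$sex[!dm] == "male")))
  for (lab in x$lab_names)
    rows[[length(rows) + 1]] <- data.frame(
      characteristic = paste0("lab:", lab), type = "moment",
      dm = mean(x$labs[dm, lab]), ctrl = mean(x$labs[!dm, lab]))
  pres <- .presence_matrix(x)
  for (code in colnames(pres))
    rows[[length(rows) + 1]] <- data.frame(
      characteristic = paste0("code:", code), type = "proportion",
      dm = mean(pres[dm, code]), ctrl = mean(pres[!dm, code]))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
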