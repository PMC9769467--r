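# Seeded synthetic three-cohort generator. Sampling order per record:
# cohort -> quarter/year of diagnosis (joint marginal) -> diagnosis date
# (uniform within the sampled quarter) -> demographics -> most severe
# disease phase -> derived phase flags / hospitalization -> intensive care /
# ventilation -> patient status (logistic outcome model) -> follow-up block.
# Structural rules are enforced afterwards and hold with probability 1:
# POP contains survivors only, HAP is fully hospitalized, hospitalization is
# "no" iff the most severe phase is mild (ambulatory care), and follow-up
# sub-variables are "n/a" iff no follow-up is available.

# Phase-flag encoding: the mild flag marks purely ambulatory courses (so it
# is perfectly correlated with hospitalization = "no"); a severe course also
# flags the moderate phase it passed through. The most severe phase is
# recoverable as the highest flagged phase.
severity_to_flags <- function(sev) {
  list(
    mild_phase = ifelse(sev == MISSING, MISSING,
                        ifelse(sev == "mild", "yes", "no")),
    moderate_phase = ifelse(sev == MISSING, MISSING,
                            ifelse(sev %in% c("moderate", "severe"),
                                   "yes", "no")),
    severe_phase = ifelse(sev == MISSING, MISSING,
                          ifelse(sev == "severe", "yes", "no")))
}

#' Recover the most severe disease phase from the released flags
#'
#' The released dataset carries three cumulative binary phase flags; the
#' collapsed severity category is the highest flagged phase.
#'
#' @param dataset A [cohort_dataset()].
#' @return Character vector with values `"mild"`, `"moderate"`, `"severe"`,
#'   or `"unknown/missing"`.
#' @export
most_severe_phase <- function(dataset) {
  ifelse(dataset$mild_phase == MISSING, MISSING,
         ifelse(dataset$severe_phase == "yes", "severe",
                ifelse(dataset$moderate_phase == "yes", "moderate", "mild")))
}

# First calendar day of a "Qx yyyy" label, and days in that quarter.
quarter_bounds <- function(qy) {
  q <- as.integer(substr(qy, 2, 2))
  y <- as.integer(substr(qy, 4, 7))
  start <- as.Date(sprintf("%d-%02d-01", y, (q - 1L) * 3L + 1L))
  nxt <- if (length(qy)) as.Date(ifelse(q == 4L,
                                        sprintf("%d-01-01", y + 1L),
                                        sprintf("%d-%02d-01", y, q * 3L + 1L)))
         else as.Date(character())
  list(start = start, ndays = as.integer(nxt - start))
}

#' Default synthetic generator configuration
#'
#' Marginals are the packaged reference per-cohort counts of the original
#' (pre-anonymization) snapshot, normalized to probabilities. Derived
#' conditional rates (intensive care given hospitalization, ventilation given
#' intensive care, referral share among surviving inpatients, missingness
#' overlays) are computed from the same counts. The outcome model
#' (`effect_spec`) generates inpatient death in the SUEP and HAP cohorts from
#' a logistic model in the age>59 indicator and male gender; the default
#' adjusted odds ratio for age>59 is 2.5 with a male odds ratio of 1.3 and a
#' baseline inpatient fatality of 4.5%, which places the cohort-level
#' fatality near the reference snapshot.
#'
#' @param n_total Number of records to generate.
#' @param seed Integer seed; all generator randomness derives from it.
#' @param effect_spec Optional replacement outcome model, a list with
#'   `exposure` (list: `variable`, `levels`), `covariate` (list: `variable`,
#'   `levels`), and `beta` (numeric: `intercept`, `exposure`, `covariate`,
#'   on the log-odds scale).
#' @return A generator configuration list.
#' @export
default_generator_config <- function(n_total = 4562L, seed = 1L,
                                     effect_spec = NULL) {
  ref <- reference_marginals("original")
  sizes <- reference_cohort_sizes("original")
  cohorts <- names(sizes)
  prob <- function(co, variable) {
    v <- ref[ref$cohort == co & ref$variable == variable, ]
    stats::setNames(v$count / sum(v$count), v$category)
  }
  cnt <- function(co, variable, category) {
    v <- ref[ref$cohort == co & ref$variable == variable, ]
    sum(v$count[v$category %in% category])
  }
  marginals <- lapply(cohorts, function(co) list(
    age_group = prob(co, "age_group"),
    gender = prob(co, "gender"),
    quarter_year = prob(co, "quarter_year"),
    most_severe_phase = prob(co, "most_severe_phase"),
    any_symptom_3m = prob(co, "any_symptom_3m"),
    ability_to_work_3m = prob(co, "ability_to_work_3m")))
  names(marginals) <- cohorts
  rates <- lapply(cohorts, function(co) {
    hosp_yes <- cnt(co, "hospitalization", "yes")
    icu_yes <- cnt(co, "intensive_care", "yes")
    disch <- cnt(co, "patient_status_end_acute", "discharged")
    refl <- cnt(co, "patient_status_end_acute", "referral/transfer")
    n <- sizes[[co]]
    list(
      icu_given_hosp = if (hosp_yes > 0) icu_yes / hosp_yes else 0,
      vent_given_icu = if (icu_yes > 0)
        cnt(co, "invasive_ventilation", "yes") / icu_yes else 0,
      referral_share = if (disch + refl > 0) refl / (disch + refl) else 0,
      status_missing = cnt(co, "patient_status_end_acute", MISSING) / n,
      vent_missing = cnt(co, "invasive_ventilation", MISSING) / n,
      followup_available = cnt(co, "followup_3m_available", "yes") / n)
  })
  names(rates) <- cohorts
  if (is.null(effect_spec))
    effect_spec <- list(
      outcome = "dead",
      exposure = list(variable = "age_group", levels = c("60-79", ">=80")),
      covariate = list(variable = "gender", levels = "male"),
      beta = c(intercept = stats::qlogis(0.045),
               exposure = log(2.5), covariate = log(1.3)))
  list(n_total = as.integer(n_total), seed = as.integer(seed),
       cohort_mix = sizes / sum(sizes),
       marginals = marginals, rates = rates, effect_spec = effect_spec)
}

#' Validate a generator configuration
#'
#' @param config A generator configuration list.
#' @return Character vector of violation descriptions; empty iff valid.
#' @export
validate_generator_config <- function(config) {
  v <- character()
  if (is.null(config$n_total) || config$n_total < 0)
    v <- c(v, "n_total must be a nonnegative count")
  mix <- config$cohort_mix
  if (!setequal(names(mix), c("SUEP", "POP", "HAP")))
    v <- c(v, "cohort_mix must cover exactly SUEP, POP, HAP")
  check_prob <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      v <<- c(v, paste0(what, ": probabilities must be nonnegative and sum to 1"))
  }
  check_prob(mix, "cohort_mix")
  for (co in names(config$marginals))
    for (vn in names(config$marginals[[co]]))
      check_prob(config$marginals[[co]][[vn]], paste(co, vn))
  b <- config$effect_spec$beta
  if (is.null(b) || !all(c("intercept", "exposure", "covariate") %in% names(b)))
    v <- c(v, "effect_spec$beta must name intercept, exposure, covariate")
  v
}

#' Generate a synthetic cohort dataset
#'
#' Fully reproducible from `config$seed`. See the package vignette for the
#' sampling scheme and which features of real registry data it does and does
#' not emulate.
#'
#' @param config A generator configuration, see
#'   [default_generator_config()].
#' @return A [cohort_dataset()] with `config$n_total` records.
#' @export
generate_cohort <- function(config = default_generator_config()) {
  problems <- validate_generator_config(config)
  if (length(problems) > 0)
    stop("invalid generator config:\n  ", paste(problems, collapse = "\n  "))
  n <- config$n_total
  empty <- function() {
    cols <- c(PRIVATE_COLUMNS, puf_variables())
    df <- as.data.frame(stats::setNames(rep(list(character()), length(cols)),
                                        cols), stringsAsFactors = FALSE)
    df$diagnosis_date <- as.Date(character())
    cohort_dataset(df)
  }
  if (n == 0) return(empty())
  set.seed(config$seed)
  cohort <- sample(names(config$cohort_mix), n, replace = TRUE,
                   prob = config$cohort_mix)
  samp <- function(marg, idx) {
    out <- character(length(idx))
    for (co in unique(cohort[idx])) {
      sel <- cohort[idx] == co
      p <- config$marginals[[co]][[marg]]
      out[sel] <- sample(names(p), sum(sel), replace = TRUE, prob = p)
    }
    out
  }
  all_idx <- seq_len(n)
  qy <- samp("quarter_year", all_idx)
  diagnosis_date <- as.Date(rep(NA, n))
  dated <- qy != MISSING
  if (any(dated)) {
    qb <- quarter_bounds(qy[dated])
    diagnosis_date[dated] <- qb$start +
      floor(stats::runif(sum(dated)) * qb$ndays)
  }
  quarter <- ifelse(dated, substr(qy, 1, 2), MISSING)
  year <- ifelse(dated, substr(qy, 4, 7), MISSING)
  age_group <- samp("age_group", all_idx)
  gender <- samp("gender", all_idx)
  sev <- samp("most_severe_phase", all_idx)
  flags <- severity_to_flags(sev)
  hospitalization <- ifelse(sev == MISSING, MISSING,
                            ifelse(sev == "mild", "no", "yes"))
  rate <- function(name) vapply(cohort, function(co)
    config$rates[[co]][[name]], numeric(1), USE.NAMES = FALSE)
  u_icu <- stats::runif(n)
  intensive_care <- ifelse(hospitalization == "yes" &
                             u_icu < rate("icu_given_hosp"), "yes", "no")
  u_vent <- stats::runif(n)
  invasive_ventilation <- ifelse(intensive_care == "yes" &
                                   u_vent < rate("vent_given_icu"),
                                 "yes", "no")
  u_ventmiss <- stats::runif(n)
  invasive_ventilation[u_ventmiss < rate("vent_missing")] <- MISSING
  # patient status: ambulatory cases end ambulant; inpatient death follows
  # the logistic outcome model (never in POP: survivors only by design)
  es <- config$effect_spec
  indicator <- function(spec) {
    vals <- switch(spec$variable, age_group = age_group, gender = gender,
                   stop("effect_spec variable must be age_group or gender"))
    as.numeric(vals %in% spec$levels)
  }
  lp <- es$beta[["intercept"]] + es$beta[["exposure"]] * indicator(es$exposure) +
    es$beta[["covariate"]] * indicator(es$covariate)
  p_dead <- stats::plogis(lp)
  u_dead <- stats::runif(n)
  u_ref <- stats::runif(n)
  status <- rep(MISSING, n)
  status[hospitalization == "no"] <- "ambulant"
  inpat <- hospitalization == "yes"
  dead <- inpat & cohort != "POP" & u_dead < p_dead
  status[dead] <- "dead"
  surv <- inpat & !dead
  status[surv] <- ifelse(u_ref[surv] < rate("referral_share")[surv],
                         "referral/transfer", "discharged")
  u_statmiss <- stats::runif(n)
  status[u_statmiss < rate("status_missing")] <- MISSING
  u_fa <- stats::runif(n)
  followup <- ifelse(cohort == "POP" | u_fa < rate("followup_available"),
                     "yes", "no/not yet")
  avail <- followup == "yes"
  any_symptom <- rep(NOT_APPLICABLE, n)
  ability <- rep(NOT_APPLICABLE, n)
  if (any(avail)) {
    any_symptom[avail] <- samp("any_symptom_3m", which(avail))
    ability[avail] <- samp("ability_to_work_3m", which(avail))
  }
  df <- data.frame(
    case_id = sprintf("case%06d", seq_len(n)),
    diagnosis_date = diagnosis_date,
    age_group = age_group, gender = gender,
    quarter_first_diagnosis = quarter, year_first_diagnosis = year,
    cohort = cohort,
    mild_phase = flags$mild_phase, moderate_phase = flags$moderate_phase,
    severe_phase = flags$severe_phase,
    patient_status_end_acute = status, hospitalization = hospitalization,
    intensive_care = intensive_care,
    invasive_ventilation = invasive_ventilation,
    followup_3m_available = followup,
    ability_to_work_3m = ability, any_symptom_3m = any_symptom,
    stringsAsFactors = FALSE)
  cohort_dataset(enforce_structural_rules(df))
}

#' Enforce the generator's structural rules
#'
#' Applied after sampling so the constraints hold with probability 1:
#' HAP records are hospitalized; POP records survive the acute phase and all
#' have a follow-up; follow-up sub-variables are `"n/a"` exactly for cases
#' without follow-up.
#'
#' @param df Data frame of case records (columns as in the schema).
#' @return The data frame with rules applied.
#' @export
enforce_structural_rules <- function(df) {
  hap <- df$cohort == "HAP"
  df$hospitalization[hap] <- "yes"
  # keep mild <-> never-hospitalized exact: a (default-impossible) mild HAP
  # draw is promoted to a moderate course
  promote <- hap & df$mild_phase == "yes"
  df$mild_phase[promote] <- "no"
  df$moderate_phase[promote] <- "yes"
  pop <- df$cohort == "POP"
  df$patient_status_end_acute[pop & df$patient_status_end_acute == "dead"] <-
    "discharged"
  df$followup_3m_available[pop] <- "yes"
  no_fu <- df$followup_3m_available == "no/not yet"
  df$ability_to_work_3m[no_fu] <- NOT_APPLICABLE
  df$any_symptom_3m[no_fu] <- NOT_APPLICABLE
  df$ability_to_work_3m[!no_fu & df$ability_to_work_3m == NOT_APPLICABLE] <-
    MISSING
  df$any_symptom_3m[!no_fu & df$any_symptom_3m == NOT_APPLICABLE] <- MISSING
  df
}

#' Nested growth prefixes of a dataset
#'
#' Orders records by diagnosis date (missing dates last), ties broken by
#' `case_id`, and returns nested prefixes of sizes `step`, `2*step`, ...;
#' the final prefix is always the full dataset. This emulates a registry
#' accruing cases over time for continuous-release simulations.
#'
#' @param dataset A [cohort_dataset()].
#' @param step Positive prefix increment.
#' @return List of [cohort_dataset()] prefixes, each a superset of the
#'   previous.
#' @export
growth_prefixes <- function(dataset, step) {
  stopifnot(step >= 1)
  n <- nrow(dataset)
  ord <- order(is.na(dataset$diagnosis_date), dataset$diagnosis_date,
               dataset$case_id)
  sorted <- dataset[ord, , drop = FALSE]
  sizes <- unique(c(seq(step, n, by = step), n))
  lapply(sizes, function(s) {
    d <- sorted[seq_len(s), , drop = FALSE]
    rownames(d) <- NULL
    class(d) <- c("cohort_dataset", "data.frame")
    d
  })
}
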