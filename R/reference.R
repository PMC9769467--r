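# Packaged reference marginals: published per-cohort category counts for the
# three-cohort COVID-19 registry snapshot (original and anonymized release).
# They parameterize the default synthetic generator and support worked
# descriptive checks. Counts for the two follow-up sub-variables are
# conditional on follow-up availability; "quarter_year" is the joint
# quarter-by-year distribution; "most_severe_phase" is the collapsed WHO
# Clinical Progression Scale category from which the three released phase
# flags derive.

#' Reference per-cohort category counts
#'
#' @param which `"original"` (pre-anonymization snapshot) or `"anonymized"`
#'   (released PUF).
#' @return Data frame with columns `cohort`, `variable`, `category`, `count`.
#' @export
reference_marginals <- function(which = c("original", "anonymized")) {
  which <- match.arg(which)
  path <- system.file("extdata", "reference_marginals.csv",
                      package = "pufanon", mustWork = TRUE)
  ref <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  ref[ref$dataset == which, c("cohort", "variable", "category", "count")]
}

#' Reference cohort sizes
#' @param which `"original"` or `"anonymized"`.
#' @return Named integer vector of per-cohort record counts.
#' @export
reference_cohort_sizes <- function(which = c("original", "anonymized")) {
  which <- match.arg(which)
  ref <- reference_marginals(which)
  age <- ref[ref$variable == "age_group", ]
  tapply(age$count, age$cohort, sum)[c("SUEP", "POP", "HAP")]
}

# Expand one cohort's reference counts into per-record column values.
# Variables are realized marginally (records within a cohort are filled in
# blocks), which reproduces every univariate count exactly; joint structure
# beyond the encoded derivations (phase flags, follow-up applicability) is
# not meaningful. A variable whose counts fall short of the cohort size is
# padded with its modal known category.
expand_reference_cohort <- function(ref, cohort, n) {
  sub <- ref[ref$cohort == cohort, ]
  draw <- function(variable, pad_with = NULL) {
    v <- sub[sub$variable == variable, ]
    vals <- rep(v$category, v$count)
    if (length(vals) > n) stop("reference counts exceed cohort size for ",
                               variable)
    if (length(vals) < n) {
      if (is.null(pad_with)) {
        known <- v[!v$category %in% c(MISSING, NOT_APPLICABLE), ]
        pad_with <- known$category[which.max(known$count)]
      }
      vals <- c(vals, rep(pad_with, n - length(vals)))
    }
    vals
  }
  qy <- draw("quarter_year")
  quarter <- ifelse(qy == MISSING, MISSING, substr(qy, 1, 2))
  year <- ifelse(qy == MISSING, MISSING, substr(qy, 4, 7))
  sev <- draw("most_severe_phase")
  flags <- severity_to_flags(sev)
  fa <- draw("followup_3m_available")
  n_avail <- sum(fa == "yes")
  # follow-up block: order records so the first n_avail are available, and
  # fill the conditional sub-variable counts into that block
  fa <- c(rep("yes", n_avail), rep("no/not yet", n - n_avail))
  cond_draw <- function(variable) {
    v <- sub[sub$variable == variable, ]
    vals <- rep(v$category, v$count)
    if (length(vals) != n_avail)
      stop("conditional counts for ", variable,
           " do not match follow-up availability")
    c(vals, rep(NOT_APPLICABLE, n - n_avail))
  }
  data.frame(
    cohort = rep(cohort, n),
    age_group = draw("age_group"),
    gender = draw("gender"),
    quarter_first_diagnosis = quarter,
    year_first_diagnosis = year,
    mild_phase = flags$mild_phase,
    moderate_phase = flags$moderate_phase,
    severe_phase = flags$severe_phase,
    patient_status_end_acute = draw("patient_status_end_acute"),
    hospitalization = draw("hospitalization"),
    intensive_care = draw("intensive_care"),
    invasive_ventilation = draw("invasive_ventilation"),
    followup_3m_available = fa,
    ability_to_work_3m = cond_draw("ability_to_work_3m"),
    any_symptom_3m = cond_draw("any_symptom_3m"),
    stringsAsFactors = FALSE)
}

#' Dataset realizing the reference marginals
#'
#' Builds a [cohort_dataset()] whose per-cohort univariate counts reproduce
#' the packaged reference marginals exactly. Variables are filled marginally:
#' cross-variable structure (beyond phase-flag derivation and follow-up
#' applicability) is arbitrary, so the result supports descriptive,
#' frequency-based checks only, not association analyses. Diagnosis dates
#' are absent (quarter/year are the released granularity).
#'
#' @param which `"original"` or `"anonymized"`.
#' @return A [cohort_dataset()].
#' @export
reference_dataset <- function(which = c("original", "anonymized")) {
  which <- match.arg(which)
  ref <- reference_marginals(which)
  sizes <- reference_cohort_sizes(which)
  parts <- lapply(names(sizes), function(co)
    expand_reference_cohort(ref, co, sizes[[co]]))
  df <- do.call(rbind, parts)
  df$case_id <- sprintf("%s%05d", tolower(substr(which, 1, 4)),
                        seq_len(nrow(df)))
  df$diagnosis_date <- as.Date(NA)
  cohort_dataset(df)
}
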