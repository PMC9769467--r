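# Statistical-bias evaluation harness: quantifies what class-level
# suppression does to descriptive distributions, case fatality rates, and
# adjusted logistic effect estimates, both at a fixed snapshot and along a
# growing (continuous-release) data stream.

#' Indicator condition on a categorical variable
#'
#' Describes a binary condition "variable takes one of these levels", used
#' for regression outcomes and exposures (e.g. age over 59 is
#' `level_condition("age_group", c("60-79", ">=80"))`).
#'
#' @param variable Schema variable name.
#' @param levels Category labels counting as `TRUE`.
#' @return A condition list.
#' @export
level_condition <- function(variable, levels) {
  schema <- puf_schema()
  if (!variable %in% names(schema)) stop("unknown variable: ", variable)
  bad <- setdiff(levels, schema[[variable]]$categories)
  if (length(bad) > 0)
    stop("unknown categories for ", variable, ": ",
         paste(bad, collapse = ", "))
  list(variable = variable, levels = levels)
}

# Apply a subpopulation filter: a named list variable -> allowed levels.
apply_filter <- function(dataset, filter) {
  if (is.null(filter) || length(filter) == 0) return(dataset)
  keep <- rep(TRUE, nrow(dataset))
  for (v in names(filter)) keep <- keep & dataset[[v]] %in% filter[[v]]
  dataset[keep, , drop = FALSE]
}

# Complete-case restriction for a set of variables: records whose value is
# an explicit missing label (or not-applicable) are excluded.
complete_cases <- function(dataset, variables) {
  keep <- rep(TRUE, nrow(dataset))
  for (v in variables)
    keep <- keep & !(dataset[[v]] %in% c(MISSING, NOT_APPLICABLE))
  dataset[keep, , drop = FALSE]
}

#' Chi-squared comparison of a variable before and after anonymization
#'
#' Pearson chi-squared homogeneity test (no continuity correction) on the
#' two per-category count vectors. By default the explicit missing and
#' not-applicable categories are excluded — the tested distributions are the
#' substantive categories — and categories with zero count in both datasets
#' are dropped; both choices change the degrees of freedom, which equal the
#' number of retained categories minus one.
#'
#' @param original,anonymized [cohort_dataset()]s sharing the schema.
#' @param variable Schema variable to compare.
#' @param include_missing Keep missing/not-applicable categories?
#' @return List with `variable`, `categories`, `counts_original`,
#'   `counts_anonymized`, `chi2_statistic`, `degrees_of_freedom`, `p_value`,
#'   and `small_expected_counts` (flag: some expected cell below 5, where
#'   the chi-squared approximation is shaky).
#' @export
compare_distributions <- function(original, anonymized, variable,
                                  include_missing = FALSE) {
  schema <- puf_schema()
  if (!variable %in% names(schema)) stop("unknown variable: ", variable)
  cats <- schema[[variable]]$categories
  if (!include_missing) cats <- setdiff(cats, c(MISSING, NOT_APPLICABLE))
  co <- as.integer(table(factor(original[[variable]], levels = cats)))
  ca <- as.integer(table(factor(anonymized[[variable]], levels = cats)))
  keep <- co + ca > 0
  cats <- cats[keep]; co <- co[keep]; ca <- ca[keep]
  if (length(cats) < 2)
    stop("fewer than 2 retained categories for ", variable,
         ": chi-squared test is degenerate")
  test <- suppressWarnings(stats::chisq.test(rbind(co, ca), correct = FALSE))
  list(variable = variable, categories = cats,
       counts_original = co, counts_anonymized = ca,
       chi2_statistic = unname(test$statistic),
       degrees_of_freedom = unname(test$parameter),
       p_value = unname(test$p.value),
       small_expected_counts = any(test$expected < 5))
}

#' Case fatality rate of selected cohorts
#'
#' Deaths over cases with known patient status at the end of the acute
#' phase, within the selected sub-cohorts.
#'
#' @param dataset A [cohort_dataset()].
#' @param cohorts Nonempty set of cohort labels.
#' @return List with `cfr` (proportion), `numerator`, `denominator`.
#' @export
case_fatality_rate <- function(dataset, cohorts = c("SUEP", "HAP")) {
  if (length(cohorts) == 0) stop("cohort set must not be empty")
  sub <- dataset[dataset$cohort %in% cohorts, , drop = FALSE]
  status <- sub$patient_status_end_acute
  denominator <- sum(status != MISSING)
  if (denominator == 0)
    stop("case fatality rate undefined: no records with known patient status")
  numerator <- sum(status == "dead")
  list(cfr = numerator / denominator,
       numerator = numerator, denominator = denominator)
}

# Run a chained incremental release along growth prefixes; returns the list
# of prefixes and the per-prefix cumulative releases.
release_stream <- function(dataset, config, step) {
  prefixes <- growth_prefixes(dataset, step)
  releases <- vector("list", length(prefixes))
  prev <- NULL
  for (i in seq_along(prefixes)) {
    prev <- incremental_release(prev, prefixes[[i]], config)
    releases[[i]] <- prev
  }
  list(prefixes = prefixes, releases = releases)
}

#' Fraction of cases published along a growing dataset
#'
#' Simulates a continuous release over the diagnosis-date-ordered growth
#' prefixes and records, per prefix, how many records the cumulative release
#' publishes, overall and per sub-cohort.
#'
#' @param dataset A [cohort_dataset()].
#' @param config A [privacy_config()].
#' @param step Prefix increment.
#' @return Data frame with columns `original_size`, `released_count`,
#'   `fraction`, and per-cohort `released_<cohort>` / `fraction_<cohort>`.
#' @export
fraction_published_curve <- function(dataset, config = privacy_config(),
                                     step = 250L) {
  st <- release_stream(dataset, config, step)
  cohorts <- puf_schema()$cohort$categories
  rows <- lapply(seq_along(st$prefixes), function(i) {
    pre <- st$prefixes[[i]]
    rel <- released_data(pre, st$releases[[i]])
    row <- data.frame(original_size = nrow(pre),
                      released_count = nrow(rel),
                      fraction = nrow(rel) / nrow(pre))
    for (co in cohorts) {
      n_co <- sum(pre$cohort == co)
      r_co <- sum(rel$cohort == co)
      row[[paste0("released_", co)]] <- r_co
      row[[paste0("fraction_", co)]] <- if (n_co > 0) r_co / n_co else NA_real_
    }
    row
  })
  do.call(rbind, rows)
}

#' Case-fatality-rate bias along a growing dataset
#'
#' For each growth prefix, computes the CFR on the prefix and on its
#' cumulative anonymized release; bias is anonymized minus original. Sizes
#' where the release has no record with known status are flagged
#' (`valid = FALSE`) and excluded from the summary.
#'
#' @param dataset A [cohort_dataset()].
#' @param config A [privacy_config()].
#' @param cohorts Cohorts entering the CFR.
#' @param step Prefix increment.
#' @return List with `points` (data frame: `original_size`, `cfr_original`,
#'   `cfr_anonymized`, `bias`, `valid`) and `summary` (median and IQR of
#'   `|bias|` over valid sizes).
#' @export
cfr_bias_curve <- function(dataset, config = privacy_config(),
                           cohorts = c("SUEP", "HAP"), step = 250L) {
  st <- release_stream(dataset, config, step)
  rows <- lapply(seq_along(st$prefixes), function(i) {
    pre <- st$prefixes[[i]]
    rel <- released_data(pre, st$releases[[i]])
    orig <- tryCatch(case_fatality_rate(pre, cohorts), error = function(e) NULL)
    anon <- tryCatch(case_fatality_rate(rel, cohorts), error = function(e) NULL)
    valid <- !is.null(orig) && !is.null(anon)
    data.frame(original_size = nrow(pre),
               cfr_original = if (!is.null(orig)) orig$cfr else NA_real_,
               cfr_anonymized = if (!is.null(anon)) anon$cfr else NA_real_,
               bias = if (valid) anon$cfr - orig$cfr else NA_real_,
               valid = valid)
  })
  points <- do.call(rbind, rows)
  ab <- abs(points$bias[points$valid])
  list(points = points,
       summary = list(
         n_valid = length(ab),
         median_abs_bias = if (length(ab)) stats::median(ab) else NA_real_,
         iqr_abs_bias = if (length(ab))
           unname(stats::quantile(ab, c(0.25, 0.75))) else c(NA_real_, NA_real_)))
}

#' Adjusted odds ratio from a logistic model
#'
#' Maximum-likelihood logistic regression of a binary outcome condition on a
#' binary exposure condition plus categorical covariates entered as
#' indicator dummies (reference levels: age group `"18-39"`, gender
#' `"female"`; first schema category otherwise). Cases with missing or
#' not-applicable values in any involved variable are excluded
#' (complete-case analysis). The confidence interval is the 95% Wald
#' interval on the log-odds scale. Fits showing signs of separation or
#' non-convergence are returned with `flagged = TRUE`, never silently
#' altered.
#'
#' @param dataset A [cohort_dataset()].
#' @param outcome,exposure [level_condition()]s.
#' @param covariates Character vector of adjustment variables (possibly
#'   empty). Must not include the exposure variable.
#' @param filter Optional named list variable -> allowed levels restricting
#'   the subpopulation before fitting.
#' @return List with `odds_ratio`, `ci_low`, `ci_high`, `n_used`, `flagged`,
#'   and `model` (descriptor).
#' @export
adjusted_or <- function(dataset, outcome, exposure,
                        covariates = c("age_group", "gender"),
                        filter = NULL) {
  if (exposure$variable %in% covariates)
    stop("exposure variable must not also be a covariate")
  involved <- unique(c(outcome$variable, exposure$variable, covariates))
  d <- apply_filter(dataset, filter)
  d <- complete_cases(d, involved)
  n <- nrow(d)
  y <- as.integer(d[[outcome$variable]] %in% outcome$levels)
  x <- as.integer(d[[exposure$variable]] %in% exposure$levels)
  if (length(unique(y)) < 2)
    stop("degenerate fit: outcome '", outcome$variable,
         "' has a single level after filtering")
  if (length(unique(x)) < 2)
    stop("degenerate fit: exposure '", exposure$variable,
         "' has a single level after filtering")
  refs <- c(age_group = "18-39", gender = "female")
  mf <- data.frame(.y = y, .x = x)
  for (v in covariates) {
    ref <- if (v %in% names(refs)) refs[[v]] else
      puf_schema()[[v]]$categories[1]
    lev <- unique(d[[v]])
    mf[[v]] <- factor(d[[v]], levels = c(ref, setdiff(lev, ref)))
  }
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = mf, family = stats::binomial()))
  co <- summary(fit)$coefficients
  est <- co[".x", "Estimate"]
  se <- co[".x", "Std. Error"]
  zcrit <- stats::qnorm(0.975)
  flagged <- !fit$converged || abs(est) > 15 || se > 15 ||
    any(fit$fitted.values < 1e-8) || any(fit$fitted.values > 1 - 1e-8)
  list(odds_ratio = exp(est),
       ci_low = exp(est - zcrit * se),
       ci_high = exp(est + zcrit * se),
       n_used = n, flagged = flagged,
       model = list(outcome = outcome, exposure = exposure,
                    covariates = covariates, filter = filter))
}

#' Odds-ratio comparison along a growing dataset
#'
#' Fits [adjusted_or()] on each growth prefix and on its cumulative
#' anonymized release, records the per-size absolute odds-ratio deviation,
#' and summarizes it. Sizes where either fit fails or is flagged are
#' recorded as gaps and excluded from the summary.
#'
#' @param dataset A [cohort_dataset()].
#' @param config A [privacy_config()].
#' @param outcome,exposure,covariates,filter As in [adjusted_or()].
#' @param step Prefix increment.
#' @return List with `points` (data frame: `original_size`, `n_original`,
#'   `or_original`, `ci_low_original`, `ci_high_original`, the `_anonymized`
#'   counterparts, `abs_deviation`, `valid`) and `summary`
#'   (`median_abs_dev`, `min_abs_dev`, `max_abs_dev` over valid sizes).
#' @export
or_comparison_curve <- function(dataset, config = privacy_config(),
                                outcome, exposure,
                                covariates = c("gender"),
                                filter = NULL, step = 250L) {
  st <- release_stream(dataset, config, step)
  fit_safe <- function(d) {
    tryCatch(adjusted_or(d, outcome, exposure, covariates, filter),
             error = function(e) NULL)
  }
  rows <- lapply(seq_along(st$prefixes), function(i) {
    pre <- st$prefixes[[i]]
    rel <- released_data(pre, st$releases[[i]])
    fo <- fit_safe(pre); fa <- fit_safe(rel)
    ok <- function(f) !is.null(f) && !f$flagged
    valid <- ok(fo) && ok(fa)
    g <- function(f, what) if (!is.null(f)) f[[what]] else NA_real_
    data.frame(
      original_size = nrow(pre),
      n_original = g(fo, "n_used"), or_original = g(fo, "odds_ratio"),
      ci_low_original = g(fo, "ci_low"), ci_high_original = g(fo, "ci_high"),
      n_anonymized = g(fa, "n_used"), or_anonymized = g(fa, "odds_ratio"),
      ci_low_anonymized = g(fa, "ci_low"),
      ci_high_anonymized = g(fa, "ci_high"),
      abs_deviation = if (valid)
        abs(fo$odds_ratio - fa$odds_ratio) else NA_real_,
      valid = valid)
  })
  points <- do.call(rbind, rows)
  dev <- points$abs_deviation[points$valid]
  list(points = points,
       summary = list(
         n_valid = length(dev),
         median_abs_dev = if (length(dev)) stats::median(dev) else NA_real_,
         min_abs_dev = if (length(dev)) min(dev) else NA_real_,
         max_abs_dev = if (length(dev)) max(dev) else NA_real_))
}
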