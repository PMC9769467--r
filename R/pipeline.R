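# End-to-end orchestration: generate or load -> triage -> anonymize
# (incrementally over growth prefixes) -> risk profiles -> bias evaluation,
# with a single seed from which every stochastic stage derives its own
# sub-seed, so stages rerun in isolation reproducibly.

sub_seed <- function(seed, stage) {
  (as.integer(seed) * 7919L + sum(utf8ToInt(stage))) %% 2147483647L
}

#' Pipeline configuration
#'
#' Exactly one of `generator` / `input_path` provides the original dataset.
#'
#' @param generator A generator configuration
#'   ([default_generator_config()]), or `NULL` when reading from a file.
#' @param input_path Path to a private-mode PUF CSV, or `NULL`.
#' @param ratings Variable ratings data frame for [triage()].
#' @param implicit_overrides Implicitly protected variables.
#' @param k,t Privacy parameters.
#' @param step Growth-prefix increment for the curves.
#' @param cfr_cohorts Cohorts entering the case-fatality-rate analysis.
#' @param seed Master seed.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(generator = default_generator_config(),
                            input_path = NULL,
                            ratings = default_variable_ratings(),
                            implicit_overrides = default_implicit_overrides(),
                            k = 11L, t = 0.5, step = 250L,
                            cfr_cohorts = c("SUEP", "HAP"),
                            seed = 1L, out_dir = NULL) {
  if (is.null(generator) == is.null(input_path))
    stop("exactly one of generator settings or input path must be given")
  structure(list(generator = generator, input_path = input_path,
                 ratings = ratings, implicit_overrides = implicit_overrides,
                 k = k, t = t, step = step, cfr_cohorts = cfr_cohorts,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full anonymization and bias-evaluation pipeline
#'
#' @param config A [pipeline_config()].
#' @return A bias report: list with the original and released datasets,
#'   triage result, final release (audit), risk profiles before and after,
#'   the rendered cohort table, per-variable distribution tests, the
#'   fraction-published and CFR-bias curves, and the default odds-ratio
#'   comparison.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$generator)) {
    gen <- config$generator
    gen$seed <- sub_seed(config$seed, "generate")
    original <- generate_cohort(gen)
  } else {
    original <- read_puf_csv(config$input_path)
  }
  problems <- validate_dataset(original)
  if (nrow(problems) > 0)
    stop("input dataset fails validation (", nrow(problems), " violations)")
  tri <- triage(config$ratings, config$implicit_overrides)
  pconf <- privacy_config(k = config$k, t = config$t,
                          key_variables = tri$key_variables,
                          sensitive_variables = tri$sensitive_variables)
  st <- release_stream(original, pconf, config$step)
  release <- st$releases[[length(st$releases)]]
  released <- released_data(original, release)
  risk_before <- reidentification_risks(original, tri$key_variables)
  risk_after <- if (nrow(released) > 0)
    reidentification_risks(released, tri$key_variables) else NULL
  tests <- lapply(setdiff(puf_variables(), "cohort"), function(v)
    tryCatch(compare_distributions(original, released, v),
             error = function(e) NULL))
  tests <- Filter(Negate(is.null), tests)
  fraction <- fraction_published_curve(original, pconf, config$step)
  cfr <- cfr_bias_curve(original, pconf, config$cfr_cohorts, config$step)
  orcmp <- or_comparison_curve(
    original, pconf,
    outcome = level_condition("patient_status_end_acute", "dead"),
    exposure = level_condition("age_group", c("60-79", ">=80")),
    covariates = "gender",
    filter = list(cohort = config$cfr_cohorts, hospitalization = "yes"),
    step = config$step)
  report <- list(
    sizes = list(original = nrow(original), released = nrow(released)),
    triage = tri, privacy = pconf,
    release = release,
    risk_before = risk_before, risk_after = risk_after,
    cohort_table = render_cohort_table(original, released),
    distribution_tests = tests,
    fraction_curve = fraction, cfr_curve = cfr, or_comparison = orcmp,
    original = original, released = released)
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_puf_csv(report$released, file.path(out_dir, "puf.csv"))
  write_puf_csv(report$original, file.path(out_dir, "original_private.csv"),
                include_private = TRUE)
  utils::write.csv(report$cohort_table,
                   file.path(out_dir, "cohort_table.csv"), row.names = FALSE)
  utils::write.csv(report$fraction_curve,
                   file.path(out_dir, "fraction_published.csv"),
                   row.names = FALSE)
  utils::write.csv(report$cfr_curve$points,
                   file.path(out_dir, "cfr_bias.csv"), row.names = FALSE)
  utils::write.csv(report$or_comparison$points,
                   file.path(out_dir, "or_comparison.csv"), row.names = FALSE)
  utils::write.csv(report$release$class_decisions,
                   file.path(out_dir, "release_audit.csv"), row.names = FALSE)
  tests <- lapply(report$distribution_tests, function(x)
    data.frame(variable = x$variable, chi2 = x$chi2_statistic,
               df = x$degrees_of_freedom, p_value = x$p_value))
  utils::write.csv(do.call(rbind, tests),
                   file.path(out_dir, "distribution_tests.csv"),
                   row.names = FALSE)
  risks <- list(before = report$risk_before, after = report$risk_after)
  jsonlite::write_json(risks, file.path(out_dir, "risk.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Render a per-cohort descriptive table
#'
#' For every variable and category: count and column percentage per cohort,
#' in the original and the anonymized dataset. The percentage base is the
#' cohort's dataset size, excluding not-applicable records for the follow-up
#' sub-variables (which are reported conditionally on follow-up
#' availability); percentages use one decimal, and an empty base renders as
#' an em dash.
#'
#' @param original,anonymized [cohort_dataset()]s sharing the schema.
#' @return Data frame with columns `variable`, `category`, `cohort`,
#'   `original`, `anonymized` (formatted "count (pct%)" cells).
#' @export
render_cohort_table <- function(original, anonymized) {
  schema <- puf_schema()
  cohorts <- schema$cohort$categories
  cell <- function(dataset, variable, category, co) {
    vals <- dataset[[variable]][dataset$cohort == co]
    base <- sum(vals != NOT_APPLICABLE)
    cnt <- sum(vals == category)
    if (base == 0) sprintf("%d (—)", cnt)
    else sprintf("%d (%.1f%%)", cnt, 100 * cnt / base)
  }
  rows <- list()
  for (def in schema) {
    if (def$name == "cohort") next
    for (cat in setdiff(def$categories, NOT_APPLICABLE)) {
      for (co in cohorts) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = def$name, category = cat, cohort = co,
          original = cell(original, def$name, cat, co),
          anonymized = cell(anonymized, def$name, cat, co),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
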