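#!/usr/bin/env Rscript
# Quantify the statistical bias introduced by suppression: chi-squared
# comparisons of variable distributions before vs after anonymization, the
# fraction of cases published and the case-fatality-rate bias along the
# growing dataset, and adjusted odds-ratio comparisons (inpatient death by
# age over 59, adjusted for gender, SUEP + HAP).

suppressPackageStartupMessages(library(pufanon))

original <- read_puf_csv("results/cohort_private.csv")
puf <- read_puf_csv("results/puf.csv")
config <- privacy_config(k = 11, t = 0.5)

## distribution comparisons
tests <- list()
for (v in setdiff(puf_variables(), "cohort")) {
  tests[[v]] <- tryCatch(compare_distributions(original, puf, v),
                         error = function(e) NULL)
}
tests <- Filter(Negate(is.null), tests)
tab <- do.call(rbind, lapply(tests, function(x)
  data.frame(variable = x$variable, chi2 = x$chi2_statistic,
             df = x$degrees_of_freedom, p_value = x$p_value,
             small_expected = x$small_expected_counts)))
write.csv(tab, "results/distribution_tests.csv", row.names = FALSE)
cat("distribution comparisons (P < 0.05 marked *):\n")
for (i in seq_len(nrow(tab)))
  cat(sprintf("  %-26s chi2 = %7.2f  df = %d  P %s%s\n", tab$variable[i],
              tab$chi2[i], tab$df[i],
              ifelse(tab$p_value[i] < 0.001, "< 0.001",
                     sprintf("= %.3f", tab$p_value[i])),
              ifelse(tab$p_value[i] < 0.05, " *", "")))

## fraction published and CFR bias along the stream
fc <- fraction_published_curve(original, config, step = 250)
write.csv(fc, "results/fraction_published.csv", row.names = FALSE)
cat(sprintf("\nfraction published: %.1f%% at n = %d, %.1f%% at n = %d\n",
            100 * fc$fraction[1], fc$original_size[1],
            100 * fc$fraction[nrow(fc)], fc$original_size[nrow(fc)]))

cc <- cfr_bias_curve(original, config, c("SUEP", "HAP"), step = 250)
write.csv(cc$points, "results/cfr_bias.csv", row.names = FALSE)
cat(sprintf("CFR |bias| median %.4f (IQR %.4f-%.4f) over %d sizes\n",
            cc$summary$median_abs_bias, cc$summary$iqr_abs_bias[1],
            cc$summary$iqr_abs_bias[2], cc$summary$n_valid))

## adjusted odds ratios before vs after
cmp <- or_comparison_curve(
  original, config,
  outcome = level_condition("patient_status_end_acute", "dead"),
  exposure = level_condition("age_group", c("60-79", ">=80")),
  covariates = "gender",
  filter = list(cohort = c("SUEP", "HAP"), hospitalization = "yes"),
  step = 250)
write.csv(cmp$points, "results/or_comparison.csv", row.names = FALSE)
last <- cmp$points[nrow(cmp$points), ]
cat(sprintf("\ninpatient death ~ age>59 + gender (SUEP+HAP), full data:\n"))
cat(sprintf("  original:   OR %.2f (95%% CI %.2f-%.2f, n = %d)\n",
            last$or_original, last$ci_low_original, last$ci_high_original,
            last$n_original))
cat(sprintf("  anonymized: OR %.2f (95%% CI %.2f-%.2f, n = %d)\n",
            last$or_anonymized, last$ci_low_anonymized,
            last$ci_high_anonymized, last$n_anonymized))
cat(sprintf("  |OR deviation|: median %.3f, min %.3f, max %.3f over %d sizes\n",
            cmp$summary$median_abs_dev, cmp$summary$min_abs_dev,
            cmp$summary$max_abs_dev, cmp$summary$n_valid))
cat("wrote results/{distribution_tests,fraction_published,cfr_bias,or_comparison}.csv\n")
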