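# Prosecutor-model re-identification risk: an attacker who knows a target's
# key-variable values and knows the target is in the data picks the right
# record with probability 1/(equivalence-class size).

#' Re-identification risk profile of a dataset
#'
#' Per-record risk is the reciprocal of the record's key-variable
#' equivalence-class size. The profile reports the maximum (reciprocal of
#' the smallest class size), minimum (reciprocal of the largest), and the
#' average. The default average is record-weighted — the mean of per-record
#' risks, which equals `n_classes / n_records`; a class-weighted average
#' (mean of per-class risks) is available via `average`.
#'
#' @param dataset A nonempty [cohort_dataset()].
#' @param key_variables Quasi-identifiers; defaults to the triage keys.
#' @param average `"record"` (default) or `"class"` weighting.
#' @return List with `max_risk`, `avg_risk`, `min_risk` (proportions in
#'   (0, 1]), `n_records`, `n_classes`.
#' @export
reidentification_risks <- function(dataset,
                                   key_variables = triage()$key_variables,
                                   average = c("record", "class")) {
  average <- match.arg(average)
  if (nrow(dataset) == 0)
    stop("re-identification risk is undefined for an empty dataset")
  idx <- class_index(dataset, key_variables)
  sizes <- as.integer(table(idx))
  avg <- switch(average,
                record = length(sizes) / nrow(dataset),
                class = mean(1 / sizes))
  list(max_risk = 1 / min(sizes),
       avg_risk = avg,
       min_risk = 1 / max(sizes),
       n_records = nrow(dataset),
       n_classes = length(sizes))
}

#' Format a risk profile as percentages
#'
#' @param profile A profile from [reidentification_risks()].
#' @return Named character vector with risks as percentages, two decimals.
#' @export
format_risk_percent <- function(profile) {
  c(max_risk = sprintf("%.2f%%", 100 * profile$max_risk),
    avg_risk = sprintf("%.2f%%", 100 * profile$avg_risk),
    min_risk = sprintf("%.2f%%", 100 * profile$min_risk))
}
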