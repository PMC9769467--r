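# Fixture builders and independent brute-force oracles. The oracles use
# direct formulas and pairwise scans only — no package internals — so they
# stay independent of the code paths they check.

M <- "unknown/missing"

# A valid record template; override columns to build toy datasets.
toy_dataset <- function(n, ...) {
  if (n == 0) {
    d <- toy_dataset(1)
    return(cohort_dataset(d[0, , drop = FALSE]))
  }
  base <- data.frame(
    case_id = sprintf("t%04d", seq_len(n)),
    diagnosis_date = as.Date(NA),
    age_group = "40-59", gender = "female",
    quarter_first_diagnosis = "Q1", year_first_diagnosis = "2021",
    cohort = "SUEP",
    mild_phase = "no", moderate_phase = "yes", severe_phase = "no",
    patient_status_end_acute = "discharged", hospitalization = "yes",
    intensive_care = "no", invasive_ventilation = "no",
    followup_3m_available = "no/not yet",
    ability_to_work_3m = "n/a", any_symptom_3m = "n/a",
    stringsAsFactors = FALSE)
  over <- list(...)
  for (v in names(over)) base[[v]] <- over[[v]]
  cohort_dataset(base)
}

# Random valid dataset over a reduced key space, for oracle-equivalence runs.
random_toy_dataset <- function(n, seed) {
  set.seed(seed)
  toy_dataset(
    n,
    age_group = sample(c("18-39", "40-59", "60-79"), n, replace = TRUE),
    gender = sample(c("male", "female"), n, replace = TRUE),
    quarter_first_diagnosis = sample(c("Q1", "Q2"), n, replace = TRUE),
    patient_status_end_acute = sample(
      c("ambulant", "discharged", "dead", M), n, replace = TRUE,
      prob = c(0.3, 0.45, 0.15, 0.1)),
    intensive_care = sample(c("yes", "no"), n, replace = TRUE,
                            prob = c(0.25, 0.75)))
}

# --- brute-force oracles -------------------------------------------------

# Equivalence classes by pairwise key comparison; returns list of integer
# row-index vectors.
bf_classes <- function(df, keys) {
  n <- nrow(df)
  assigned <- rep(FALSE, n)
  classes <- list()
  for (i in seq_len(n)) {
    if (assigned[i]) next
    members <- i
    for (j in seq_len(n)) {
      if (j == i || assigned[j]) next
      same <- all(vapply(keys, function(k)
        identical(df[[k]][i], df[[k]][j]), logical(1)))
      if (same) members <- c(members, j)
    }
    assigned[members] <- TRUE
    classes[[length(classes) + 1L]] <- sort(members)
  }
  classes
}

# Pearson chi-squared by the direct sum((O-E)^2/E) formula on a 2 x c table.
bf_chisq <- function(counts1, counts2) {
  obs <- rbind(counts1, counts2)
  E <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  sum((obs - E)^2 / E)
}

# Total-variation / normalized earth-mover distances from raw value vectors.
bf_distance <- function(class_vals, ref_vals, categories, ordinal) {
  p <- sapply(categories, function(cc) mean(class_vals == cc))
  q <- sapply(categories, function(cc) mean(ref_vals == cc))
  if (!ordinal) return(sum(abs(p - q)) / 2)
  m <- length(categories)
  sum(abs(cumsum(p - q)[-m])) / (m - 1)
}

# Full class-decision oracle: released iff size >= k and every sensitive
# variable's distance to the whole-dataset distribution is <= t.
bf_release_decisions <- function(df, keys, sensitive, k, t,
                                 ordinal = rep(FALSE, length(sensitive))) {
  schema <- puf_schema()
  classes <- bf_classes(df, keys)
  lapply(classes, function(members) {
    if (length(members) < k) return(list(members = members,
                                         decision = "suppressed_k"))
    for (si in seq_along(sensitive)) {
      v <- sensitive[si]
      d <- bf_distance(df[[v]][members], df[[v]],
                       schema[[v]]$categories, ordinal[si])
      if (d > t) return(list(members = members, decision = "suppressed_t"))
    }
    list(members = members, decision = "released")
  })
}

# 2x2 cross-product odds ratio with Wald CI on the log scale.
bf_crossprod_or <- function(a, b, c, d) {
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, ci_low = exp(log(or) - qnorm(0.975) * se),
       ci_high = exp(log(or) + qnorm(0.975) * se))
}
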