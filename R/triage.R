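# Variable risk triage: expert scores on replicability (can the value be
# observed again about the same person), availability (how easily an attacker
# obtains it from external sources) and distinguishability (how much it
# singles a person out), each 1..3. Variables scoring above the key threshold
# become quasi-identifiers; the rest are sensitive unless an explicit
# override marks them as implicitly protected through perfect correlation
# with another sensitive variable.

KEY_SCORE_THRESHOLD <- 5L

#' Default variable risk ratings
#'
#' The packaged replicability/availability/distinguishability ratings for the
#' 15 PUF variables, as used for the default privacy configuration. Custom
#' ratings with the same columns can be supplied to [triage()].
#'
#' @return Data frame with columns `variable`, `replicability`,
#'   `availability`, `distinguishability`.
#' @export
default_variable_ratings <- function() {
  path <- system.file("extdata", "variable_ratings.csv", package = "pufanon",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Variables implicitly protected via perfect correlation
#'
#' Hospitalization is determined by the disease-phase flags (mild phase means
#' ambulatory care and vice versa), and follow-up availability is determined
#' by whether the follow-up sub-variables are applicable; both are therefore
#' protected through the explicitly protected sensitive variables rather than
#' listed in the t-closeness set.
#'
#' @return Character vector of variable names.
#' @export
default_implicit_overrides <- function() {
  c("followup_3m_available", "hospitalization")
}

#' Score a single variable rating
#'
#' Total risk score is the sum of the three axis scores; a variable is a key
#' variable (quasi-identifier) iff the total exceeds 5.
#'
#' @param replicability,availability,distinguishability Integer scores in 1..3.
#' @return List with `total` and `is_key`.
#' @export
score_variable <- function(replicability, availability, distinguishability) {
  s <- c(replicability, availability, distinguishability)
  if (length(s) != 3 || any(is.na(s)) || any(s != as.integer(s)) ||
      any(s < 1) || any(s > 3))
    stop("axis scores must be integers in 1..3")
  total <- as.integer(sum(s))
  list(total = total, is_key = total > KEY_SCORE_THRESHOLD)
}

#' Classify variables as key / sensitive / implicitly protected
#'
#' Applies [score_variable()] to every rating row and partitions the variable
#' set: key variables are those with total score > 5; among the remaining
#' (non-key) variables, those in `implicit_overrides` are classed as
#' implicitly protected and the rest as sensitive.
#'
#' @param ratings Data frame as returned by [default_variable_ratings()].
#' @param implicit_overrides Character vector of non-key variables protected
#'   only via correlation with sensitive variables.
#' @return List with `key_variables`, `sensitive_variables`,
#'   `implicit_variables` (character vectors partitioning the schema
#'   variables) and `scores` (data frame with per-variable `total`, `is_key`).
#' @export
triage <- function(ratings = default_variable_ratings(),
                   implicit_overrides = default_implicit_overrides()) {
  vars <- puf_variables()
  if (anyDuplicated(ratings$variable))
    stop("variable rated more than once: ",
         paste(unique(ratings$variable[duplicated(ratings$variable)]),
               collapse = ", "))
  unrated <- setdiff(vars, ratings$variable)
  if (length(unrated) > 0)
    stop("unrated variable(s): ", paste(unrated, collapse = ", "))
  unknown <- setdiff(ratings$variable, vars)
  if (length(unknown) > 0)
    stop("rating for unknown variable(s): ", paste(unknown, collapse = ", "))
  scored <- lapply(seq_len(nrow(ratings)), function(i)
    score_variable(ratings$replicability[i], ratings$availability[i],
                   ratings$distinguishability[i]))
  scores <- data.frame(
    variable = ratings$variable,
    total = vapply(scored, `[[`, integer(1), "total"),
    is_key = vapply(scored, `[[`, logical(1), "is_key"),
    stringsAsFactors = FALSE)
  scores <- scores[match(vars, scores$variable), ]
  rownames(scores) <- NULL
  key <- scores$variable[scores$is_key]
  nonkey <- scores$variable[!scores$is_key]
  implicit <- intersect(implicit_overrides, nonkey)
  sensitive <- setdiff(nonkey, implicit)
  list(key_variables = key, sensitive_variables = sensitive,
       implicit_variables = implicit, scores = scores)
}
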