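# Suppression-based anonymization: records are released unchanged or
# withheld, never generalized (granularity reduction is fixed upstream in
# the schema). A whole equivalence class — all records identical on the key
# variables, missing labels included — is released iff it has at least k
# members and, for every sensitive variable, its within-class distribution
# lies within distance t of the variable's distribution over the full
# original dataset. The incremental mode re-evaluates on the cumulative
# dataset at each release and never retracts previously published records.

#' Privacy configuration
#'
#' @param k Minimum equivalence-class size for release (k-anonymity).
#' @param t Maximum sensitive-variable distribution distance (t-closeness);
#'   the boundary is inclusive (distance equal to `t` is releasable).
#' @param key_variables Quasi-identifiers defining equivalence classes.
#' @param sensitive_variables Variables protected by t-closeness.
#' @param ordinal Named logical vector (or single default) saying which
#'   sensitive variables use the ordinal (earth-mover) distance rather than
#'   the nominal (total-variation) distance. Defaults to the schema's
#'   ordinal flags.
#' @return A `privacy_config` list.
#' @export
privacy_config <- function(k = 11L, t = 0.5,
                           key_variables = NULL,
                           sensitive_variables = NULL,
                           ordinal = NULL) {
  if (is.null(key_variables) || is.null(sensitive_variables)) {
    tri <- triage()
    if (is.null(key_variables)) key_variables <- tri$key_variables
    if (is.null(sensitive_variables))
      sensitive_variables <- tri$sensitive_variables
  }
  if (k < 2) stop("k must be at least 2")
  if (t < 0 || t > 1) stop("t must lie in [0, 1]")
  if (length(intersect(key_variables, sensitive_variables)) > 0)
    stop("key and sensitive variable sets must be disjoint")
  schema <- puf_schema()
  if (is.null(ordinal))
    ordinal <- vapply(sensitive_variables,
                      function(v) isTRUE(schema[[v]]$ordinal), logical(1))
  structure(list(k = as.integer(k), t = t,
                 key_variables = key_variables,
                 sensitive_variables = sensitive_variables,
                 ordinal = ordinal),
            class = "privacy_config")
}

# Integer class index per record for a set of key variables.
class_index <- function(dataset, key_variables) {
  key <- do.call(paste, c(lapply(key_variables, function(v)
    dataset[[v]]), sep = "\r"))
  factor(key)
}

#' Partition a dataset into key-variable equivalence classes
#'
#' Two records share a class iff their values agree on every key variable;
#' missing labels are ordinary categories and group together.
#'
#' @param dataset A [cohort_dataset()].
#' @param key_variables Character vector of schema variables (nonempty).
#' @return List of classes, each a list with `key_tuple` (named character),
#'   `member_ids`, and `size`; classes partition the records.
#' @export
partition_equivalence_classes <- function(dataset, key_variables) {
  if (length(key_variables) == 0)
    stop("key variable set must not be empty")
  missing_vars <- setdiff(key_variables, names(dataset))
  if (length(missing_vars) > 0)
    stop("unknown key variable(s): ", paste(missing_vars, collapse = ", "))
  if (nrow(dataset) == 0) return(list())
  idx <- class_index(dataset, key_variables)
  lapply(levels(idx), function(lv) {
    members <- which(idx == lv)
    tuple <- vapply(key_variables, function(v)
      as.character(dataset[[v]][members[1]]), character(1))
    names(tuple) <- key_variables
    list(key_tuple = tuple,
         member_ids = dataset$case_id[members],
         size = length(members))
  })
}

#' Distance between a class distribution and a reference distribution
#'
#' Nominal variables use the total-variation distance, half the L1 distance
#' between the probability vectors. Ordinal variables use the normalized
#' earth-mover distance: the mean absolute difference of the cumulative
#' distributions over the `m - 1` interior cut points, so that full
#' separation of the two extreme categories scores 1. Both are symmetric,
#' range over [0, 1], and are 0 iff the distributions are equal.
#'
#' @param class_distribution,reference_distribution Named probability
#'   vectors over the same ordered category set, each summing to 1.
#' @param ordinal Use the earth-mover distance?
#' @return Distance in [0, 1].
#' @export
closeness_distance <- function(class_distribution, reference_distribution,
                               ordinal = FALSE) {
  p <- class_distribution
  q <- reference_distribution
  if (length(p) != length(q) || !identical(names(p), names(q)))
    stop("distributions must cover the same ordered category set")
  stopifnot(abs(sum(p) - 1) < 1e-8, abs(sum(q) - 1) < 1e-8)
  if (!ordinal) return(sum(abs(p - q)) / 2)
  m <- length(p)
  if (m < 2) return(0)
  cum <- cumsum(p - q)
  sum(abs(cum[-m])) / (m - 1)
}

# Distribution of one variable over its full schema category set.
category_distribution <- function(values, categories) {
  cnt <- table(factor(values, levels = categories))
  as.numeric(cnt) / sum(cnt) -> p
  stats::setNames(p, categories)
}

# Per-class t-closeness check against reference distributions computed on
# the full dataset. Returns, per class, the worst offending variable and its
# distance (the first variable exceeding t, else the maximal distance seen).
class_t_audit <- function(dataset, idx, config) {
  refs <- lapply(config$sensitive_variables, function(v)
    category_distribution(dataset[[v]], puf_schema()[[v]]$categories))
  names(refs) <- config$sensitive_variables
  lv <- levels(idx)
  res <- data.frame(class = lv, t_ok = TRUE,
                    offending_variable = NA_character_,
                    max_distance = 0, stringsAsFactors = FALSE)
  for (i in seq_along(lv)) {
    members <- idx == lv[i]
    worst_v <- NA_character_; worst_d <- 0; ok <- TRUE
    for (v in config$sensitive_variables) {
      d <- closeness_distance(
        category_distribution(dataset[[v]][members],
                              puf_schema()[[v]]$categories),
        refs[[v]],
        ordinal = isTRUE(config$ordinal[[v]]))
      if (d > worst_d) { worst_d <- d; worst_v <- v }
      if (d > config$t) { ok <- FALSE }
    }
    res$t_ok[i] <- ok
    res$offending_variable[i] <- worst_v
    res$max_distance[i] <- worst_d
  }
  res
}

#' Anonymize a dataset by class-level record suppression
#'
#' Releases exactly those equivalence classes that satisfy both guarantees:
#' class size at least `k`, and for every sensitive variable a
#' [closeness_distance()] to the full-dataset distribution of at most `t`.
#' Released records are unchanged; suppression operates on whole classes.
#'
#' @param dataset A [cohort_dataset()].
#' @param config A [privacy_config()].
#' @return An `anonymized_release` list: `released_ids`, `suppressed_ids`,
#'   `class_decisions` (per-class size, decision `released` /
#'   `suppressed_k` / `suppressed_t`, offending variable and distance),
#'   `config`, `release_index`, `frozen_classes`, and
#'   `frozen_released_ids` (records published before their class drifted
#'   out of t-closeness; empty for a one-shot release).
#' @export
anonymize <- function(dataset, config = privacy_config()) {
  n <- nrow(dataset)
  if (n == 0)
    return(structure(list(released_ids = character(),
                          suppressed_ids = character(),
                          class_decisions = data.frame(),
                          config = config, release_index = 1L,
                          frozen_classes = character(),
                          frozen_released_ids = character()),
                     class = "anonymized_release"))
  idx <- class_index(dataset, config$key_variables)
  sizes <- table(idx)
  audit <- class_t_audit(dataset, idx, config)
  decision <- ifelse(as.numeric(sizes)[match(audit$class, names(sizes))] <
                       config$k, "suppressed_k",
                     ifelse(audit$t_ok, "released", "suppressed_t"))
  audit$size <- as.integer(sizes[match(audit$class, names(sizes))])
  audit$decision <- decision
  released <- dataset$case_id[idx %in% audit$class[decision == "released"]]
  structure(list(
    released_ids = released,
    suppressed_ids = setdiff(dataset$case_id, released),
    class_decisions = audit[, c("class", "size", "decision",
                                "offending_variable", "max_distance")],
    config = config, release_index = 1L,
    frozen_classes = character(),
    frozen_released_ids = character()),
    class = "anonymized_release")
}

#' Incremental (continuous) release
#'
#' Re-evaluates the class decisions on the cumulative dataset and merges
#' them with the previous release so that publication is monotone: no record
#' is ever retracted. A class that newly satisfies both guarantees is
#' released in full; a class whose members were already published but which
#' would now fail t-closeness (possible as the reference distribution drifts
#' with accrual) is frozen at its previously released membership and
#' reported in `frozen_classes` — the freeze is audited, never silent. Class
#' sizes only grow, so the k guarantee cannot newly fail for published
#' classes.
#'
#' @param previous The previous `anonymized_release`, or `NULL` for the
#'   first release.
#' @param dataset The cumulative [cohort_dataset()]; must be a superset of
#'   the dataset underlying `previous`.
#' @param config A [privacy_config()].
#' @return An `anonymized_release` with `release_index` incremented.
#' @export
incremental_release <- function(previous, dataset,
                                config = privacy_config()) {
  if (is.null(previous)) return(anonymize(dataset, config))
  prev_ids <- c(previous$released_ids, previous$suppressed_ids)
  if (!all(prev_ids %in% dataset$case_id))
    stop("dataset must be a superset of the previously anonymized dataset")
  current <- anonymize(dataset, config)
  idx <- class_index(dataset, config$key_variables)
  dec <- current$class_decisions
  frozen <- character()
  frozen_ids <- previous$frozen_released_ids
  released <- current$released_ids
  # classes with previously published members that fail t now: freeze
  for (i in seq_len(nrow(dec))) {
    if (dec$decision[i] != "suppressed_t") next
    members <- dataset$case_id[idx == dec$class[i]]
    already <- intersect(members, previous$released_ids)
    if (length(already) > 0) {
      released <- c(released, already)
      dec$decision[i] <- "released_frozen"
      frozen <- c(frozen, dec$class[i])
      frozen_ids <- union(frozen_ids, already)
    }
  }
  released <- union(released, previous$released_ids)
  structure(list(
    released_ids = released,
    suppressed_ids = setdiff(dataset$case_id, released),
    class_decisions = dec,
    config = config,
    release_index = previous$release_index + 1L,
    frozen_classes = union(previous$frozen_classes, frozen),
    frozen_released_ids = frozen_ids),
    class = "anonymized_release")
}

#' Extract the released records of a release
#'
#' @param dataset The dataset the release was computed on.
#' @param release An `anonymized_release`.
#' @return A [cohort_dataset()] restricted to the released records.
#' @export
released_data <- function(dataset, release) {
  d <- dataset[dataset$case_id %in% release$released_ids, , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("cohort_dataset", "data.frame")
  d
}
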