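# PUF schema: the 15 released variables, their category sets, and the
# private bookkeeping columns (case_id, diagnosis_date).

MISSING <- "unknown/missing"
NOT_APPLICABLE <- "n/a"

#' PUF variable schema
#'
#' Returns the schema of the 15 public-use-file variables: demographic
#' identifiers released at coarse granularity (age group, gender, quarter and
#' year of first diagnosis, sub-cohort) and clinical course/outcome variables
#' (disease-phase flags, patient status at the end of the acute phase,
#' hospitalization, intensive care, invasive ventilation, and the 3-month
#' follow-up block). Missing values are explicit category labels
#' (`"unknown/missing"`, and `"n/a"` for follow-up sub-variables of cases
#' without a follow-up visit), never `NA`: this makes equivalence-class and
#' distribution logic total over the category sets.
#'
#' @return A named list of variable definitions, each a list with elements
#'   `name`, `categories` (ordered character vector of unique labels),
#'   `missing_label` (label or `NA`), and `ordinal` (logical).
#' @export
puf_schema <- function() {
  v <- function(name, categories, missing_label = NA_character_, ordinal = FALSE) {
    stopifnot(!anyDuplicated(categories),
              is.na(missing_label) || missing_label %in% categories)
    list(name = name, categories = categories,
         missing_label = missing_label, ordinal = ordinal)
  }
  defs <- list(
    v("age_group", c("<=17", "18-39", "40-59", "60-79", ">=80", MISSING),
      MISSING, ordinal = TRUE),
    v("gender", c("male", "female", "diverse", MISSING), MISSING),
    v("quarter_first_diagnosis", c("Q1", "Q2", "Q3", "Q4", MISSING),
      MISSING, ordinal = TRUE),
    v("year_first_diagnosis", c("2020", "2021", "2022", "2023", MISSING),
      MISSING, ordinal = TRUE),
    v("cohort", c("SUEP", "POP", "HAP")),
    v("mild_phase", c("yes", "no", MISSING), MISSING),
    v("moderate_phase", c("yes", "no", MISSING), MISSING),
    v("severe_phase", c("yes", "no", MISSING), MISSING),
    v("patient_status_end_acute",
      c("ambulant", "discharged", "referral/transfer", "dead", MISSING), MISSING),
    v("hospitalization", c("yes", "no", MISSING), MISSING),
    v("intensive_care", c("yes", "no", MISSING), MISSING),
    v("invasive_ventilation", c("yes", "no", MISSING), MISSING),
    v("followup_3m_available", c("yes", "no/not yet")),
    v("ability_to_work_3m", c(NOT_APPLICABLE, "yes", "no", MISSING), MISSING),
    v("any_symptom_3m", c(NOT_APPLICABLE, "yes", "no", MISSING), MISSING)
  )
  names(defs) <- vapply(defs, `[[`, "", "name")
  defs
}

#' Names of the schema variables
#' @return Character vector of the 15 PUF variable names, in release order.
#' @export
puf_variables <- function() names(puf_schema())

# Private columns carried alongside the PUF variables.
PRIVATE_COLUMNS <- c("case_id", "diagnosis_date")

#' Construct a cohort dataset
#'
#' Wraps a data frame of case records into the container used throughout the
#' package. The data frame must carry one column per schema variable plus
#' `case_id` (unique opaque token) and `diagnosis_date` (`Date`, may be `NA`).
#'
#' @param records Data frame of case records.
#' @return The data frame with class `cohort_dataset` prepended.
#' @export
cohort_dataset <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c(PRIVATE_COLUMNS, puf_variables())
  miss <- setdiff(needed, names(records))
  if (length(miss) > 0)
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  records <- as.data.frame(records[needed], stringsAsFactors = FALSE)
  records$case_id <- as.character(records$case_id)
  records$diagnosis_date <- as.Date(records$diagnosis_date)
  if (anyDuplicated(records$case_id))
    stop("case_id values must be unique")
  class(records) <- c("cohort_dataset", "data.frame")
  records
}

#' Validate a cohort dataset against the PUF schema
#'
#' Checks every record against the schema: values must belong to their
#' variable's category set, and quarter/year of first diagnosis must agree
#' with the diagnosis date when the date is present. Violations are returned
#' as data, not raised, so validation reports are complete.
#'
#' @param dataset A [cohort_dataset()].
#' @return Data frame with columns `case_id`, `variable`, `value`, `problem`;
#'   zero rows iff the dataset is valid.
#' @export
validate_dataset <- function(dataset) {
  schema <- puf_schema()
  out <- list()
  for (def in schema) {
    vals <- as.character(dataset[[def$name]])
    bad <- !(vals %in% def$categories)
    if (any(bad)) {
      out[[length(out) + 1L]] <- data.frame(
        case_id = dataset$case_id[bad], variable = def$name,
        value = vals[bad], problem = "value outside category set",
        stringsAsFactors = FALSE)
    }
  }
  dated <- !is.na(dataset$diagnosis_date)
  if (any(dated)) {
    d <- dataset$diagnosis_date[dated]
    expect_q <- paste0("Q", (as.integer(format(d, "%m")) - 1L) %/% 3L + 1L)
    expect_y <- format(d, "%Y")
    bad_q <- dataset$quarter_first_diagnosis[dated] != expect_q
    bad_y <- dataset$year_first_diagnosis[dated] != expect_y
    if (any(bad_q))
      out[[length(out) + 1L]] <- data.frame(
        case_id = dataset$case_id[dated][bad_q],
        variable = "quarter_first_diagnosis",
        value = dataset$quarter_first_diagnosis[dated][bad_q],
        problem = "inconsistent with diagnosis_date", stringsAsFactors = FALSE)
    if (any(bad_y))
      out[[length(out) + 1L]] <- data.frame(
        case_id = dataset$case_id[dated][bad_y],
        variable = "year_first_diagnosis",
        value = dataset$year_first_diagnosis[dated][bad_y],
        problem = "inconsistent with diagnosis_date", stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(case_id = character(), variable = character(),
                      value = character(), problem = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Read a PUF CSV file
#'
#' Reads the release CSV format (comma-separated, UTF-8, header row).
#' Empty cells are mapped to the variable's missing label. Files may carry
#' the private columns (`case_id`, `diagnosis_date`); public files without
#' them get synthetic row-number ids and `NA` dates. Unknown columns are
#' tolerated and reported via a warning.
#'
#' @param path Path to a CSV file.
#' @return A [cohort_dataset()].
#' @export
read_puf_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  miss <- setdiff(puf_variables(), names(raw))
  if (length(miss) > 0)
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(raw), c(PRIVATE_COLUMNS, puf_variables()))
  if (length(extra) > 0)
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  n <- nrow(raw)
  if (!"case_id" %in% names(raw))
    raw$case_id <- if (n > 0) sprintf("row%06d", seq_len(n)) else character()
  if (!"diagnosis_date" %in% names(raw)) {
    raw$diagnosis_date <- rep(NA_character_, n)
  } else {
    raw$diagnosis_date[!nzchar(raw$diagnosis_date)] <- NA_character_
  }
  schema <- puf_schema()
  for (def in schema) {
    v <- raw[[def$name]]
    if (!is.na(def$missing_label)) v[!nzchar(v)] <- def$missing_label
    raw[[def$name]] <- v
  }
  cohort_dataset(raw)
}

#' Write a PUF CSV file
#'
#' Writes the dataset in the release format with a deterministic column
#' order. In public mode (`include_private = FALSE`, the default) the
#' `case_id` and `diagnosis_date` columns are omitted: the released
#' granularity for timing is quarter/year only.
#'
#' @param dataset A [cohort_dataset()].
#' @param path Output path.
#' @param include_private Keep `case_id` and `diagnosis_date` columns?
#' @export
write_puf_csv <- function(dataset, path, include_private = FALSE) {
  cols <- puf_variables()
  if (include_private) cols <- c(PRIVATE_COLUMNS, cols)
  out <- as.data.frame(dataset)[cols]
  if (include_private)
    out$diagnosis_date <- ifelse(is.na(out$diagnosis_date), "",
                                 format(out$diagnosis_date, "%Y-%m-%d"))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(NULL)
}

#' Frequency table of one variable
#'
#' Counts and relative frequencies per category, optionally stratified by
#' sub-cohort. Counts cover the full category set (zero-filled); proportions
#' are `NA` in empty strata.
#'
#' @param dataset A [cohort_dataset()].
#' @param variable A schema variable name.
#' @param stratify_by_cohort Stratify by the `cohort` variable?
#' @return Data frame with columns `cohort` (if stratified), `category`,
#'   `count`, `proportion`.
#' @export
frequency_table <- function(dataset, variable, stratify_by_cohort = FALSE) {
  schema <- puf_schema()
  if (!variable %in% names(schema)) stop("unknown variable: ", variable)
  cats <- schema[[variable]]$categories
  one <- function(vals) {
    cnt <- table(factor(vals, levels = cats))
    n <- sum(cnt)
    data.frame(category = cats, count = as.integer(cnt),
               proportion = if (n > 0) as.integer(cnt) / n else
                 rep(NA_real_, length(cats)),
               stringsAsFactors = FALSE)
  }
  if (!stratify_by_cohort) return(one(dataset[[variable]]))
  res <- lapply(schema$cohort$categories, function(co) {
    tab <- one(dataset[[variable]][dataset$cohort == co])
    cbind(cohort = co, tab, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
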