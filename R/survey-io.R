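## Survey schema ------------------------------------------------------------

#' Column names of the household survey schema
#'
#' The money columns are, in order: household income, total household
#' expenditure (THE_h, includes food), food expenditure, and the five OOP
#' health-spending components (consultations, hospitalization, medicines,
#' diagnostic tests, transportation).  Period and currency are *metadata*
#' of the dataset (see [money_convention()]), not part of the column names.
#'
#' @return Character vector of column names.
#' @export
survey_schema <- function() {
  c("household_id", money_columns(), "household_size",
    "patient_sex", "patient_age", "patient_education_years",
    "patient_diagnosis", "patient_employed",
    "caregiver_sex", "caregiver_age", "caregiver_education_years",
    "caregiver_relationship", "missed_work_days", "marital_status")
}

money_columns <- function() {
  c("income", "expenditure_total", "expenditure_food", oop_columns())
}

#' @rdname survey_schema
#' @export
oop_columns <- function() {
  c("oop_consultation", "oop_hospitalization", "oop_medicines",
    "oop_diagnostics", "oop_transport")
}

sex_levels <- c("male", "female")
marital_levels <- c("single", "married")

## Validation ---------------------------------------------------------------

## Row-wise invariant checks. Returns a data.frame (row, reason) of
## violations; a row may appear more than once if it breaks several rules.
validate_rows <- function(df) {
  reasons <- list()
  flag <- function(bad, reason) {
    if (any(bad, na.rm = TRUE)) {
      idx <- which(bad)
      reasons[[length(reasons) + 1L]] <<- data.frame(
        row = idx, reason = reason, stringsAsFactors = FALSE)
    }
  }
  for (col in money_columns()) {
    x <- df[[col]]
    flag(is.na(x), sprintf("missing or non-numeric value in '%s'", col))
    flag(!is.na(x) & (!is.finite(x) | x < 0),
         sprintf("'%s' must be finite and non-negative", col))
  }
  flag(is.na(df$household_size) | df$household_size < 1 |
         df$household_size != round(df$household_size),
       "'household_size' must be an integer >= 1")
  ok_money <- !is.na(df$expenditure_food) & !is.na(df$expenditure_total)
  flag(ok_money & df$expenditure_food > df$expenditure_total,
       "food expenditure exceeds total expenditure")
  flag(!(df$patient_sex %in% sex_levels),
       "'patient_sex' must be 'male' or 'female'")
  flag(!(df$caregiver_sex %in% sex_levels),
       "'caregiver_sex' must be 'male' or 'female'")
  flag(!(df$marital_status %in% marital_levels),
       "'marital_status' must be 'single' or 'married'")
  flag(is.na(df$patient_age) | df$patient_age < 0, "invalid 'patient_age'")
  flag(is.na(df$missed_work_days) | df$missed_work_days < 0,
       "invalid 'missed_work_days'")
  flag(is.na(df$patient_employed), "missing 'patient_employed'")
  if (length(reasons) == 0L) {
    data.frame(row = integer(), reason = character(),
               stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, reasons)
    out[order(out$row), , drop = FALSE]
  }
}

#' Assemble a validated household survey
#'
#' Rows violating the schema invariants (negative or missing money values,
#' food expenditure above total expenditure, non-integer household size,
#' unknown categorical levels) are rejected with row-indexed diagnostics,
#' mirroring the exclusion of households with unrecorded expenses rather
#' than imputing or clamping.
#'
#' @param records Data frame with the columns of [survey_schema()].
#' @param convention [money_convention()] of the money columns.
#' @return A `household_survey`: list with elements `records` (accepted
#'   rows), `rejects` (data frame of `row`, `reason`), `convention`.
#' @export
household_survey <- function(records, convention = money_convention()) {
  stopifnot(inherits(convention, "money_convention"))
  missing_cols <- setdiff(survey_schema(), names(records))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records)[, survey_schema()]
  records$patient_employed <- as_flag(records$patient_employed)
  rejects <- validate_rows(records)
  bad <- unique(rejects$row)
  accepted <- records[setdiff(seq_len(nrow(records)), bad), , drop = FALSE]
  rownames(accepted) <- NULL
  structure(
    list(records = accepted, rejects = rejects, convention = convention),
    class = "household_survey"
  )
}

as_flag <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) return(ifelse(is.na(x), NA_integer_,
                                   as.integer(x != 0)))
  lx <- tolower(as.character(x))
  out <- rep(NA_integer_, length(lx))
  out[lx %in% c("true", "t", "yes", "1")] <- 1L
  out[lx %in% c("false", "f", "no", "0")] <- 0L
  out
}

#' @export
print.household_survey <- function(x, ...) {
  cat(sprintf(
    "<household survey: %d households (%d rejected), %s, %s>\n",
    nrow(x$records), length(unique(x$rejects$row)),
    x$convention$currency, x$convention$period))
  invisible(x)
}

#' Load household survey microdata from a delimited text file
#'
#' Reads a header-required CSV (configurable delimiter), coerces money
#' columns to numeric, and validates every row against the schema
#' invariants.  Rows that fail validation — including cells that do not
#' parse as numbers — are rejected with a row-indexed reason, never
#' silently repaired.  The count of accepted and rejected rows is
#' reported via `message()`.
#'
#' @param path Path to the delimited file.
#' @param convention [money_convention()] describing the units of the
#'   money columns in the file.
#' @param delimiter Field delimiter (default comma).
#' @return A `household_survey`; see [household_survey()].
#' @export
load_survey <- function(path, convention = money_convention(),
                        delimiter = ",") {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           colClasses = "character", check.names = TRUE,
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  missing_cols <- setdiff(survey_schema(), names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("no data rows in ", path, call. = FALSE)
  }
  numeric_cols <- c(money_columns(), "household_size", "patient_age",
                    "patient_education_years", "caregiver_age",
                    "caregiver_education_years", "missed_work_days")
  for (col in numeric_cols) {
    ## unparseable cells become NA here and are rejected by validation
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  survey <- household_survey(raw, convention)
  message(sprintf("load_survey: %d accepted, %d rejected",
                  nrow(survey$records), length(unique(survey$rejects$row))))
  survey
}

#' Write a survey (and its reject log) back to CSV
#'
#' @param survey A `household_survey`.
#' @param path Output CSV path for the accepted records.
#' @param rejects_path Optional path for the reject log.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path, rejects_path = NULL) {
  stopifnot(inherits(survey, "household_survey"))
  utils::write.csv(survey$records, path, row.names = FALSE)
  if (!is.null(rejects_path)) {
    utils::write.csv(survey$rejects, rejects_path, row.names = FALSE)
  }
  invisible(path)
}

## Unit normalization -------------------------------------------------------

#' Annualize a monthly survey
#'
#' Multiplies every money column by exactly 12 and flips the period
#' metadata to annual, following the convention that flows recorded for
#' the previous month are scaled to annual measures.  All non-money
#' fields are untouched.  Annualizing an already-annual survey is a state
#' error, not a no-op: silent double scaling is the failure mode the
#' period metadata exists to prevent.
#'
#' @param survey A monthly `household_survey`.
#' @return The survey with annual money columns.
#' @export
annualize <- function(survey) {
  stopifnot(inherits(survey, "household_survey"))
  if (survey$convention$period != "monthly") {
    stop("survey is already annual; refusing to annualize twice",
         call. = FALSE)
  }
  for (col in money_columns()) {
    survey$records[[col]] <- survey$records[[col]] * 12
  }
  survey$convention$period <- "annual"
  survey
}

#' Total out-of-pocket health expenditure per household
#'
#' Sum of the five OOP components: consultations, hospitalization,
#' medicines, diagnostic tests and transportation.  Continuous, bounded
#' below by zero.
#'
#' @param x A `household_survey` or a data frame of records.
#' @return Numeric vector, one total per household.
#' @export
oop_total <- function(x) {
  records <- if (inherits(x, "household_survey")) x$records else x
  stopifnot(all(oop_columns() %in% names(records)))
  rowSums(records[, oop_columns(), drop = FALSE])
}
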