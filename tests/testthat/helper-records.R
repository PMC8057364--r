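## Minimal valid records with controllable money fields; all other
## covariates held at constants so CHE-chain tests are not distracted.
make_records <- function(the, food, size = rep(1L, length(the)),
                         oop = NULL, income = the) {
  n <- length(the)
  if (is.null(oop)) {
    oop <- matrix(0, n, 5)
  }
  data.frame(
    household_id = sprintf("H%03d", seq_len(n)),
    income = income,
    expenditure_total = the,
    expenditure_food = food,
    oop_consultation = oop[, 1],
    oop_hospitalization = oop[, 2],
    oop_medicines = oop[, 3],
    oop_diagnostics = oop[, 4],
    oop_transport = oop[, 5],
    household_size = size,
    patient_sex = rep("male", n),
    patient_age = rep(30, n),
    patient_education_years = rep(9, n),
    patient_diagnosis = rep("schizophrenia", n),
    patient_employed = rep(0L, n),
    caregiver_sex = rep("female", n),
    caregiver_age = rep(45, n),
    caregiver_education_years = rep(11, n),
    caregiver_relationship = rep("mother", n),
    missed_work_days = rep(2L, n),
    marital_status = rep("single", n),
    stringsAsFactors = FALSE
  )
}

annual_survey <- function(records) {
  household_survey(records, money_convention("MXN", "annual"))
}

monthly_survey <- function(records) {
  household_survey(records, money_convention("MXN", "monthly"))
}

## Random small dataset for oracle-equivalence checks: positive totals,
## food strictly inside total, occasional zero OOP.
random_small_records <- function(n = NULL) {
  if (is.null(n)) n <- sample(1:50, 1)
  the <- stats::runif(n, 500, 100000)
  food <- the * stats::runif(n, 0.05, 0.95)
  size <- sample(1:8, n, replace = TRUE)
  oop <- matrix(stats::runif(n * 5, 0, 4000), n, 5)
  oop[stats::runif(n * 5) < 0.3] <- 0
  make_records(the, food, size = size, oop = oop)
}

write_survey_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}
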