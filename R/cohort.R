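#' Blood-pressure cohorts
#'
#' A cohort bundles a patients table and a readings table. Readings are dated
#' systolic/diastolic pairs labelled by source (`"telemonitored"` for values
#' submitted from home, `"surgery"` for values recorded at the practice).
#' Patients carry practice, sex, year of birth, deprivation decile (SIMD,
#' lower = more deprived) and study group (`"telemonitoring"` if the patient
#' used the home system, `"comparator"` otherwise).
#'
#' @param patients A data frame with columns `patient_id`, `practice_id`,
#'   `sex` (`"male"`/`"female"`), `year_of_birth`, `simd_decile` (1-10),
#'   `group` (`"telemonitoring"`/`"comparator"`).
#' @param readings A data frame with columns `patient_id`, `date` (`Date`),
#'   `source` (`"telemonitored"`/`"surgery"`), `systolic`, `diastolic`
#'   (integer mmHg).
#' @param telemonitoring_start Date the telemonitoring service started;
#'   readings before this date are dropped by [filter_calendar()]. Default
#'   `"2015-09-01"`.
#' @return A `bp_cohort`: a list with tibbles `patients` and `readings` and
#'   the `telemonitoring_start` date.
#' @export
bp_cohort <- function(patients, readings,
                      telemonitoring_start = as.Date("2015-09-01")) {
  patients <- validate_patients(as_tibble(patients))
  readings <- validate_readings(as_tibble(readings))
  orphan <- setdiff(readings$patient_id, patients$patient_id)
  if (length(orphan) > 0) {
    abort(sprintf(
      "%d reading(s) reference patient ids absent from the patients table (e.g. %s)",
      sum(readings$patient_id %in% orphan), orphan[1]
    ))
  }
  bad <- readings %>%
    left_join(select(patients, "patient_id", "group"), by = "patient_id") %>%
    filter(.data$group == "comparator", .data$source != "surgery")
  if (nrow(bad) > 0) {
    abort(sprintf(
      "comparator patients must have surgery-source readings only (%d offending rows)",
      nrow(bad)
    ))
  }
  dup <- readings %>% count(.data$patient_id, .data$date, .data$source,
                            .data$systolic, .data$diastolic) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    warn(sprintf("%d duplicated reading(s) retained (no deduplication is applied)",
                 sum(dup$n) - nrow(dup)))
  }
  structure(
    list(patients = patients, readings = readings,
         telemonitoring_start = as.Date(telemonitoring_start)),
    class = "bp_cohort"
  )
}

#' @export
print.bp_cohort <- function(x, ...) {
  cat("<bp_cohort>\n")
  cat(sprintf("  %d patients (%d telemonitoring, %d comparator) in %d practices\n",
              nrow(x$patients),
              sum(x$patients$group == "telemonitoring"),
              sum(x$patients$group == "comparator"),
              length(unique(x$patients$practice_id))))
  cat(sprintf("  %d readings (%d telemonitored, %d surgery)\n",
              nrow(x$readings),
              sum(x$readings$source == "telemonitored"),
              sum(x$readings$source == "surgery")))
  cat(sprintf("  telemonitoring start: %s\n", format(x$telemonitoring_start)))
  invisible(x)
}

validate_patients <- function(patients) {
  required <- c("patient_id", "practice_id", "sex", "year_of_birth",
                "simd_decile", "group")
  check_columns(patients, required, "patients")
  check_levels(patients$sex, c("male", "female"), "sex", "patients")
  check_levels(patients$group, c("telemonitoring", "comparator"), "group",
               "patients")
  check_integerish(patients$year_of_birth, "year_of_birth", "patients")
  check_integerish(patients$simd_decile, "simd_decile", "patients")
  if (anyDuplicated(patients$patient_id)) {
    abort("patients: duplicated patient_id")
  }
  patients <- mutate(patients,
                     patient_id = as.character(.data$patient_id),
                     practice_id = as.character(.data$practice_id),
                     year_of_birth = as.integer(.data$year_of_birth),
                     simd_decile = as.integer(.data$simd_decile))
  bad <- which(patients$simd_decile < 1 | patients$simd_decile > 10)
  if (length(bad) > 0) {
    abort(sprintf("patients row %d: simd_decile must be in 1..10 (got %s)",
                  bad[1], patients$simd_decile[bad[1]]))
  }
  patients
}

validate_readings <- function(readings) {
  required <- c("patient_id", "date", "source", "systolic", "diastolic")
  check_columns(readings, required, "readings")
  date <- as.Date(readings$date, format = "%Y-%m-%d")
  bad <- which(is.na(date) & !is.na(readings$date))
  if (length(bad) > 0) {
    abort(sprintf("readings row %d: column 'date' is not an ISO date (got %s)",
                  bad[1], readings$date[bad[1]]))
  }
  check_levels(readings$source, c("telemonitored", "surgery"), "source",
               "readings")
  check_integerish(readings$systolic, "systolic", "readings")
  check_integerish(readings$diastolic, "diastolic", "readings")
  mutate(readings,
         patient_id = as.character(.data$patient_id),
         date = as.Date(.data$date),
         systolic = as.integer(.data$systolic),
         diastolic = as.integer(.data$diastolic))
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
}

check_levels <- function(x, levels, col, what) {
  bad <- which(!x %in% levels)
  if (length(bad) > 0) {
    abort(sprintf("%s row %d: column '%s' has unknown code '%s' (expected %s)",
                  what, bad[1], col, x[bad[1]],
                  paste(levels, collapse = "/")))
  }
}

check_integerish <- function(x, col, what) {
  num <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(num) | num != round(num))
  if (length(bad) > 0) {
    abort(sprintf("%s row %d: column '%s' must be an integer (got '%s')",
                  what, bad[1], col, x[bad[1]]))
  }
}

#' Read and write cohorts as CSV
#'
#' `read_cohort()` reads the readings and patients CSV files (schemas below)
#' into a [bp_cohort()]; malformed rows raise row-numbered errors.
#' `write_cohort()` writes the two files back out.
#'
#' Readings CSV: `patient_id, date (YYYY-MM-DD), source, systolic, diastolic`.
#' Patients CSV: `patient_id, practice_id, sex, year_of_birth, simd_decile,
#' group`.
#'
#' @param readings_path,patients_path CSV file paths.
#' @inheritParams bp_cohort
#' @return `read_cohort()` returns a `bp_cohort`; `write_cohort()` returns the
#'   cohort invisibly.
#' @export
read_cohort <- function(readings_path, patients_path,
                        telemonitoring_start = as.Date("2015-09-01")) {
  for (p in c(readings_path, patients_path)) {
    if (!file.exists(p)) abort(sprintf("file not found: %s", p))
  }
  readings <- as_tibble(read.csv(readings_path, colClasses = "character"))
  patients <- as_tibble(read.csv(patients_path, colClasses = "character"))
  bp_cohort(patients, readings, telemonitoring_start)
}

#' @param cohort A `bp_cohort`.
#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, readings_path, patients_path) {
  stopifnot(inherits(cohort, "bp_cohort"))
  readings <- mutate(cohort$readings, date = format(.data$date, "%Y-%m-%d"))
  write.csv(readings, readings_path, row.names = FALSE, quote = FALSE)
  write.csv(cohort$patients, patients_path, row.names = FALSE, quote = FALSE)
  invisible(cohort)
}

#' Exclusion rules for erroneous blood-pressure readings
#'
#' Readings are screened with six plausibility rules (in this order): systolic
#' < 60 mmHg, systolic > 262 mmHg, diastolic < 40 mmHg, diastolic > 124 mmHg,
#' diastolic greater than systolic, and systolic less than 10 mmHg above
#' diastolic. A reading failing several rules is tagged with the first failed
#' rule unless `verbose = TRUE`, which tags all of them
#' (semicolon-separated).
#'
#' @param readings A readings tibble (see [bp_cohort()]).
#' @param verbose Report every violated rule instead of the first.
#' @return A list of class `bp_exclusions`: `kept` (readings passing all
#'   rules) and `excluded` (failing readings with a `rule_id` column).
#' @export
apply_exclusion_criteria <- function(readings, verbose = FALSE) {
  readings <- as_tibble(readings)
  rules <- exclusion_rules()
  viol <- vapply(rules, function(f) f(readings$systolic, readings$diastolic),
                 logical(nrow(readings)))
  if (nrow(readings) == 1L) viol <- matrix(viol, nrow = 1)
  any_viol <- rowSums(viol) > 0
  tag <- character(nrow(readings))
  if (any(any_viol)) {
    ids <- names(rules)
    tag[any_viol] <- apply(viol[any_viol, , drop = FALSE], 1, function(v) {
      if (verbose) paste(ids[v], collapse = ";") else ids[which(v)[1]]
    })
  }
  structure(
    list(kept = readings[!any_viol, , drop = FALSE],
         excluded = mutate(readings[any_viol, , drop = FALSE],
                           rule_id = tag[any_viol])),
    class = "bp_exclusions"
  )
}

#' @export
print.bp_exclusions <- function(x, ...) {
  cat(sprintf("<bp_exclusions> kept %d, excluded %d reading(s)\n",
              nrow(x$kept), nrow(x$excluded)))
  if (nrow(x$excluded) > 0) print(count(x$excluded, .data$rule_id))
  invisible(x)
}

# Named predicates, in reporting order.
exclusion_rules <- function() {
  list(
    "systolic<60"             = function(s, d) s < 60,
    "systolic>262"            = function(s, d) s > 262,
    "diastolic<40"            = function(s, d) d < 40,
    "diastolic>124"           = function(s, d) d > 124,
    "diastolic>systolic"      = function(s, d) d > s,
    "systolic-diastolic<10"   = function(s, d) s < d + 10
  )
}

#' Calendar and age eligibility filters
#'
#' `filter_calendar()` keeps readings dated on or after the cutoff (readings
#' strictly before the telemonitoring start are excluded; the start date
#' itself is kept). `filter_age()` keeps patients whose approximate age
#' (`reference_year - year_of_birth`) is between 18 and 90 inclusive.
#'
#' @param readings A readings tibble.
#' @param cutoff Cutoff date (default 2015-09-01).
#' @return A filtered tibble.
#' @export
filter_calendar <- function(readings, cutoff = as.Date("2015-09-01")) {
  filter(as_tibble(readings), .data$date >= as.Date(cutoff))
}

#' @param patients A patients tibble.
#' @param reference_year Year used to derive approximate age (default 2015).
#' @param min_age,max_age Inclusive age bounds.
#' @rdname filter_calendar
#' @export
filter_age <- function(patients, reference_year = 2015,
                       min_age = 18, max_age = 90) {
  patients <- as_tibble(patients)
  age <- reference_year - patients$year_of_birth
  if (any(age < 0)) abort("reference_year precedes some years of birth")
  patients[age >= min_age & age <= max_age, , drop = FALSE]
}

#' Apply cleaning and eligibility filters to a whole cohort
#'
#' Convenience wrapper: applies the six exclusion rules to readings, the
#' calendar cutoff (the cohort's `telemonitoring_start`), and the 18-90 age
#' filter to patients, returning a cleaned `bp_cohort` plus the exclusion
#' report.
#'
#' @param cohort A `bp_cohort`.
#' @param reference_year Year for the age filter.
#' @return A list with `cohort` (cleaned) and `exclusions` (`bp_exclusions`).
#' @export
clean_cohort <- function(cohort, reference_year = 2015) {
  stopifnot(inherits(cohort, "bp_cohort"))
  excl <- apply_exclusion_criteria(cohort$readings)
  readings <- filter_calendar(excl$kept, cohort$telemonitoring_start)
  patients <- filter_age(cohort$patients, reference_year)
  readings <- filter(readings, .data$patient_id %in% patients$patient_id)
  cleaned <- structure(
    list(patients = patients, readings = readings,
         telemonitoring_start = cohort$telemonitoring_start),
    class = "bp_cohort"
  )
  list(cohort = cleaned, exclusions = excl)
}
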