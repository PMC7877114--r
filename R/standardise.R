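#' Select the index ("baseline") reading for one patient
#'
#' Telemonitoring patients use their chronologically second telemonitored
#' reading (the first may have been used to test the system); comparator
#' patients use their first surgery reading on or after the calendar cutoff.
#'
#' @param patient One-row patients tibble (or list with `group`).
#' @param readings That patient's cleaned readings.
#' @param cutoff Calendar cutoff (default 2015-09-01).
#' @return A one-row readings tibble, or `NULL` if no index reading exists.
#' @export
select_index_reading <- function(patient, readings,
                                 cutoff = as.Date("2015-09-01")) {
  readings <- arrange(as_tibble(readings), .data$date)
  if (patient$group == "telemonitoring") {
    cand <- filter(readings, .data$source == "telemonitored",
                   .data$date >= as.Date(cutoff))
    if (nrow(cand) < 2) return(NULL)
    cand[2, , drop = FALSE]
  } else {
    cand <- filter(readings, .data$source == "surgery",
                   .data$date >= as.Date(cutoff))
    if (nrow(cand) < 1) return(NULL)
    cand[1, , drop = FALSE]
  }
}

#' Select the final (6-12 month) reading for one patient
#'
#' Among same-source readings dated 183 to 365 days (inclusive) after the
#' baseline, returns the one closest to 12 months (365 days); ties are broken
#' towards the later reading.
#'
#' @param readings One patient's readings, already restricted to the source
#'   matching their group.
#' @param baseline_date Date of the index reading.
#' @param window Inclusive day-offset window, default `c(183, 365)`.
#' @return A one-row readings tibble, or `NULL` if the window is empty.
#' @export
select_final_reading <- function(readings, baseline_date,
                                 window = c(183, 365)) {
  readings <- as_tibble(readings)
  d <- as.numeric(readings$date - as.Date(baseline_date))
  cand <- readings[d >= window[1] & d <= window[2], , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  dd <- as.numeric(cand$date - as.Date(baseline_date))
  cand <- cand[order(abs(dd - 365), -dd), , drop = FALSE]
  cand[1, , drop = FALSE]
}

#' Build the standardised two-reading dataset
#'
#' Reduces a cleaned cohort to one record per patient: an index ("baseline")
#' reading and a final reading 6-12 months later, mirroring the
#' standardisation step shared by the stratified, matched and
#' propensity-score analyses. Telemonitoring patients contribute
#' telemonitored readings only (index = second reading); comparator patients
#' contribute surgery readings only (index = first reading on/after the
#' cutoff). Patients additionally need a full potential year of follow-up:
#' `baseline date + 365 <= observation_end`.
#'
#' BP differences are baseline minus final, so positive values mean
#' improvement (a fall in BP).
#'
#' @param cohort A cleaned `bp_cohort` (see [clean_cohort()]).
#' @param observation_end Last date of the data extract; defaults to the
#'   latest reading date in the cohort.
#' @param window Final-reading day-offset window, default `c(183, 365)`.
#' @return A tibble of class `bp_standardised`, one row per retained patient:
#'   patient covariates, `baseline_date`, `final_date`, `baseline_sbp`,
#'   `final_sbp`, `baseline_dbp`, `final_dbp`, `sbp_diff`, `dbp_diff`,
#'   `age_2015`, `simd5plus`. The attrition flow report (a tibble of step
#'   label and patient count) is attached as attribute `"flow"`; see
#'   [flow_report()].
#' @export
build_standardised_dataset <- function(cohort, observation_end = NULL,
                                       window = c(183, 365)) {
  stopifnot(inherits(cohort, "bp_cohort"))
  patients <- cohort$patients
  cutoff <- cohort$telemonitoring_start
  if (is.null(observation_end)) {
    observation_end <- suppressWarnings(max(cohort$readings$date))
  }
  observation_end <- as.Date(observation_end)

  eligible <- cohort$readings %>%
    inner_join(select(patients, "patient_id", "group"), by = "patient_id") %>%
    filter(.data$date >= cutoff,
           (.data$group == "telemonitoring" &
              .data$source == "telemonitored") |
             (.data$group == "comparator" & .data$source == "surgery")) %>%
    arrange(.data$patient_id, .data$date)

  # within-patient chronological rank (eligible is sorted by patient, date)
  rank_in_patient <- if (nrow(eligible) == 0) integer(0) else
    sequence(rle(eligible$patient_id)$lengths)
  index <- eligible %>%
    filter((.data$group == "telemonitoring" & rank_in_patient == 2L) |
             (.data$group == "comparator" & rank_in_patient == 1L)) %>%
    select("patient_id", baseline_date = "date", baseline_sbp = "systolic",
           baseline_dbp = "diastolic")

  full_year <- filter(index,
                      .data$baseline_date + 365 <= observation_end)

  final <- eligible %>%
    inner_join(select(full_year, "patient_id", "baseline_date"),
               by = "patient_id") %>%
    mutate(.offset = as.numeric(.data$date - .data$baseline_date)) %>%
    filter(.data$.offset >= window[1], .data$.offset <= window[2]) %>%
    arrange(.data$patient_id, abs(.data$.offset - 365), -.data$.offset)
  final <- final[!duplicated(final$patient_id), , drop = FALSE] %>%
    select("patient_id", final_date = "date", final_sbp = "systolic",
           final_dbp = "diastolic")

  records <- full_year %>%
    inner_join(final, by = "patient_id") %>%
    inner_join(patients, by = "patient_id") %>%
    mutate(sbp_diff = .data$baseline_sbp - .data$final_sbp,
           dbp_diff = .data$baseline_dbp - .data$final_dbp,
           age_2015 = 2015 - .data$year_of_birth,
           simd5plus = .data$simd_decile >= 5) %>%
    select("patient_id", "practice_id", "group", "sex", "year_of_birth",
           "simd_decile", "age_2015", "simd5plus",
           "baseline_date", "final_date",
           "baseline_sbp", "final_sbp", "baseline_dbp", "final_dbp",
           "sbp_diff", "dbp_diff")

  flow <- tibble(
    step = c("patients",
             "with eligible readings after cutoff",
             "with an index reading",
             "with a full year of potential follow-up",
             "with a final reading 6-12 months later"),
    n = c(nrow(patients),
          n_distinct(eligible$patient_id),
          nrow(index),
          nrow(full_year),
          nrow(records))
  )
  structure(records, flow = flow,
            class = c("bp_standardised", class(records)))
}

#' Attrition flow report of a standardised dataset
#'
#' @param records A `bp_standardised` tibble.
#' @return A tibble of processing step and patient count (monotone
#'   non-increasing).
#' @export
flow_report <- function(records) {
  attr(records, "flow")
}

#' Shift comparator readings for an assumed white-coat effect
#'
#' Subtracts `delta` mmHg from the systolic and diastolic values (baseline
#' and final) of comparator patients in a standardised dataset; BP
#' differences are recomputed (they are unchanged, since the shift cancels in
#' baseline minus final, but threshold-based stratum membership changes).
#'
#' @param records A `bp_standardised` tibble.
#' @param delta White-coat adjustment in mmHg (applied as a reduction).
#' @return The adjusted records.
#' @export
adjust_white_coat <- function(records, delta = 5) {
  stopifnot(delta >= 0)
  comp <- records$group == "comparator"
  for (col in c("baseline_sbp", "final_sbp", "baseline_dbp", "final_dbp")) {
    records[[col]][comp] <- records[[col]][comp] - delta
  }
  records$sbp_diff <- records$baseline_sbp - records$final_sbp
  records$dbp_diff <- records$baseline_dbp - records$final_dbp
  records
}
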