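# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

make_readings <- function(patient_id = "p1",
                          date = as.Date("2016-01-01"),
                          source = "surgery",
                          systolic = 130L, diastolic = 80L) {
  tibble::tibble(patient_id = patient_id, date = as.Date(date),
                 source = source, systolic = as.integer(systolic),
                 diastolic = as.integer(diastolic))
}

make_patients <- function(patient_id = "p1", practice_id = "A",
                          sex = "male", year_of_birth = 1950L,
                          simd_decile = 6L, group = "comparator") {
  tibble::tibble(patient_id = patient_id, practice_id = practice_id,
                 sex = sex, year_of_birth = as.integer(year_of_birth),
                 simd_decile = as.integer(simd_decile), group = group)
}

# A deterministic hand-sized cohort: one telemonitoring patient with weekly
# home readings, one comparator with sparse surgery readings.
tiny_cohort <- function() {
  tm_dates <- as.Date("2015-10-01") + seq(0, 364, by = 7)
  readings <- dplyr::bind_rows(
    make_readings("t1", tm_dates, "telemonitored",
                  systolic = 150L - seq_along(tm_dates),
                  diastolic = 90L - (seq_along(tm_dates) %/% 4)),
    make_readings("c1", as.Date(c("2015-09-10", "2016-03-10", "2016-08-20")),
                  "surgery", c(145L, 142L, 140L), c(88L, 86L, 85L))
  )
  patients <- dplyr::bind_rows(
    make_patients("t1", "A", "female", 1955L, 7L, "telemonitoring"),
    make_patients("c1", "A", "male", 1948L, 4L, "comparator")
  )
  bp_cohort(patients, readings)
}

# Small null-scenario simulation config used by several fast tests.
fast_config <- function(seed, n_patients = 300, ...) {
  args <- utils::modifyList(
    list(n_patients = n_patients, n_practices = 4, seed = seed,
         telemon_rate = 0.5,
         enrolment_end = as.Date("2015-10-31"),
         followup_end = as.Date("2016-12-31")),
    list(...))
  do.call(sim_config, args)
}

null_config <- function(seed, n_patients = 400, ...) {
  fast_config(
    seed, n_patients = n_patients, n_practices = 8,
    intervention_slope_effect = 0,
    dropout_base_hazard = 0,
    selection_coefficients = c(intercept = 0, age = 0, simd = 0,
                               baseline = 0),
    ...
  )
}

# Standardised-record rows built directly (bypassing cohort machinery) for
# analysis-level tests that want full control of covariates.
make_records <- function(n_per_group = 60, seed = 1,
                         telemon_final_shift = 0,
                         comparator_offset = 0) {
  set.seed(seed)
  n <- 2 * n_per_group
  group <- rep(c("telemonitoring", "comparator"), each = n_per_group)
  base <- round(rnorm(n, 140, 12))
  fin <- round(base + rnorm(n, 0, 8)) +
    ifelse(group == "telemonitoring", telemon_final_shift, 0)
  off <- ifelse(group == "comparator", comparator_offset, 0)
  tibble::tibble(
    patient_id = sprintf("r%03d", seq_len(n)),
    practice_id = sample(c("A", "B", "C"), n, replace = TRUE),
    group = group,
    sex = sample(c("male", "female"), n, replace = TRUE),
    year_of_birth = sample(1930:1990, n, replace = TRUE),
    simd_decile = sample(1:10, n, replace = TRUE),
    age_2015 = 2015 - year_of_birth,
    simd5plus = simd_decile >= 5,
    baseline_date = as.Date("2015-10-01") + sample(0:60, n, replace = TRUE),
    final_date = baseline_date + sample(183:365, n, replace = TRUE),
    baseline_sbp = base + off,
    final_sbp = fin + off,
    baseline_dbp = round(0.6 * base) + off,
    final_dbp = round(0.6 * fin) + off,
    sbp_diff = baseline_sbp - final_sbp,
    dbp_diff = baseline_dbp - final_dbp
  )
}
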