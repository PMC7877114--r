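#' Simulation configuration for synthetic telemonitoring cohorts
#'
#' Builds the configuration for [simulate_cohort()]. The generator emulates
#' the main bias mechanisms of a non-randomised telemonitoring roll-out:
#' confounded enrolment (selection on age, deprivation and latent BP),
#' latent linear BP trajectories with random intercepts and slopes, a fixed
#' white-coat offset added to surgery readings, source-specific end-digit
#' rounding (strong double-zero preference in surgery readings, weak in
#' telemonitored ones), much denser telemonitored reading schedules,
#' BP-dependent withdrawal from telemonitoring, and independent Gaussian
#' measurement error.
#'
#' Defaults are calibrated to the marginal characteristics of a routine
#' primary-care hypertension population (mean age about 68, ~53% female,
#' index systolic around 140 mmHg, ~10% of patients enrolled in
#' telemonitoring, double-zero prevalence ~11% in surgery readings and ~2%
#' in telemonitored readings).
#'
#' @param n_patients Number of patients.
#' @param n_practices Number of GP practices (patients assigned uniformly).
#' @param enrolment_start,enrolment_end Enrolment window: each patient's
#'   study entry date is uniform in this window.
#' @param followup_end Last possible observation date.
#' @param intercept_mean,intercept_sd Latent baseline systolic BP (mmHg) at
#'   study entry.
#' @param slope_mean,slope_sd Latent systolic drift (mmHg/week).
#' @param intervention_slope_effect True additional slope (mmHg/week) for
#'   telemonitoring patients from enrolment; the recovery target.
#' @param white_coat_offset mmHg added to every surgery-source reading.
#' @param measurement_sd Per-reading Gaussian error SD (mmHg).
#' @param selection_coefficients Named numeric vector `c(intercept, age,
#'   simd, baseline)`: log-odds of telemonitoring enrolment is
#'   `intercept + age*(age-65) + simd*(simd-5.5) + baseline*(latentBP-140)`.
#' @param selection_noise_sd SD of noise added to the latent baseline before
#'   it enters the selection model (selection on noisy baselines produces
#'   regression to the mean downstream); default 0 (selection on the true
#'   latent value).
#' @param telemon_rate Expected telemonitored readings per week.
#' @param surgery_rate Expected surgery readings per year (all patients;
#'   telemonitoring patients keep visiting the practice).
#' @param history_weeks Weeks of pre-enrolment surgery history generated per
#'   patient (feeds the prior-reading-count adjustment of the longitudinal
#'   model).
#' @param dropout_base_hazard Baseline weekly withdrawal hazard for
#'   telemonitoring patients.
#' @param dropout_coefficient Per-mmHg increase in the weekly withdrawal
#'   log-hazard with current latent systolic (centred at 140 mmHg).
#' @param surgery_round_probs,telemon_round_probs Length-3 probability
#'   vectors (round to nearest 10, nearest 5, none); the same draw is applied
#'   jointly to systolic and diastolic, which is what yields the double-zero
#'   preference.
#' @param diastolic_ratio,diastolic_sd Diastolic = ratio * systolic +
#'   Gaussian(0, sd), with the same rounding draw.
#' @param age_mean,age_sd,female_prob,simd_weights Demographic marginals:
#'   approximate age in 2015 (truncated to 18-90), probability of female sex,
#'   and sampling weights over SIMD deciles 1-10.
#' @param seed Integer seed; the simulation is deterministic given the seed.
#' @return A `bp_sim_config` list.
#' @export
sim_config <- function(n_patients = 4000,
                       n_practices = 8,
                       enrolment_start = as.Date("2015-09-01"),
                       enrolment_end = as.Date("2016-02-29"),
                       followup_end = as.Date("2017-08-31"),
                       intercept_mean = 140, intercept_sd = 12,
                       slope_mean = -0.07, slope_sd = 0.05,
                       intervention_slope_effect = -0.065,
                       white_coat_offset = 5,
                       measurement_sd = 11,
                       selection_coefficients = c(intercept = -2.35,
                                                  age = -0.06,
                                                  simd = 0.20,
                                                  baseline = -0.01),
                       selection_noise_sd = 0,
                       telemon_rate = 1.0,
                       surgery_rate = 4,
                       history_weeks = 52,
                       dropout_base_hazard = 0.001,
                       dropout_coefficient = 0.02,
                       surgery_round_probs = c(0.09, 0.06, 0.85),
                       telemon_round_probs = c(0.005, 0.01, 0.985),
                       diastolic_ratio = 0.60, diastolic_sd = 6,
                       age_mean = 68, age_sd = 12,
                       female_prob = 0.53,
                       simd_weights = c(2, 3, 4, 5, 6, 8, 10, 11, 12, 13),
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$enrolment_start <- as.Date(enrolment_start)
  cfg$enrolment_end <- as.Date(enrolment_end)
  cfg$followup_end <- as.Date(followup_end)
  validate_sim_config(cfg)
  structure(cfg, class = "bp_sim_config")
}

validate_sim_config <- function(cfg) {
  problems <- character(0)
  bad <- function(field, msg) sprintf("%s: %s", field, msg)
  if (cfg$n_patients < 1) problems <- c(problems, bad("n_patients", "must be >= 1"))
  if (cfg$n_practices < 1) problems <- c(problems, bad("n_practices", "must be >= 1"))
  if (cfg$enrolment_end < cfg$enrolment_start)
    problems <- c(problems, bad("enrolment_end", "precedes enrolment_start"))
  if (cfg$followup_end < cfg$enrolment_end)
    problems <- c(problems, bad("followup_end", "precedes enrolment_end"))
  for (f in c("intercept_sd", "slope_sd", "measurement_sd", "diastolic_sd",
              "selection_noise_sd", "age_sd")) {
    if (cfg[[f]] < 0) problems <- c(problems, bad(f, "must be >= 0"))
  }
  for (f in c("telemon_rate", "surgery_rate")) {
    if (cfg[[f]] <= 0) problems <- c(problems, bad(f, "must be > 0"))
  }
  for (f in c("surgery_round_probs", "telemon_round_probs")) {
    p <- cfg[[f]]
    if (length(p) != 3 || any(p < 0) || any(p > 1) ||
        abs(sum(p) - 1) > 1e-8) {
      problems <- c(problems, bad(f, "must be 3 probabilities summing to 1"))
    }
  }
  if (!all(c("intercept", "age", "simd", "baseline") %in%
           names(cfg$selection_coefficients))) {
    problems <- c(problems,
                  bad("selection_coefficients",
                      "needs named elements intercept, age, simd, baseline"))
  }
  if (cfg$dropout_base_hazard < 0)
    problems <- c(problems, bad("dropout_base_hazard", "must be >= 0"))
  if (length(problems) > 0) {
    abort(paste(c("invalid simulation config:", problems), collapse = "\n  "))
  }
  invisible(cfg)
}

#' Assign study groups by confounded enrolment
#'
#' Draws telemonitoring membership with probability
#' `plogis(intercept + age*(age-65) + simd*(simd-5.5) + baseline*(bp-140))`
#' using the `selection_coefficients` of the config. Uses the current RNG
#' state (seeded by [simulate_cohort()]).
#'
#' @param latent_baselines Per-patient latent baseline systolic (mmHg),
#'   possibly noise-contaminated.
#' @param age,simd Per-patient covariates.
#' @param config A [sim_config()].
#' @return Character vector of `"telemonitoring"`/`"comparator"` labels.
#' @export
assign_groups <- function(latent_baselines, age, simd, config) {
  p <- selection_probability(latent_baselines, age, simd, config)
  ifelse(runif(length(p)) < p, "telemonitoring", "comparator")
}

selection_probability <- function(latent_baselines, age, simd, config) {
  b <- config$selection_coefficients
  plogis(b[["intercept"]] + b[["age"]] * (age - 65) +
           b[["simd"]] * (simd - 5.5) +
           b[["baseline"]] * (latent_baselines - 140))
}

#' Simulate a synthetic telemonitoring cohort with ground truth
#'
#' Generates a [bp_cohort()] plus the latent ground truth used to create it.
#' Per patient: a latent linear systolic trajectory `intercept + slope * t`
#' (weeks since study entry), shifted by `intervention_slope_effect * t`
#' from enrolment for telemonitoring patients. Each emitted reading is the
#' latent value, plus the white-coat offset if surgery-sourced, plus Gaussian
#' measurement error, then end-digit rounding (nearest 10 / nearest 5 / none,
#' drawn per reading with source-specific probabilities and applied jointly
#' to systolic and diastolic), then integer truncation. Reading times follow
#' homogeneous Poisson processes (telemonitored at `telemon_rate`/week from
#' enrolment; surgery at `surgery_rate`/year from `history_weeks` before
#' enrolment). Telemonitoring patients may withdraw: the weekly hazard is
#' `dropout_base_hazard * exp(dropout_coefficient * (latent - 140))`, and no
#' readings are emitted after the dropout week.
#'
#' @param config A [sim_config()].
#' @return A list with `cohort` (a `bp_cohort`) and `truth` (a tibble with
#'   `patient_id`, `latent_intercept`, `latent_slope`, `group`,
#'   `dropout_week`, `enrol_date`, `selection_prob`); the true slope effect
#'   is attached as `attr(truth, "intervention_slope_effect")`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "bp_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients

  # demographics
  age <- round(rnorm(n, config$age_mean, config$age_sd))
  age <- pmin(pmax(age, 18), 90)
  yob <- 2015L - as.integer(age)
  sex <- ifelse(runif(n) < config$female_prob, "female", "male")
  simd <- sample(1:10, n, replace = TRUE, prob = config$simd_weights)
  practice <- sprintf("P%02d", sample.int(config$n_practices, n, replace = TRUE))
  pid <- sprintf("S%05d", seq_len(n))

  # latent trajectories and enrolment
  a <- rnorm(n, config$intercept_mean, config$intercept_sd)
  b <- rnorm(n, config$slope_mean, config$slope_sd)
  window_days <- as.integer(config$enrolment_end - config$enrolment_start)
  enrol <- config$enrolment_start +
    floor(runif(n, 0, window_days + 1))

  sel_baseline <- a + rnorm(n, 0, config$selection_noise_sd)
  sel_prob <- selection_probability(sel_baseline, age, simd, config)
  group <- ifelse(runif(n) < sel_prob, "telemonitoring", "comparator")
  is_tm <- group == "telemonitoring"
  delta <- ifelse(is_tm, config$intervention_slope_effect, 0)

  # BP-dependent withdrawal (telemonitoring patients only): first week w with
  # a positive Bernoulli draw under the current-latent-BP hazard.
  max_weeks <- ceiling(as.numeric(config$followup_end - min(enrol)) / 7)
  dropout_week <- rep(NA_real_, n)
  if (config$dropout_base_hazard > 0 && any(is_tm)) {
    idx <- which(is_tm)
    alive <- rep(TRUE, length(idx))
    for (w in seq_len(max_weeks)) {
      latent_w <- a[idx] + (b[idx] + delta[idx]) * w
      h <- pmin(config$dropout_base_hazard *
                  exp(config$dropout_coefficient * (latent_w - 140)), 1)
      drop_now <- alive & (runif(length(idx)) < h)
      dropout_week[idx[drop_now]] <- w
      alive <- alive & !drop_now
      if (!any(alive)) break
    }
  }
  # last date on which the patient emits readings
  end_date <- rep(config$followup_end, n)
  has_drop <- !is.na(dropout_week)
  end_date[has_drop] <- pmin(end_date[has_drop],
                             enrol[has_drop] + round(dropout_week[has_drop] * 7))

  surgery <- poisson_readings(
    pid, start = enrol - round(config$history_weeks * 7), end = end_date,
    rate_per_day = config$surgery_rate / 365.25
  )
  telemon <- poisson_readings(
    pid[is_tm], start = enrol[is_tm], end = end_date[is_tm],
    rate_per_day = config$telemon_rate / 7
  )
  readings <- bind_rows(
    mutate(surgery, source = "surgery"),
    mutate(telemon, source = "telemonitored")
  )

  ord <- match(readings$patient_id, pid)
  t_weeks <- as.numeric(readings$date - enrol[ord]) / 7
  latent <- a[ord] + b[ord] * t_weeks + delta[ord] * pmax(t_weeks, 0)
  sys_raw <- latent +
    config$white_coat_offset * (readings$source == "surgery") +
    rnorm(nrow(readings), 0, config$measurement_sd)
  dia_raw <- config$diastolic_ratio * sys_raw +
    rnorm(nrow(readings), 0, config$diastolic_sd)

  probs <- rbind(config$surgery_round_probs, config$telemon_round_probs)
  mode_p <- probs[ifelse(readings$source == "surgery", 1L, 2L), , drop = FALSE]
  u <- runif(nrow(readings))
  mode <- ifelse(u < mode_p[, 1], 10L, ifelse(u < mode_p[, 1] + mode_p[, 2], 5L, 1L))
  readings$systolic <- as.integer(round_end_digit(sys_raw, mode))
  readings$diastolic <- as.integer(round_end_digit(dia_raw, mode))

  readings <- readings %>%
    select("patient_id", "date", "source", "systolic", "diastolic") %>%
    arrange(.data$patient_id, .data$date, .data$source)

  patients <- tibble(
    patient_id = pid, practice_id = practice, sex = sex,
    year_of_birth = yob, simd_decile = as.integer(simd), group = group
  )
  truth <- tibble(
    patient_id = pid, latent_intercept = a, latent_slope = b,
    group = group, dropout_week = dropout_week,
    enrol_date = enrol, selection_prob = sel_prob
  )
  attr(truth, "intervention_slope_effect") <- config$intervention_slope_effect

  cohort <- suppressWarnings(
    bp_cohort(patients, readings,
              telemonitoring_start = config$enrolment_start)
  )
  list(cohort = cohort, truth = truth)
}

# Homogeneous Poisson process per patient over [start, end] (by day),
# vectorised over patients. Returns patient_id + date rows.
poisson_readings <- function(pid, start, end, rate_per_day) {
  n_days <- pmax(as.numeric(end - start) + 1, 0)
  counts <- rpois(length(pid), rate_per_day * n_days)
  total <- sum(counts)
  if (total == 0) {
    return(tibble(patient_id = character(0), date = as.Date(character(0))))
  }
  id <- rep(pid, counts)
  s <- rep(start, counts)
  nd <- rep(n_days, counts)
  tibble(patient_id = id, date = s + floor(runif(total, 0, nd)))
}

# Round to the nearest multiple of `mode` (10, 5, or 1 = truncate only),
# then truncate to integer.
round_end_digit <- function(x, mode) {
  out <- trunc(x)
  r10 <- mode == 10L
  r5 <- mode == 5L
  out[r10] <- round(x[r10] / 10) * 10
  out[r5] <- round(x[r5] / 5) * 5
  out
}
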