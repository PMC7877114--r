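test_that("noiseless flat configuration emits the latent intercept verbatim", {
  cfg <- fast_config(1, n_patients = 40,
                     measurement_sd = 0, white_coat_offset = 0,
                     slope_mean = 0, slope_sd = 0,
                     intervention_slope_effect = 0,
                     diastolic_sd = 0,
                     surgery_round_probs = c(0, 0, 1),
                     telemon_round_probs = c(0, 0, 1),
                     dropout_base_hazard = 0)
  sim <- simulate_cohort(cfg)
  truth <- sim$truth
  joined <- dplyr::left_join(sim$cohort$readings, truth, by = "patient_id")
  expect_equal(joined$systolic, as.integer(trunc(joined$latent_intercept)))
})

test_that("forced rounding drives every surgery end digit to zero", {
  cfg <- fast_config(2, n_patients = 60,
                     surgery_round_probs = c(1, 0, 0),
                     dropout_base_hazard = 0)
  sim <- simulate_cohort(cfg)
  surgery <- dplyr::filter(sim$cohort$readings, source == "surgery")
  expect_true(all(surgery$systolic %% 10 == 0))
  expect_true(all(surgery$diastolic %% 10 == 0))
})

test_that("simulation is deterministic in the seed and varies across seeds", {
  a <- simulate_cohort(fast_config(11, n_patients = 80))
  b <- simulate_cohort(fast_config(11, n_patients = 80))
  c <- simulate_cohort(fast_config(12, n_patients = 80))
  expect_identical(a$cohort$readings, b$cohort$readings)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$cohort$readings$date, c$cohort$readings$date))
})

test_that("group assignment follows the closed-form logistic probabilities", {
  cfg <- fast_config(3)
  # symmetric null: all coefficients zero => 50% enrolment
  cfg0 <- fast_config(3, n_patients = 10000,
                      selection_coefficients = c(intercept = 0, age = 0,
                                                 simd = 0, baseline = 0))
  set.seed(99)
  g <- assign_groups(rnorm(10000, 140, 12), rep(65, 10000), rep(5, 10000),
                     cfg0)
  expect_equal(mean(g == "telemonitoring"), 0.5, tolerance = 0.04)

  # saturation: huge coefficient on baseline BP splits at the midpoint
  cfg_sat <- fast_config(3, selection_coefficients = c(
    intercept = 0, age = 0, simd = 0, baseline = 50))
  set.seed(100)
  bp <- c(rep(120, 500), rep(160, 500))
  g <- assign_groups(bp, rep(65, 1000), rep(5, 1000), cfg_sat)
  expect_true(all(g[bp > 140] == "telemonitoring"))
  expect_true(all(g[bp < 140] == "comparator"))

  # moderate coefficients: empirical frequencies match plogis() oracle
  cfg_mod <- fast_config(3, selection_coefficients = c(
    intercept = -0.5, age = -0.05, simd = 0.2, baseline = -0.02))
  set.seed(101)
  n <- 40000
  age <- sample(40:90, n, TRUE); simd <- sample(1:10, n, TRUE)
  bp <- rnorm(n, 140, 12)
  g <- assign_groups(bp, age, simd, cfg_mod)
  p_oracle <- plogis(-0.5 - 0.05 * (age - 65) + 0.2 * (simd - 5.5) -
                       0.02 * (bp - 140))
  # bin by oracle probability and compare observed enrolment frequency
  bins <- cut(p_oracle, breaks = seq(0, 1, 0.1))
  obs <- tapply(g == "telemonitoring", bins, mean)
  exp_p <- tapply(p_oracle, bins, mean)
  keep <- !is.na(obs) & table(bins) > 500
  expect_true(all(abs(obs[keep] - exp_p[keep]) < 0.03))
})

test_that("selection on latent BP separates group baselines in the configured direction", {
  cfg <- sim_config(n_patients = 5000, seed = 5,
                    telemon_rate = 0.5,
                    selection_coefficients = c(intercept = 0, age = 0,
                                               simd = 0, baseline = 0.08))
  truth <- simulate_cohort(cfg)$truth
  means <- tapply(truth$latent_intercept, truth$group, mean)
  expect_gt(means[["telemonitoring"]], means[["comparator"]] + 2)
})

test_that("white-coat offset appears as the surgery-minus-home gap at equal latent BP", {
  # flat trajectories, no rounding: gap is estimable directly per patient
  cfg <- fast_config(6, n_patients = 400,
                     slope_mean = 0, slope_sd = 0,
                     intervention_slope_effect = 0,
                     white_coat_offset = 5,
                     surgery_round_probs = c(0, 0, 1),
                     telemon_round_probs = c(0, 0, 1),
                     dropout_base_hazard = 0,
                     selection_coefficients = c(intercept = 2, age = 0,
                                                simd = 0, baseline = 0))
  sim <- simulate_cohort(cfg)
  per <- sim$cohort$readings %>%
    dplyr::semi_join(dplyr::filter(sim$cohort$patients,
                                   group == "telemonitoring"),
                     by = "patient_id") %>%
    dplyr::group_by(patient_id, source) %>%
    dplyr::summarise(m = mean(systolic), n = dplyr::n(), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = source, values_from = c(m, n))
  per <- dplyr::filter(per, n_surgery >= 2, n_telemonitored >= 2)
  gap <- mean(per$m_surgery - per$m_telemonitored)
  expect_equal(gap, 5, tolerance = 1)
})

test_that("double-zero preference is stronger in surgery than telemonitored readings", {
  sim <- simulate_cohort(sim_config(n_patients = 1500, seed = 7,
                                    telemon_rate = 0.5))
  surgery <- dplyr::filter(sim$cohort$readings, source == "surgery")
  telemon <- dplyr::filter(sim$cohort$readings, source == "telemonitored")
  dz <- function(x) end_digit_table(x)$double_zero_pct
  expect_gt(dz(surgery), dz(telemon))
  expect_gt(dz(surgery), 5)   # far above the 1% chance level
})

test_that("BP-dependent withdrawal removes higher-baseline patients", {
  cfg <- sim_config(n_patients = 4000, seed = 8, telemon_rate = 0.5,
                    dropout_base_hazard = 0.004, dropout_coefficient = 0.04,
                    selection_coefficients = c(intercept = 0, age = 0,
                                               simd = 0, baseline = 0))
  truth <- simulate_cohort(cfg)$truth
  tm <- dplyr::filter(truth, group == "telemonitoring")
  dropped <- !is.na(tm$dropout_week)
  expect_gt(sum(dropped), 50)
  expect_gt(mean(tm$latent_intercept[dropped]),
            mean(tm$latent_intercept[!dropped]))
  # no readings after the dropout week
  sim <- simulate_cohort(cfg)
  last <- sim$cohort$readings %>%
    dplyr::group_by(patient_id) %>%
    dplyr::summarise(last = max(date), .groups = "drop") %>%
    dplyr::inner_join(dplyr::filter(sim$truth, !is.na(dropout_week)),
                      by = "patient_id")
  expect_true(all(as.numeric(last$last - last$enrol_date) / 7 <=
                    last$dropout_week + 1e-9))
})

test_that("invalid configuration fields are named individually", {
  expect_error(sim_config(measurement_sd = -1), "measurement_sd")
  expect_error(sim_config(surgery_round_probs = c(0.5, 0.5, 0.5)),
               "surgery_round_probs")
  expect_error(sim_config(telemon_rate = 0), "telemon_rate")
  err <- tryCatch(sim_config(measurement_sd = -1, telemon_rate = -2),
                  error = conditionMessage)
  expect_match(err, "measurement_sd")
  expect_match(err, "telemon_rate")
})
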