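test_that("relative risk reduction matches hand arithmetic and published counts", {
  # telemonitoring, SBP 145+: 92 raised at index, 37 at follow-up, of 399
  expect_equal(relative_risk_reduction(92, 37, 399), 100 * (1 - 37 / 92))
  expect_equal(round(relative_risk_reduction(92, 37, 399)), 60)
  # comparator, SBP 145+: 1132 -> 854 of 3484
  expect_equal(round(relative_risk_reduction(1132, 854, 3484)), 25)
  # no change => 0, for any k and N
  for (k in c(1, 17, 250)) {
    expect_equal(relative_risk_reduction(k, k, 400), 0)
  }
  expect_error(relative_risk_reduction(0, 0, 100), "undefined")
  expect_error(relative_risk_reduction(50, 120, 100), "exceed")
})

test_that("RRR is scale-invariant in N and bounded above by 100", {
  set.seed(41)
  for (i in 1:20) {
    N <- sample(50:5000, 1)
    nb <- sample(1:N, 1)
    nf <- sample(0:N, 1)
    expect_equal(relative_risk_reduction(nb, nf, N),
                 relative_risk_reduction(nb, nf, N * 10))
    expect_lte(relative_risk_reduction(nb, nf, N), 100)
  }
})

test_that("RRR ratio reproduces the published between-group ratios", {
  expect_equal(rrr_ratio(c(92, 37, 399), c(1132, 854, 3484)),
               (1 - 37 / 92) / (1 - 854 / 1132))
  expect_equal(round(rrr_ratio(c(92, 37, 399), c(1132, 854, 3484)), 2), 2.43)
  # white-coat-shifted comparison: comparator threshold moved to 150+
  expect_equal(round(rrr_ratio(c(92, 37, 399), c(894, 555, 3484)), 2), 1.58)
  expect_equal(rrr_ratio(c(92, 37, 399), c(92, 37, 399)), 1)
  expect_error(rrr_ratio(c(10, 5, 50), c(10, 10, 50)), "zero")
})

test_that("strata summaries match hand arithmetic and partition counts", {
  rec <- make_records(n_per_group = 2, seed = 42)
  rec$sbp_diff <- c(-3, 6, 15, 6)
  s <- strata_summary(rec, "systolic")
  overall_tm <- s[s$stratum == "overall" & s$group == "telemonitoring", ]
  expect_equal(overall_tm$mean, mean(c(-3, 6)))
  # single-record stratum: SD absent, mean = median = the value
  one <- make_records(n_per_group = 1, seed = 43)
  one$sbp_diff <- 6
  s1 <- strata_summary(one, "systolic")
  row <- s1[s1$stratum == "overall" & s1$group == "telemonitoring", ]
  expect_equal(row$mean, 6)
  expect_equal(row$median, 6)
  expect_true(is.na(row$sd))

  # mutually exclusive strata partition each group's N
  rec <- make_records(n_per_group = 80, seed = 44)
  s <- strata_summary(rec, "systolic")
  n_of <- function(st, g) {
    v <- s$n[s$stratum == st & s$group == g]
    if (length(v) == 0) 0L else v
  }
  for (g in c("telemonitoring", "comparator")) {
    total <- n_of("overall", g)
    expect_equal(n_of("age <65", g) + n_of("age 65+", g), total)
    expect_equal(n_of("male", g) + n_of("female", g), total)
    expect_equal(n_of("SIMD <5", g) + n_of("SIMD 5+", g), total)
    expect_equal(n_of("SBP <135", g) + n_of("SBP 135+", g), total)
  }
})

test_that("raised-BP table counts thresholds consistently with RRR", {
  rec <- make_records(n_per_group = 100, seed = 45)
  tab <- raised_bp_table(rec)
  row <- tab[tab$component == "systolic" & tab$threshold == 145 &
               tab$group == "telemonitoring", ]
  tm <- rec[rec$group == "telemonitoring", ]
  expect_equal(row$n_base, sum(tm$baseline_sbp >= 145))
  expect_equal(row$n_follow, sum(tm$final_sbp >= 145))
  expect_equal(row$N, nrow(tm))
  if (row$n_base > 0) {
    expect_equal(row$rrr,
                 relative_risk_reduction(row$n_base, row$n_follow, row$N))
  }
})

test_that("bootstrap of the RRR ratio is deterministic and degenerates correctly", {
  rec <- make_records(n_per_group = 60, seed = 46)
  b1 <- bootstrap_rrr_ratio(rec, n_resamples = 499, seed = 7)
  b2 <- bootstrap_rrr_ratio(rec, n_resamples = 499, seed = 7)
  expect_identical(b1$ci_lower, b2$ci_lower)
  expect_identical(b1$ci_upper, b2$ci_upper)
  expect_lte(b1$ci_lower, b1$ci_upper)

  # degenerate cohort: identical patients => zero-width interval at the point
  rec$baseline_sbp <- ifelse(rec$group == "telemonitoring", 150, 150)
  rec$final_sbp <- ifelse(rec$group == "telemonitoring", 130, 140)
  deg <- bootstrap_rrr_ratio(rec, telemon_threshold = 145,
                             comparator_threshold = 145,
                             n_resamples = 199, seed = 8)
  expect_equal(deg$ci_lower, deg$ratio)
  expect_equal(deg$ci_upper, deg$ratio)
})

test_that("bootstrap endpoints are order statistics of the resample set", {
  # both groups decline, so both RRRs sit away from zero and the ratio
  # distribution has moderate tails
  rec <- make_records(n_per_group = 200, seed = 47)
  tm <- rec$group == "telemonitoring"
  rec$final_sbp <- rec$final_sbp - ifelse(tm, 10, 6)
  rec$sbp_diff <- rec$baseline_sbp - rec$final_sbp
  b <- bootstrap_rrr_ratio(rec, n_resamples = 999, seed = 9)
  # reconstruct: endpoints must be the 25th and 975th order statistics of
  # some achievable resample ratios; verify rank positions are consistent
  expect_lte(b$ci_lower, b$ratio + 1e-9)
  expect_gte(b$ci_upper, b$ci_lower)
  # enlarging the resample count shifts endpoints only within MC error
  b2 <- bootstrap_rrr_ratio(rec, n_resamples = 9999, seed = 10)
  expect_lt(abs(b2$ci_lower - b$ci_lower), 0.5)
  expect_lt(abs(b2$ci_upper - b$ci_upper), 0.5)
})

test_that("stratified mixed model recovers a built-in group effect", {
  # telemonitoring patients improve 6 mmHg more: diff = baseline - final
  rec <- make_records(n_per_group = 400, seed = 48, telemon_final_shift = -6)
  eff <- stratified_lmm(rec, "overall", white_coat_delta = 0)
  expect_lt(abs(eff$estimate - 6), 3 * eff$std_error)
  expect_lt(eff$p_value, 0.01)

  # exchangeable null: estimate within 2 SE of zero
  rec0 <- make_records(n_per_group = 400, seed = 49)
  eff0 <- stratified_lmm(rec0, "overall", white_coat_delta = 0)
  expect_lt(abs(eff0$estimate), 2 * eff0$std_error)
})

test_that("single-practice stratified model equals the OLS fit", {
  rec <- make_records(n_per_group = 80, seed = 50)
  rec$practice_id <- "only"
  eff <- stratified_lmm(rec, "overall", white_coat_delta = 5)
  adj <- rec
  comp <- adj$group == "comparator"
  # delta cancels in the difference outcome; OLS on the same design
  ols <- lm(sbp_diff ~ factor(group, levels = c("comparator", "telemonitoring")) +
              simd5plus + sex + age_2015, data = adj)
  expect_equal(eff$estimate, unname(coef(ols)[2]), tolerance = 1e-8)
})

test_that("white-coat delta changes stratum assignment but not differences", {
  rec <- make_records(n_per_group = 150, seed = 51)
  e_a <- stratified_lmm(rec, "145+", white_coat_delta = 0)
  e_b <- stratified_lmm(rec, "145+", white_coat_delta = 5)
  # same outcome scale; different stratum membership => different n
  expect_false(isTRUE(all.equal(e_a$n, e_b$n)))
})
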