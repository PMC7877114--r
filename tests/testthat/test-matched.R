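test_that("white-coat adjustment is a pure additive shift", {
  r <- make_readings(systolic = 145L, diastolic = 90L)
  adj <- white_coat_adjust(r, 5)
  expect_equal(adj$systolic, 140)
  expect_equal(adj$diastolic, 85)
  expect_equal(adj$date, r$date)
  expect_equal(white_coat_adjust(r, 0), r)
  expect_equal(white_coat_adjust(white_coat_adjust(r, 3), 2),
               white_coat_adjust(r, 5))
  expect_error(white_coat_adjust(r, -1))
})

test_that("systolic gridding matches enumeration of grid distances", {
  expect_equal(grid_sbp(132, "nearest_0_or_5"), 130)
  expect_equal(grid_sbp(133, "nearest_0_or_5"), 135)
  expect_equal(grid_sbp(138, "nearest_0_or_5"), 140)
  expect_equal(grid_sbp(135, "nearest_0"), 140)  # distance-5 tie rounds up
  expect_equal(grid_sbp(144, "nearest_0"), 140)
  expect_equal(grid_sbp(146, "exact"), 146)
  # oracle: nearest multiple by explicit distance enumeration
  grid5 <- seq(50, 300, by = 5)
  grid10 <- seq(50, 300, by = 10)
  for (x in 97:203) {
    d5 <- abs(grid5 - x)
    expect_equal(grid_sbp(x, "nearest_0_or_5"),
                 max(grid5[d5 == min(d5)]))  # max: ties (none for ints) up
    d10 <- abs(grid10 - x)
    expect_equal(grid_sbp(x, "nearest_0"), max(grid10[d10 == min(d10)]))
  }
})

test_that("age decades floor correctly", {
  expect_equal(age_decade(64), "60s")
  expect_equal(age_decade(70), "70s")
  expect_equal(age_decade(29), "20s")
  expect_equal(age_decade(c(18, 45, 90)), c("10s", "40s", "90s"))
})

test_that("closest-in-time preference picks the nearer final date", {
  rec <- make_records(n_per_group = 1, seed = 60)
  tm <- rec[rec$group == "telemonitoring", ]
  cp <- rec[rec$group == "comparator", ]
  # two comparators identical on criteria, differing in final-date proximity
  cp2 <- dplyr::bind_rows(cp, cp)
  cp2$patient_id <- c("far", "near")
  cp2$sex <- tm$sex; cp2$simd_decile <- tm$simd_decile
  cp2$year_of_birth <- tm$year_of_birth
  cp2$baseline_date <- tm$baseline_date
  cp2$baseline_sbp <- tm$baseline_sbp + 5   # cancelled by delta 5
  cp2$final_date <- tm$final_date + c(90, 5)
  rec2 <- dplyr::bind_rows(tm, cp2)
  m <- find_matches(rec2, criteria = list(sbp_matching = "nearest_0_or_5",
                                          white_coat_delta = 5))
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$comparator_id, "near")

  # no comparator sharing the SIMD decile => zero pairs
  cp3 <- cp2
  cp3$simd_decile <- ((tm$simd_decile) %% 10) + 1L
  m0 <- find_matches(dplyr::bind_rows(tm, cp3),
                     criteria = list(sbp_matching = "exact",
                                     white_coat_delta = 0))
  expect_equal(nrow(m0$pairs), 0L)
  expect_equal(m0$unmatched, tm$patient_id)
})

test_that("greedy matching agrees with an independent brute-force matcher", {
  set.seed(61)
  for (trial in 1:60) {
    n <- sample(3:8, 1)
    rec <- make_records(n_per_group = n, seed = 1000 + trial)
    # coarsen covariates so matches are plausible at tiny n
    rec$simd_decile <- sample(4:5, nrow(rec), TRUE)
    rec$year_of_birth <- sample(c(1945L, 1955L), nrow(rec), TRUE)
    rec$age_2015 <- 2015 - rec$year_of_birth
    mode <- sample(c("exact", "nearest_0_or_5", "nearest_0"), 1)
    delta <- sample(c(0, 5, 7), 1)
    m <- find_matches(rec, criteria = list(sbp_matching = mode,
                                           white_coat_delta = delta))
    got <- if (nrow(m$pairs) == 0) character(0) else
      paste(m$pairs$telemon_id, m$pairs$comparator_id, sep = "->")
    expect_identical(got, brute_force_match(rec, mode, delta))
  }
})

test_that("matching is injective, exact on criteria, and deterministic", {
  rec <- make_records(n_per_group = 120, seed = 62)
  m <- find_matches(rec)
  expect_equal(anyDuplicated(m$pairs$comparator_id), 0L)
  expect_equal(anyDuplicated(m$pairs$telemon_id), 0L)
  m2 <- find_matches(rec[sample(nrow(rec)), ])
  expect_identical(m$pairs, m2$pairs)
  # verify matched-on equality per pair against the raw records
  adj <- adjust_white_coat(rec, m$criteria$white_coat_delta)
  for (i in seq_len(min(nrow(m$pairs), 20))) {
    t_row <- adj[adj$patient_id == m$pairs$telemon_id[i], ]
    c_row <- adj[adj$patient_id == m$pairs$comparator_id[i], ]
    expect_equal(t_row$simd_decile, c_row$simd_decile)
    expect_equal(t_row$sex, c_row$sex)
    expect_equal(grid_sbp(t_row$baseline_sbp, "nearest_0_or_5"),
                 grid_sbp(c_row$baseline_sbp, "nearest_0_or_5"))
  }
})

test_that("paired t-test matches the generic one-sample t-test oracle", {
  rec <- make_records(n_per_group = 40, seed = 63)
  # coarsen to guarantee a healthy number of pairs
  rec$simd_decile <- 5L
  rec$year_of_birth <- 1950L
  rec$age_2015 <- 65
  m <- find_matches(rec, criteria = list(sbp_matching = "nearest_0",
                                         white_coat_delta = 5))
  expect_gte(nrow(m$pairs), 3)
  eff <- paired_t_test(m, "systolic")
  d <- m$pairs$comparator_final_sbp - m$pairs$telemon_final_sbp
  oracle <- t.test(d)
  expect_equal(eff$estimate, unname(oracle$estimate))
  expect_equal(eff$p_value, oracle$p.value)
  expect_equal(c(eff$ci_lower, eff$ci_upper), as.numeric(oracle$conf.int))

  # hand computation: differences 1, 2, 3
  pairs <- tibble::tibble(comparator_final_sbp = c(11, 12, 13),
                          telemon_final_sbp = c(10, 10, 10),
                          comparator_final_dbp = 0, telemon_final_dbp = 0)
  eff <- paired_t_test(pairs, "systolic")
  expect_equal(eff$estimate, 2)
  expect_equal(eff$std_error, 1 / sqrt(3))
  expect_equal(eff$estimate / eff$std_error, 2 * sqrt(3), tolerance = 1e-9)

  # identical outcomes: mean difference zero, flagged p
  pairs$comparator_final_sbp <- pairs$telemon_final_sbp
  expect_warning(eff0 <- paired_t_test(pairs, "systolic"), "zero variance")
  expect_equal(eff0$estimate, 0)
  expect_true(is.na(eff0$p_value))
  expect_error(paired_t_test(pairs[1, ], "systolic"), "at least 2")
})

test_that("sensitivity grid runs all nine settings and nests the single analysis", {
  rec <- make_records(n_per_group = 120, seed = 64)
  grid <- sensitivity_grid(rec)
  expect_equal(nrow(grid), 9L)
  expect_true(all(is.na(grid$error) | nchar(grid$error) > 0))
  # a single-setting grid reproduces the standalone analysis
  one <- sensitivity_grid(rec, settings = tibble::tibble(
    sbp_matching = "nearest_0_or_5", white_coat_delta = 5))
  m <- find_matches(rec, criteria = list(sbp_matching = "nearest_0_or_5",
                                         white_coat_delta = 5))
  eff <- paired_t_test(m)
  expect_equal(one$n_pairs, nrow(m$pairs))
  expect_equal(one$estimate, eff$estimate)
  expect_equal(one$p_value, eff$p_value)
})

test_that("increasing delta shifts the matched mean difference by about -delta", {
  # null records with a built-in comparator offset of 7 (white-coat analogue)
  rec <- make_records(n_per_group = 350, seed = 65, comparator_offset = 7)
  est <- sapply(c(0, 5, 7), function(d) {
    m <- find_matches(rec, criteria = list(sbp_matching = "nearest_0_or_5",
                                           white_coat_delta = d))
    paired_t_test(m)$estimate
  })
  # delta equal to the true offset recovers ~0; slope about -1 per mmHg
  expect_lt(abs(est[3]), 2)
  expect_equal(est[1] - est[2], 5, tolerance = 2)
})
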