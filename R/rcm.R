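#' Prior-reading-count category
#'
#' Number of surgery BP measurements in the year before a patient's first
#' retained reading, as the categorical adjustment variable: `"0"`, `"1-4"`,
#' `"5+"`.
#'
#' @param count Non-negative integer counts.
#' @return A factor with levels `"0"`, `"1-4"`, `"5+"`.
#' @export
prior_reading_category <- function(count) {
  if (any(count < 0)) abort("prior reading count cannot be negative")
  factor(ifelse(count == 0, "0", ifelse(count <= 4, "1-4", "5+")),
         levels = c("0", "1-4", "5+"))
}

#' Prepare long-format data for random-coefficient modelling
#'
#' Builds one row per retained reading for the longitudinal analysis that
#' uses all available data. Readings failing the plausibility rules are
#' dropped; each patient's chronologically first telemonitored reading is
#' deleted (it may have been used to test the system); only readings on or
#' after the calendar cutoff are kept as outcomes. The patient clock
#' (`patient_time`, fractional weeks) starts at each patient's first
#' retained reading. The prior-reading adjustment counts surgery readings in
#' the 365 days before that first retained reading — the only place
#' pre-cutoff readings are used.
#'
#' Group codes: 0 = surgery reading from a comparator patient, 1 = surgery
#' reading from a telemonitoring patient, 2 = telemonitored reading. The
#' 1-vs-0 (surgery-vs-surgery) contrast is exposed downstream but flagged:
#' home readings transcribed into practice systems contaminate it.
#'
#' @param cohort A `bp_cohort` whose readings still include pre-cutoff
#'   history (do not calendar-filter first).
#' @param cutoff Calendar cutoff for outcome readings; defaults to the
#'   cohort's `telemonitoring_start`.
#' @return A tibble with `patient_id`, `practice_id`, `date`, `source`,
#'   `sbp`, `dbp`, `patient_time`, `group_code` (factor 0/1/2),
#'   `prior_count`, `prior_count_category`, `age_2015`, `simd5plus`, `sex`.
#' @export
prepare_longitudinal <- function(cohort, cutoff = NULL) {
  stopifnot(inherits(cohort, "bp_cohort"))
  cutoff <- as.Date(cutoff %||% cohort$telemonitoring_start)
  readings <- apply_exclusion_criteria(cohort$readings)$kept %>%
    inner_join(cohort$patients, by = "patient_id") %>%
    arrange(.data$patient_id, .data$date)

  # delete each patient's first telemonitored reading
  readings <- readings %>%
    group_by(.data$patient_id) %>%
    mutate(.tm_rank = cumsum(.data$source == "telemonitored")) %>%
    ungroup() %>%
    filter(!(.data$source == "telemonitored" & .data$.tm_rank == 1L)) %>%
    select(-".tm_rank")

  outcomes <- filter(readings, .data$date >= cutoff)
  t0 <- outcomes %>%
    group_by(.data$patient_id) %>%
    summarise(t0 = min(.data$date), .groups = "drop")

  prior <- readings %>%
    filter(.data$source == "surgery") %>%
    inner_join(t0, by = "patient_id") %>%
    filter(.data$date < .data$t0, .data$date >= .data$t0 - 365) %>%
    count(.data$patient_id, name = "prior_count")

  outcomes %>%
    inner_join(t0, by = "patient_id") %>%
    left_join(prior, by = "patient_id") %>%
    mutate(
      prior_count = tidyr::replace_na(.data$prior_count, 0L),
      patient_time = as.numeric(.data$date - .data$t0) / 7,
      group_code = factor(
        ifelse(.data$source == "telemonitored", "2",
               ifelse(.data$group == "telemonitoring", "1", "0")),
        levels = c("0", "1", "2")),
      prior_count_category = prior_reading_category(.data$prior_count),
      age_2015 = 2015 - .data$year_of_birth,
      simd5plus = .data$simd_decile >= 5
    ) %>%
    select("patient_id", "practice_id", "date", "source",
           sbp = "systolic", dbp = "diastolic",
           "patient_time", "group_code", "prior_count",
           "prior_count_category", "age_2015", "simd5plus", "sex")
}

#' Random-coefficients model for one practice
#'
#' Fits the longitudinal mixed model to one practice's rows: BP on patient
#' time, group code, their interaction, the prior-reading category, age,
#' SIMD 5+ and sex, with correlated random intercept and random
#' patient-time slope per patient (unstructured 2x2 covariance). The
#' patient-time-by-group interaction coefficients are the weekly
#' between-group differences in BP change; the group main effects absorb
#' level differences such as white-coat effect. Covariates constant within
#' the practice are dropped from the fixed effects automatically.
#'
#' @param rows Output of [prepare_longitudinal()], one practice.
#' @param component `"systolic"` or `"diastolic"`.
#' @param reml Use REML (default) or ML.
#' @return A list of class `bp_practice_fit`: `practice_id`, `estimates`
#'   (tibble of contrast, estimate, SE — the two slope contrasts in
#'   mmHg/week plus the two group level contrasts in mmHg), `varcorr`,
#'   `singular`, `n_patients`, `n_readings`.
#' @export
fit_practice_rcm <- function(rows, component = c("systolic", "diastolic"),
                             reml = TRUE) {
  component <- match.arg(component)
  rows <- as_tibble(rows)
  per_patient <- count(rows, .data$patient_id)
  if (nrow(per_patient) < 2 || sum(per_patient$n >= 2) < 2) {
    abort("random-coefficients model needs >= 2 patients with >= 2 readings")
  }
  rows$bp <- if (component == "systolic") rows$sbp else rows$dbp
  rows$group_code <- droplevels(rows$group_code)
  rows$prior_count_category <- droplevels(rows$prior_count_category)

  covars <- c("prior_count_category", "age_2015", "simd5plus", "sex")
  keep <- vapply(covars, function(v) length(unique(rows[[v]])) > 1, logical(1))
  rhs <- paste(c("patient_time * group_code", covars[keep],
                 "(patient_time | patient_id)"), collapse = " + ")
  fit <- lmer_quiet(stats::as.formula(paste("bp ~", rhs)), data = rows,
                    reml = reml)

  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  contrast_names <- c("telemon_vs_comparator" = "patient_time:group_code2",
                      "surgery_vs_surgery" = "patient_time:group_code1",
                      "level_telemon_vs_comparator" = "group_code2",
                      "level_surgery_vs_surgery" = "group_code1")
  estimates <- purrr::imap_dfr(contrast_names, function(term, lab) {
    if (term %in% names(beta)) {
      tibble(contrast = lab, estimate = unname(beta[term]),
             std_error = unname(se[term]))
    } else {
      tibble(contrast = lab, estimate = NA_real_, std_error = NA_real_)
    }
  })
  structure(
    list(practice_id = rows$practice_id[1],
         estimates = estimates,
         varcorr = lme4::VarCorr(fit),
         singular = lme4::isSingular(fit),
         n_patients = nrow(per_patient),
         n_readings = nrow(rows)),
    class = "bp_practice_fit"
  )
}

#' @export
print.bp_practice_fit <- function(x, ...) {
  cat(sprintf("<bp_practice_fit> practice %s: %d patients, %d readings%s\n",
              x$practice_id, x$n_patients, x$n_readings,
              if (x$singular) " (singular fit)" else ""))
  print(x$estimates)
  invisible(x)
}

#' Fit per-practice models across a cohort
#'
#' Runs [fit_practice_rcm()] within each practice; practices whose model
#' cannot be fitted (insufficient data, missing contrast, non-convergence)
#' are skipped with a logged reason.
#'
#' @param rows Output of [prepare_longitudinal()].
#' @inheritParams fit_practice_rcm
#' @return A list of `bp_practice_fit` objects; skipped practices appear in
#'   `attr(, "skipped")` as a tibble of practice id and reason.
#' @export
fit_all_practices <- function(rows, component = c("systolic", "diastolic"),
                              reml = TRUE) {
  component <- match.arg(component)
  ids <- sort(unique(rows$practice_id))
  skipped <- tibble(practice_id = character(0), reason = character(0))
  fits <- list()
  for (id in ids) {
    res <- tryCatch(
      fit_practice_rcm(rows[rows$practice_id == id, , drop = FALSE],
                       component = component, reml = reml),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      skipped <- add_row(skipped, practice_id = id, reason = res)
      inform(sprintf("practice %s skipped: %s", id, res))
    } else {
      fits[[id]] <- res
    }
  }
  attr(fits, "skipped") <- skipped
  fits
}

#' Overall random-coefficients model, unadjusted for practice
#'
#' The same longitudinal model fitted to all practices pooled, at the cost
#' of not adjusting for practice (a combined practice-plus-patient
#' random-effects model tends not to converge when the between-practice
#' variance is near zero).
#'
#' @param rows Output of [prepare_longitudinal()] (all practices).
#' @param contrast `"telemon_vs_comparator"` (group 2 vs 0, the headline
#'   contrast) or `"surgery_vs_surgery"` (group 1 vs 0; interpret with
#'   caution, see [prepare_longitudinal()]).
#' @inheritParams fit_practice_rcm
#' @return A [`bp_effect`][new_bp_effect] row in mmHg/week (method
#'   `"random_coefficients_overall"`); annualise with [annualise()].
#' @export
fit_overall_rcm <- function(rows, component = c("systolic", "diastolic"),
                            contrast = c("telemon_vs_comparator",
                                         "surgery_vs_surgery"),
                            reml = TRUE) {
  contrast <- match.arg(contrast)
  fit <- fit_practice_rcm(mutate(rows, practice_id = "all"),
                          component = component, reml = reml)
  row <- fit$estimates[fit$estimates$contrast == contrast, ]
  if (is.na(row$estimate)) {
    abort(sprintf("contrast '%s' not estimable on these rows", contrast))
  }
  est <- row$estimate
  se <- row$std_error
  new_bp_effect(
    estimate = est, std_error = se,
    ci_lower = est - 1.96 * se, ci_upper = est + 1.96 * se,
    p_value = 2 * pnorm(-abs(est / se)),
    n = fit$n_patients,
    method = "random_coefficients_overall",
    contrast = contrast, unit = "mmHg/week",
    caution = contrast == "surgery_vs_surgery"
  )
}

#' Convert a weekly BP change to an annual one
#'
#' Multiplies by 365.25/7 (about 52.18 weeks per year); apply to estimates
#' and CI endpoints alike. Set `weeks_per_year = 52` for plain 52-week
#' years.
#'
#' @param weekly Value(s) in mmHg/week.
#' @param weeks_per_year Conversion factor, default `365.25 / 7`.
#' @return Value(s) in mmHg/year.
#' @export
annualise <- function(weekly, weeks_per_year = 365.25 / 7) {
  weekly * weeks_per_year
}
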