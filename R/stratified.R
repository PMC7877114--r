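#' Descriptive BP-difference summaries by stratum
#'
#' Summarises baseline-minus-final BP differences by group within the
#' pre-specified strata: overall; age <65 / 65+; sex; SIMD <5 / 5+ (more
#' deprived / more affluent); and baseline systolic BP <135 / 135+ / 140+ /
#' 145+ / 150+ (the systolic strata overlap by design). Values are
#' unadjusted for white-coat effect; shift the records first with
#' [adjust_white_coat()] if required.
#'
#' @param records A `bp_standardised` tibble.
#' @param component `"systolic"` or `"diastolic"` (which difference to
#'   summarise; strata are always defined on baseline systolic).
#' @return A tibble with one row per stratum x group: `n`, `mean`, `sd`,
#'   `median`, `q1`, `q3`, `min`, `max` (statistics are `NA` for empty or
#'   singleton strata where undefined).
#' @export
strata_summary <- function(records, component = c("systolic", "diastolic")) {
  component <- match.arg(component)
  if (nrow(records) == 0) abort("strata_summary: no records")
  value <- if (component == "systolic") records$sbp_diff else records$dbp_diff

  strata <- list(
    "overall"   = rep(TRUE, nrow(records)),
    "age <65"   = records$age_2015 < 65,
    "age 65+"   = records$age_2015 >= 65,
    "male"      = records$sex == "male",
    "female"    = records$sex == "female",
    "SIMD <5"   = !records$simd5plus,
    "SIMD 5+"   = records$simd5plus,
    "SBP <135"  = records$baseline_sbp < 135,
    "SBP 135+"  = records$baseline_sbp >= 135,
    "SBP 140+"  = records$baseline_sbp >= 140,
    "SBP 145+"  = records$baseline_sbp >= 145,
    "SBP 150+"  = records$baseline_sbp >= 150
  )
  purrr::map_dfr(names(strata), function(s) {
    keep <- strata[[s]]
    if (!any(keep)) return(NULL)  # filled in as n = 0 by complete() below
    tibble(stratum = s, group = records$group[keep], value = value[keep]) %>%
      group_by(.data$stratum, .data$group) %>%
      summarise(
        n = dplyr::n(),
        mean = mean(.data$value), sd = sd(.data$value),
        median = median(.data$value),
        q1 = quantile(.data$value, 0.25, names = FALSE),
        q3 = quantile(.data$value, 0.75, names = FALSE),
        min = min(.data$value), max = max(.data$value),
        .groups = "drop"
      )
  }) %>%
    tidyr::complete(stratum = names(strata),
                    group = c("telemonitoring", "comparator"),
                    fill = list(n = 0L)) %>%
    mutate(stratum = factor(.data$stratum, levels = names(strata))) %>%
    arrange(.data$stratum, desc(.data$group))
}

#' Relative risk reduction from raised-BP counts
#'
#' The percentage fall in the proportion of patients above a BP threshold
#' between baseline and follow-up: `100 * (1 - (n_follow/N) / (n_base/N)) =
#' 100 * (1 - n_follow/n_base)`.
#'
#' @param n_base Patients raised at baseline (must be > 0).
#' @param n_follow Patients raised at follow-up.
#' @param N Denominator (number of patients); only used for validation, the
#'   RRR is scale-invariant in `N`.
#' @return RRR in percent (vectorised).
#' @export
relative_risk_reduction <- function(n_base, n_follow, N) {
  if (any(n_base > N) || any(n_follow > N)) {
    abort("raised counts exceed the denominator N")
  }
  if (any(n_base == 0)) {
    abort("relative risk reduction is undefined when no patient is raised at baseline (n_base = 0)")
  }
  100 * (1 - n_follow / n_base)
}

#' Relative-risk-reduction ratio between groups
#'
#' The telemonitoring-group RRR divided by the comparator-group RRR (on the
#' proportion scale). Each argument is a count triple `(n_base, n_follow,
#' N)`. The comparator triple may be taken at a higher threshold than the
#' telemonitoring one to absorb an assumed white-coat shift.
#'
#' @param telemon,comparator Numeric triples `c(n_base, n_follow, N)`.
#' @return The dimensionless ratio.
#' @export
rrr_ratio <- function(telemon, comparator) {
  rt <- relative_risk_reduction(telemon[1], telemon[2], telemon[3]) / 100
  rc <- relative_risk_reduction(comparator[1], comparator[2], comparator[3]) / 100
  if (rc == 0) abort("comparator relative risk reduction is zero; ratio undefined")
  rt / rc
}

#' Raised-BP prevalence table
#'
#' For each threshold and group: the number of patients at or above the
#' threshold at baseline and at follow-up, the denominator, the baseline and
#' follow-up percentages, and the relative risk reduction. Rounded display
#' percentages are included alongside exact values.
#'
#' @param records A `bp_standardised` tibble.
#' @param sbp_thresholds,dbp_thresholds Raised-BP thresholds in mmHg.
#' @return A tibble of class `bp_raised_table`.
#' @export
raised_bp_table <- function(records,
                            sbp_thresholds = c(135, 140, 145, 150),
                            dbp_thresholds = c(85, 90)) {
  spec <- bind_rows(
    tibble(component = "systolic", threshold = sbp_thresholds),
    tibble(component = "diastolic", threshold = dbp_thresholds)
  )
  out <- purrr::pmap_dfr(spec, function(component, threshold) {
    base <- if (component == "systolic") records$baseline_sbp else records$baseline_dbp
    fin <- if (component == "systolic") records$final_sbp else records$final_dbp
    tibble(group = records$group,
           raised_base = base >= threshold, raised_follow = fin >= threshold) %>%
      group_by(.data$group) %>%
      summarise(n_base = sum(.data$raised_base),
                n_follow = sum(.data$raised_follow),
                N = dplyr::n(), .groups = "drop") %>%
      mutate(component = component, threshold = threshold,
             pct_base = 100 * .data$n_base / .data$N,
             pct_follow = 100 * .data$n_follow / .data$N,
             rrr = ifelse(.data$n_base > 0,
                          100 * (1 - .data$n_follow / .data$n_base), NA_real_),
             rrr_display = round(.data$rrr))
  }) %>%
    select("component", "threshold", "group", "n_base", "n_follow", "N",
           "pct_base", "pct_follow", "rrr", "rrr_display") %>%
    arrange(.data$component == "diastolic", .data$threshold,
            desc(.data$group))
  class(out) <- c("bp_raised_table", class(out))
  out
}

#' Bootstrap confidence interval for the RRR ratio
#'
#' Non-parametric bootstrap of the relative-risk-reduction ratio: patients
#' are resampled with replacement within each group independently (the
#' resampling unit is the patient, carrying their paired baseline/final
#' raised indicators), the ratio is recomputed per resample, and the 2.5th
#' and 97.5th percentile order statistics form the interval. (Internally a
#' resample's indicator counts are drawn as one multinomial over the four
#' (baseline, follow-up) indicator cells, which is distributionally
#' identical to resampling the patients and counting.) Resamples with
#' an undefined ratio (no raised baseline patients, or a zero comparator
#' RRR) are rejected and redrawn; if more than half of the draws are
#' rejected the bootstrap aborts.
#'
#' @param records A `bp_standardised` tibble.
#' @param telemon_threshold,comparator_threshold Raised-SBP thresholds in
#'   mmHg for each group (a higher comparator threshold absorbs an assumed
#'   white-coat shift). Default 145 for both.
#' @param n_resamples Number of bootstrap resamples (default 9999).
#' @param seed Optional integer seed.
#' @return A list of class `bp_rrr_boot`: `ratio` (point estimate),
#'   `ci_lower`, `ci_upper`, `n_resamples`, `n_rejected`, `seed`.
#' @export
bootstrap_rrr_ratio <- function(records, telemon_threshold = 145,
                                comparator_threshold = 145,
                                n_resamples = 9999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tm <- records[records$group == "telemonitoring", , drop = FALSE]
  cp <- records[records$group == "comparator", , drop = FALSE]
  if (nrow(tm) == 0 || nrow(cp) == 0) abort("both groups must be non-empty")

  tb <- tm$baseline_sbp >= telemon_threshold
  tf <- tm$final_sbp >= telemon_threshold
  cb <- cp$baseline_sbp >= comparator_threshold
  cf <- cp$final_sbp >= comparator_threshold

  point <- rrr_ratio(c(sum(tb), sum(tf), nrow(tm)),
                     c(sum(cb), sum(cf), nrow(cp)))

  # Resampling n patients with replacement and summing their paired
  # (baseline, follow-up) raised indicators is a multinomial draw over the
  # four indicator cells with the empirical cell frequencies; drawing the
  # cell counts directly is exactly equivalent and much faster.
  cell_counts <- function(base, follow, B) {
    cell <- factor(paste0(base, follow),
                   levels = c("FALSEFALSE", "FALSETRUE", "TRUEFALSE",
                              "TRUETRUE"))
    n <- length(cell)
    draws <- stats::rmultinom(B, n, prob = tabulate(cell, 4) / n)
    list(n_base = draws[3, ] + draws[4, ], n_follow = draws[2, ] + draws[4, ])
  }
  draw_batch <- function(B) {
    tcounts <- cell_counts(tb, tf, B)
    ccounts <- cell_counts(cb, cf, B)
    rt <- 1 - tcounts$n_follow / tcounts$n_base
    rc <- 1 - ccounts$n_follow / ccounts$n_base
    ratio <- rt / rc
    ratio[tcounts$n_base == 0 | ccounts$n_base == 0 | rc == 0] <- NA_real_
    ratio
  }

  ratios <- numeric(0)
  n_rejected <- 0L
  n_drawn <- 0L
  while (length(ratios) < n_resamples) {
    batch <- draw_batch(min(n_resamples - length(ratios), 2000L))
    n_drawn <- n_drawn + length(batch)
    n_rejected <- n_rejected + sum(is.na(batch))
    ratios <- c(ratios, batch[!is.na(batch)])
    if (n_drawn >= 2 * n_resamples && n_rejected > n_drawn / 2) {
      abort(sprintf(
        "bootstrap aborted: %d of %d resamples had an undefined RRR ratio",
        n_rejected, n_drawn))
    }
  }
  if (n_rejected > 0) {
    inform(sprintf("bootstrap: %d undefined resample(s) rejected and redrawn",
                   n_rejected))
  }
  sorted <- sort(ratios)
  lo <- max(1L, floor(0.025 * (n_resamples + 1)))
  hi <- min(n_resamples, ceiling(0.975 * (n_resamples + 1)))
  structure(
    list(ratio = point, ci_lower = sorted[lo], ci_upper = sorted[hi],
         n_resamples = n_resamples, n_rejected = n_rejected,
         seed = seed),
    class = "bp_rrr_boot"
  )
}

#' @export
print.bp_rrr_boot <- function(x, ...) {
  cat(sprintf(
    "<bp_rrr_boot> RRR ratio %.3f, bootstrap 95%% CI %.3f to %.3f (%d resamples, %d rejected)\n",
    x$ratio, x$ci_lower, x$ci_upper, x$n_resamples, x$n_rejected))
  invisible(x)
}

#' @export
glance.bp_rrr_boot <- function(x, ...) {
  tibble(ratio = x$ratio, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
         n_resamples = x$n_resamples, n_rejected = x$n_rejected)
}

#' Covariate-adjusted mixed model within a baseline-SBP stratum
#'
#' The model-based arm of the stratified method: comparator readings are
#' first reduced by the white-coat delta, patients are stratified on the
#' (adjusted) baseline systolic BP rather than modelling it (avoiding bias
#' from modelling change against initial value), and within the stratum a
#' linear mixed model is fitted with the BP difference as outcome, fixed
#' effects for group, SIMD 5+, sex and continuous age, and a random
#' intercept for practice. The group coefficient (telemonitoring minus
#' comparator) is returned with a Wald 95% CI. A zero practice-variance
#' boundary fit is legitimate and flagged via `singular_fit`.
#'
#' @param records A `bp_standardised` tibble (unadjusted).
#' @param stratum One of `"overall"`, `"<135"`, `"135+"`, `"140+"`,
#'   `"145+"`, `"150+"` (baseline systolic BP after adjustment).
#' @param white_coat_delta mmHg subtracted from comparator readings before
#'   stratification and differencing (default 5).
#' @param component Which BP difference to model.
#' @param adjust_scope Which comparator readings receive the delta:
#'   `"both"` (default), `"baseline"`, or `"final"` (for sensitivity to the
#'   ambiguity in where the shift belongs).
#' @return A [`bp_effect`][new_bp_effect] row (method
#'   `"standardisation_stratified"`).
#' @export
stratified_lmm <- function(records, stratum = "overall",
                           white_coat_delta = 5,
                           component = c("systolic", "diastolic"),
                           adjust_scope = c("both", "baseline", "final")) {
  component <- match.arg(component)
  adjust_scope <- match.arg(adjust_scope)
  adj <- records
  comp <- adj$group == "comparator"
  cols <- switch(adjust_scope,
                 both = c("baseline_sbp", "final_sbp", "baseline_dbp", "final_dbp"),
                 baseline = c("baseline_sbp", "baseline_dbp"),
                 final = c("final_sbp", "final_dbp"))
  for (col in cols) adj[[col]][comp] <- adj[[col]][comp] - white_coat_delta
  adj$sbp_diff <- adj$baseline_sbp - adj$final_sbp
  adj$dbp_diff <- adj$baseline_dbp - adj$final_dbp

  keep <- switch(stratum,
                 "overall" = rep(TRUE, nrow(adj)),
                 "<135" = adj$baseline_sbp < 135,
                 "135+" = adj$baseline_sbp >= 135,
                 "140+" = adj$baseline_sbp >= 140,
                 "145+" = adj$baseline_sbp >= 145,
                 "150+" = adj$baseline_sbp >= 150,
                 abort(sprintf("unknown stratum '%s'", stratum)))
  dat <- adj[keep, , drop = FALSE]
  if (length(unique(dat$group)) < 2) {
    abort(sprintf("stratum '%s' does not contain both groups", stratum))
  }
  dat$outcome <- if (component == "systolic") dat$sbp_diff else dat$dbp_diff
  dat$group <- factor(dat$group, levels = c("comparator", "telemonitoring"))
  fit <- lmer_quiet(
    outcome ~ group + simd5plus + sex + age_2015 + (1 | practice_id),
    data = dat
  )
  lmer_wald_effect(fit, "grouptelemonitoring", n = nrow(dat),
                   method = "standardisation_stratified",
                   stratum = stratum, white_coat_delta = white_coat_delta)
}
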