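#' DerSimonian-Laird random-effects meta-analysis
#'
#' Moment-based random-effects pooling. With study estimates
#' \eqn{\theta_i} and variances \eqn{v_i}: fixed-effect weights
#' \eqn{w_i = 1/v_i}; heterogeneity
#' \eqn{Q = \sum w_i (\theta_i - \bar\theta_{FE})^2};
#' \eqn{C = \sum w_i - \sum w_i^2 / \sum w_i};
#' \eqn{\tau^2 = \max(0, (Q - (k-1))/C)}; random-effects weights
#' \eqn{w_i^* = 1/(v_i + \tau^2)}; pooled estimate
#' \eqn{\sum w_i^* \theta_i / \sum w_i^*} with standard error
#' \eqn{(\sum w_i^*)^{-1/2}} and Wald 95% CI (z = 1.96, no small-sample
#' adjustment). A single study is passed through with \eqn{\tau^2 = 0}.
#'
#' @param studies A tibble with columns `label`, `estimate`, and either
#'   `variance` or `std_error` (one per study; variances must be positive).
#' @return A list of class `bp_meta`: `estimate`, `std_error`, `ci_lower`,
#'   `ci_upper`, `p_value`, `tau_squared`, `Q`, `k`, and `studies` (the
#'   inputs plus random-effects `weight_pct`).
#' @export
dersimonian_laird <- function(studies) {
  studies <- as_tibble(studies)
  if (nrow(studies) == 0) abort("no studies to pool")
  if (!"variance" %in% names(studies)) {
    if (!"std_error" %in% names(studies)) {
      abort("studies need a 'variance' or 'std_error' column")
    }
    studies$variance <- studies$std_error^2
  }
  if (any(!is.finite(studies$variance)) || any(studies$variance <= 0)) {
    abort("study variances must be positive and finite")
  }
  th <- studies$estimate
  v <- studies$variance
  k <- length(th)

  if (k == 1) {
    tau2 <- 0
    Q <- 0
    wstar <- 1 / v
  } else {
    w <- 1 / v
    theta_fe <- sum(w * th) / sum(w)
    Q <- sum(w * (th - theta_fe)^2)
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - (k - 1)) / C)
    wstar <- 1 / (v + tau2)
  }
  pooled <- sum(wstar * th) / sum(wstar)
  se <- sqrt(1 / sum(wstar))
  structure(
    list(estimate = pooled, std_error = se,
         ci_lower = pooled - 1.96 * se, ci_upper = pooled + 1.96 * se,
         p_value = 2 * pnorm(-abs(pooled / se)),
         tau_squared = tau2, Q = Q, k = k,
         studies = mutate(studies,
                          weight_pct = 100 * wstar / sum(wstar))),
    class = "bp_meta"
  )
}

#' @export
print.bp_meta <- function(x, ...) {
  cat(sprintf(
    "<bp_meta> pooled %.4f (SE %.4f), 95%% CI %.4f to %.4f; tau^2 = %.4g, Q = %.3g, k = %d\n",
    x$estimate, x$std_error, x$ci_lower, x$ci_upper,
    x$tau_squared, x$Q, x$k))
  invisible(x)
}

#' @export
glance.bp_meta <- function(x, ...) {
  tibble(estimate = x$estimate, std_error = x$std_error,
         ci_lower = x$ci_lower, ci_upper = x$ci_upper,
         p_value = x$p_value, tau_squared = x$tau_squared,
         Q = x$Q, k = x$k)
}

#' @export
tidy.bp_meta <- function(x, ...) {
  forest_data(x)
}

#' Forest-plot table for a pooled result
#'
#' One row per study (label, estimate, 95% CI, random-effects weight in
#' percent) plus a summary row reproducing the pooled result; weights sum to
#' 100%.
#'
#' @param result A `bp_meta` object.
#' @return A plot-ready tibble with `label`, `estimate`, `ci_lower`,
#'   `ci_upper`, `weight_pct`, `is_summary`.
#' @export
forest_data <- function(result) {
  stopifnot(inherits(result, "bp_meta"))
  per_study <- result$studies %>%
    transmute(label = as.character(.data$label), estimate = .data$estimate,
              ci_lower = .data$estimate - 1.96 * sqrt(.data$variance),
              ci_upper = .data$estimate + 1.96 * sqrt(.data$variance),
              weight_pct = .data$weight_pct, is_summary = FALSE)
  bind_rows(per_study,
            tibble(label = "Pooled (random effects)",
                   estimate = result$estimate,
                   ci_lower = result$ci_lower, ci_upper = result$ci_upper,
                   weight_pct = 100, is_summary = TRUE))
}

#' Pool per-practice random-coefficient fits
#'
#' Collects one interaction contrast from each practice fit and pools the
#' weekly estimates with [dersimonian_laird()].
#'
#' @param fits A list of `bp_practice_fit` objects (see
#'   [fit_all_practices()]).
#' @param contrast `"telemon_vs_comparator"` or `"surgery_vs_surgery"`.
#' @return A `bp_meta` on the mmHg/week scale; practices with an
#'   inestimable contrast are dropped with a message.
#' @export
pool_practices <- function(fits, contrast = c("telemon_vs_comparator",
                                              "surgery_vs_surgery")) {
  contrast <- match.arg(contrast)
  studies <- purrr::map_dfr(fits, function(f) {
    row <- f$estimates[f$estimates$contrast == contrast, ]
    tibble(label = f$practice_id, estimate = row$estimate,
           std_error = row$std_error)
  })
  drop <- !is.finite(studies$estimate) | !is.finite(studies$std_error)
  if (any(drop)) {
    inform(sprintf("dropping %d practice(s) with inestimable '%s' contrast",
                   sum(drop), contrast))
    studies <- studies[!drop, , drop = FALSE]
  }
  dersimonian_laird(studies)
}

#' Forest plot of per-practice estimates with the pooled summary
#'
#' @param object A `bp_meta`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bp_meta <- function(object, ...) {
  dat <- forest_data(object) %>%
    mutate(label = factor(.data$label, levels = rev(.data$label)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lower, xmax = .data$ci_upper),
      height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight_pct,
                                     shape = .data$is_summary)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 18),
                                guide = "none") +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(x = "Between-group difference in BP change",
                  y = NULL) +
    ggplot2::theme_minimal()
}
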