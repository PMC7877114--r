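#' Plot a matched-analysis sensitivity grid
#'
#' Point estimates and 95% CIs of the matched mean difference (comparator
#' minus telemonitoring final BP) across matching-grid and white-coat-delta
#' settings.
#'
#' @param grid Output of [sensitivity_grid()].
#' @return A ggplot.
#' @export
plot_sensitivity_grid <- function(grid) {
  dat <- dplyr::mutate(grid,
                       setting = sprintf("%s, -%g", .data$sbp_matching,
                                         .data$white_coat_delta))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate,
                                    y = factor(.data$setting,
                                               levels = rev(dat$setting)))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lower, xmax = .data$ci_upper),
      height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Mean difference in final BP (comparator - telemonitoring, mmHg)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot raised-BP prevalence at index and follow-up
#'
#' @param object A [raised_bp_table()] result.
#' @param ... Unused.
#' @return A ggplot faceted by component and threshold.
#' @export
autoplot.bp_raised_table <- function(object, ...) {
  dat <- tidyr::pivot_longer(object, c("pct_base", "pct_follow"),
                             names_to = "time", values_to = "pct") %>%
    mutate(time = ifelse(.data$time == "pct_base", "index", "6-12 months"),
           time = factor(.data$time, levels = c("index", "6-12 months")),
           label = sprintf("%s %g+", substr(.data$component, 1, 3),
                           .data$threshold))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$pct,
                                    fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~label, nrow = 1) +
    ggplot2::labs(x = NULL, y = "% of patients raised", fill = NULL) +
    ggplot2::theme_minimal()
}
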