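#' Terminal-digit preference cross-tabulation
#'
#' Cross-tabulates systolic against diastolic end digits (value mod 10) and
#' reports double-zero prevalence. Under digit-neutral recording each of the
#' 100 cells holds ~1% of readings, so the chance expectation for double
#' zeros is 1% (and 10% per single digit); these references are carried in
#' the result. No hypothesis test is computed: with routine-data sample
#' sizes, significance is uninformative.
#'
#' @param readings A non-empty readings tibble.
#' @return A list of class `bp_end_digits`: `counts` (10x10 integer matrix,
#'   systolic digit in rows), `total`, `double_zero_count`,
#'   `double_zero_pct`, and the chance references.
#' @export
end_digit_table <- function(readings) {
  readings <- as_tibble(readings)
  if (nrow(readings) == 0) abort("end_digit_table: no readings")
  s <- readings$systolic %% 10
  d <- readings$diastolic %% 10
  counts <- table(factor(s, levels = 0:9), factor(d, levels = 0:9))
  counts <- matrix(as.integer(counts), nrow = 10,
                   dimnames = list(systolic = 0:9, diastolic = 0:9))
  dz <- counts[1, 1]
  structure(
    list(counts = counts, total = nrow(readings),
         double_zero_count = dz,
         double_zero_pct = 100 * dz / nrow(readings),
         chance_double_zero_pct = 1,
         chance_per_digit_pct = 10),
    class = "bp_end_digits"
  )
}

#' @export
print.bp_end_digits <- function(x, ...) {
  cat(sprintf(
    "<bp_end_digits> %d readings; double zero %d (%.2f%%; chance 1%%)\n",
    x$total, x$double_zero_count, x$double_zero_pct))
  invisible(x)
}

#' Per-digit end-digit frequencies
#'
#' @param readings A non-empty readings tibble.
#' @param component `"systolic"` or `"diastolic"`.
#' @return A plot-ready tibble with `digit` (0-9), `n`, `proportion`
#'   (summing to 1) and the 0.1 chance reference.
#' @export
end_digit_frequencies <- function(readings,
                                  component = c("systolic", "diastolic")) {
  component <- match.arg(component)
  readings <- as_tibble(readings)
  if (nrow(readings) == 0) abort("end_digit_frequencies: no readings")
  digit <- readings[[component]] %% 10
  n <- tabulate(digit + 1L, nbins = 10L)
  tibble(component = component, digit = 0:9, n = n,
         proportion = n / sum(n), chance = 0.1)
}

#' @export
tidy.bp_end_digits <- function(x, ...) {
  as_tibble(as.data.frame.table(x$counts, responseName = "n")) %>%
    mutate(systolic = as.integer(as.character(.data$systolic)),
           diastolic = as.integer(as.character(.data$diastolic)),
           proportion = .data$n / x$total)
}

#' @export
glance.bp_end_digits <- function(x, ...) {
  tibble(total = x$total, double_zero_count = x$double_zero_count,
         double_zero_pct = x$double_zero_pct,
         chance_double_zero_pct = x$chance_double_zero_pct)
}

#' Bar chart of end-digit frequencies
#'
#' @param freq Output of [end_digit_frequencies()].
#' @return A ggplot.
#' @export
plot_end_digits <- function(freq) {
  ggplot2::ggplot(freq, ggplot2::aes(x = factor(.data$digit),
                                     y = 100 * .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 10, linetype = "dashed") +
    ggplot2::labs(x = "End digit", y = "% of readings",
                  title = sprintf("End digits of %s BP",
                                  freq$component[1])) +
    ggplot2::theme_minimal()
}
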