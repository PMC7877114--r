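#' Published reference counts from the Lothian telemonitoring roll-out
#'
#' Summary counts published by the quasi-experimental evaluation of BP
#' telemonitoring in Scottish (Lothian) primary care whose methods this
#' package implements. The patient-level data sit in an NHS Safe Haven and
#' are not public; these printed counts are, and they are enough to
#' reproduce the raised-BP percentages, relative risk reductions, RRR
#' ratios, and double-zero prevalence as worked examples.
#'
#' `raised_bp_reference()` returns the raised-BP counts from the
#' standardised dataset (399 telemonitoring, 3484 comparator patients):
#' patients at or above each threshold at the index reading and 6-12 months
#' later. `end_digit_reference()` returns the double-zero counts per reading
#' source.
#'
#' @return A tibble.
#' @export
raised_bp_reference <- function() {
  path <- system.file("extdata", "raised_bp_reference.csv",
                      package = "telebp", mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname raised_bp_reference
#' @export
end_digit_reference <- function() {
  path <- system.file("extdata", "end_digit_reference.csv",
                      package = "telebp", mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
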