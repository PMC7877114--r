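#' Effect estimates
#'
#' All four analysis methods report their treatment contrast as a
#' `bp_effect`: a one-row tibble with the point estimate (mmHg unless noted),
#' standard error, 95% confidence interval, two-sided p-value, sample size
#' and a method label. `tidy()` returns it as a plain tibble.
#'
#' @param estimate,std_error,ci_lower,ci_upper,p_value,n,method Fields.
#' @param ... Extra columns (e.g. convergence flags).
#' @return A `bp_effect` tibble.
#' @keywords internal
new_bp_effect <- function(estimate, std_error, ci_lower, ci_upper,
                          p_value, n, method, ...) {
  out <- tibble(method = method, estimate = estimate, std_error = std_error,
                ci_lower = ci_lower, ci_upper = ci_upper,
                p_value = p_value, n = n, ...)
  class(out) <- c("bp_effect", class(out))
  out
}

#' @export
tidy.bp_effect <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "bp_effect")
  out
}

#' @export
print.bp_effect <- function(x, ...) {
  cat(sprintf("<bp_effect> %s\n", x$method[1]))
  cat(sprintf("  estimate %.3f (SE %.3f), 95%% CI %.3f to %.3f, p = %.4g, n = %d\n",
              x$estimate[1], x$std_error[1], x$ci_lower[1], x$ci_upper[1],
              x$p_value[1], x$n[1]))
  invisible(x)
}

# Wald summary of one fixed-effect coefficient from an lme4 (or lm
# fallback) fit.
lmer_wald_effect <- function(fit, term, n, method, ...) {
  is_mixed <- inherits(fit, "merMod")
  beta <- if (is_mixed) lme4::fixef(fit) else coef(fit)
  if (!term %in% names(beta) || is.na(beta[term])) {
    abort(sprintf("term '%s' not estimable in model (have: %s)",
                  term, paste(names(beta), collapse = ", ")))
  }
  est <- unname(beta[term])
  se <- unname(sqrt(diag(as.matrix(vcov(fit)))[term]))
  z <- est / se
  new_bp_effect(
    estimate = est, std_error = se,
    ci_lower = est - 1.96 * se, ci_upper = est + 1.96 * se,
    p_value = 2 * pnorm(-abs(z)), n = n, method = method,
    singular_fit = if (is_mixed) lme4::isSingular(fit) else FALSE, ...
  )
}

# Mixed model with a practice random intercept; falls back to the
# fixed-effects-only fit when there is a single practice (a one-level
# grouping factor has no estimable variance).
lmer_quiet <- function(formula, data, reml = TRUE) {
  bars <- lme4::findbars(formula)
  grp <- all.vars(bars[[1]])[length(all.vars(bars[[1]]))]
  if (length(unique(data[[grp]])) < 2) {
    fixed <- lme4::nobars(formula)
    return(lm(fixed, data = data))
  }
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  withCallingHandlers(
    lme4::lmer(formula, data = data, REML = reml, control = ctrl),
    message = function(m) invokeRestart("muffleMessage")
  )
}
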