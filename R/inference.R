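#' Goodness of fit of a fitted model
#'
#' The p-value is the upper tail of the central chi-square distribution with
#' the model's residual degrees of freedom, evaluated at G-squared.
#'
#' @param fit an [fit_mpt()] result.
#' @return List with `g2`, `df`, `p`.
#' @export
goodness_of_fit <- function(fit) {
  stopifnot(inherits(fit, "mpt_fit"))
  if (fit$df <= 0) stop("goodness-of-fit test requires df > 0",
                        call. = FALSE)
  list(g2 = fit$g2, df = fit$df,
       p = stats::pchisq(fit$g2, fit$df, lower.tail = FALSE))
}

#' Cohen's w effect size for a chi-square-family statistic
#'
#' `w = sqrt(delta_g2 / n_total)`, with `n_total` the total number of
#' category observations entering the test (participants times trials
#' across both conditions).
#'
#' @param delta_g2 the (nonnegative) test statistic.
#' @param n_total total category observations.
#' @return Cohen's w.
#' @examples
#' effect_size_w(25.09, 1960)  # ~0.11
#' @export
effect_size_w <- function(delta_g2, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive", call. = FALSE)
  if (any(delta_g2 < 0)) stop("delta_g2 must be nonnegative", call. = FALSE)
  sqrt(delta_g2 / n_total)
}

#' Test equality of one parameter across conditions
#'
#' Fits the model with and without an equality constraint on one parameter
#' and compares fits by the likelihood-ratio statistic
#' `delta G2 = G2_restricted - G2_full`, referred to the central chi-square
#' distribution with one degree of freedom per added constraint. The effect
#' size is Cohen's w at the table's total observation count.
#'
#' @param table a [category_table()] with two (or more) conditions.
#' @param spec_full the unrestricted [model_spec()]; default unconstrained
#'   over the table's conditions.
#' @param parameter_name one of `C`, `P_Moral`, `P_Hypocritical`,
#'   `P_Antisocial`, `b`.
#' @param ... passed to [fit_mpt()] (e.g. `n_starts`).
#' @return An object of class `"mpt_comparison"`: `parameter_tested`,
#'   `delta_g2`, `df`, `p_value`, `w`, `n_total`, plus both fits.
#' @export
compare_nested <- function(table, spec_full = NULL, parameter_name, ...) {
  if (is.null(spec_full)) spec_full <- model_spec(unique(table$condition))
  if (parameter_name %in% spec_full$constraints) {
    stop("parameter already constrained in the full model", call. = FALSE)
  }
  spec_restricted <- model_spec(spec_full$conditions,
                                c(spec_full$constraints, parameter_name))
  fit_full <- fit_mpt(table, spec_full, ...)
  fit_restricted <- fit_mpt(table, spec_restricted, ...)
  if (!fit_restricted$converged) {
    stop("restricted fit did not converge", call. = FALSE)
  }
  delta <- max(fit_restricted$g2 - fit_full$g2, 0)
  df <- spec_restricted$df - spec_full$df
  n_total <- fit_full$n_total
  structure(list(parameter_tested = parameter_name,
                 delta_g2 = delta,
                 df = df,
                 p_value = stats::pchisq(delta, df, lower.tail = FALSE),
                 w = effect_size_w(delta, n_total),
                 n_total = n_total,
                 fit_full = fit_full,
                 fit_restricted = fit_restricted),
            class = "mpt_comparison")
}

#' @export
print.mpt_comparison <- function(x, ...) {
  cat(sprintf("%s: dG2(%d) = %.2f, p %s, w = %.2f\n",
              x$parameter_tested, x$df, x$delta_g2,
              if (x$p_value < 0.001) "< 0.001"
              else sprintf("= %.3f", x$p_value),
              x$w))
  invisible(x)
}

#' Power of the chi-square test at a given effect size
#'
#' Power is the probability that a noncentral chi-square variable with
#' `df` degrees of freedom and noncentrality `lambda = n_total * w^2`
#' exceeds the central chi-square critical value at level `alpha` (the
#' G*Power convention for chi-square-family tests).
#'
#' @param w Cohen's w effect size.
#' @param n_total total category observations.
#' @param df degrees of freedom of the test.
#' @param alpha significance level.
#' @return Power in \[alpha, 1\].
#' @export
power_chisq <- function(w, n_total, df, alpha = 0.05) {
  stopifnot(n_total > 0, df > 0, alpha > 0, alpha < 1, w >= 0)
  crit <- stats::qchisq(1 - alpha, df)
  stats::pchisq(crit, df, ncp = n_total * w^2, lower.tail = FALSE)
}

#' Minimal detectable effect size (sensitivity analysis)
#'
#' Solves `power_chisq(w, n_total, df, alpha) = power` for w by bracketed
#' root finding. At the design of a 20-trial experiment with 98 (or 93)
#' participants, alpha = beta = 0.05 and df = 1 this gives the familiar
#' "small effect" w of about 0.08.
#'
#' @param alpha significance level.
#' @param power target power (1 - beta).
#' @param df degrees of freedom.
#' @param n_total total category observations.
#' @param tol root-finding tolerance in w.
#' @return The minimal detectable w.
#' @examples
#' sensitivity_w(0.05, 0.95, 1, 1960)
#' @export
sensitivity_w <- function(alpha, power, df, n_total, tol = 1e-10) {
  stopifnot(alpha > 0, alpha < power, power < 1, n_total > 0, df > 0)
  f <- function(w) power_chisq(w, n_total, df, alpha) - power
  upper <- 1
  while (f(upper) < 0 && upper < 1e6) upper <- upper * 2
  if (f(upper) < 0) stop("no bracket for the sensitivity root",
                         call. = FALSE)
  stats::uniroot(f, c(0, upper), tol = tol)$root
}
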