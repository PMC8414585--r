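# Binary-outcome power calculations for two-sample MR, following the
# non-centrality-parameter normal approximation used by the mRnd
# calculator: the test statistic for a causal odds ratio OR has mean
# sqrt(N * R2 * K * (1 - K)) * |log(OR)| where N is the outcome-GWAS
# sample size, K its case fraction and R2 the variance of the exposure
# explained by the instruments.

#' Specify a binary-outcome MR power calculation
#'
#' @param n_cases,n_controls Case and control counts of the outcome
#'   GWAS.
#' @param r2 Variance of the exposure explained by the instruments, in
#'   (0, 1).
#' @param alpha Two-sided significance level (default 0.05).
#' @param target_power Power at which detectable bounds are sought
#'   (default 0.80).
#' @return An `mr_power_spec`: list `n_total`, `case_fraction`, `r2`,
#'   `alpha`, `target_power`, `n_cases`, `n_controls`.
#' @export
power_spec <- function(n_cases, n_controls, r2, alpha = 0.05,
                       target_power = 0.80) {
  if (n_cases <= 0 || n_controls <= 0) stopf("sample sizes must be positive")
  if (r2 <= 0 || r2 >= 1) stopf("r2 must lie in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  if (target_power <= 0 || target_power >= 1) {
    stopf("target_power must lie in (0, 1)")
  }
  n_total <- n_cases + n_controls
  structure(list(n_total = n_total, case_fraction = n_cases / n_total,
                 r2 = r2, alpha = alpha, target_power = target_power,
                 n_cases = n_cases, n_controls = n_controls),
            class = "mr_power_spec")
}

ncp_scale <- function(spec) {
  k <- spec$case_fraction
  sqrt(spec$n_total * spec$r2 * k * (1 - k))
}

#' Power to detect a causal odds ratio
#'
#' `power = Phi(sqrt(N * R2 * K * (1-K)) * |log(OR)| - z_{1 - alpha/2})`,
#' monotone increasing in `|log(OR)|`, `N` and `R2`, and invariant
#' under `OR -> 1/OR`.
#'
#' @param spec An `mr_power_spec`.
#' @param or_value Causal odds ratio per SD of exposure (> 0).
#' @return Power in \[0, 1\].
#' @export
mr_power <- function(spec, or_value) {
  stopifnot(inherits(spec, "mr_power_spec"))
  if (any(or_value <= 0)) stopf("or_value must be positive")
  z <- ncp_scale(spec) * abs(log(or_value))
  stats::pnorm(z - stats::qnorm(1 - spec$alpha / 2))
}

#' Detectable odds-ratio bounds at target power
#'
#' Inverts [mr_power()] at the target power:
#' `log(OR) = (z_{1 - alpha/2} + z_{power}) / sqrt(N * R2 * K * (1-K))`.
#' The two bounds are exact reciprocals and bracket 1; effects inside
#' `(lower, upper)` are undetectable at the requested power.
#'
#' @param spec An `mr_power_spec`.
#' @param or_grid Optional vector of odds ratios at which to tabulate
#'   power.
#' @return An `mr_power_result`: list `detectable_or_upper`,
#'   `detectable_or_lower`, `power_at` (`data.frame` when `or_grid`
#'   given, else `NULL`) and `spec`.
#' @export
detectable_or <- function(spec, or_grid = NULL) {
  stopifnot(inherits(spec, "mr_power_spec"))
  lor <- (stats::qnorm(1 - spec$alpha / 2) + stats::qnorm(spec$target_power)) /
    ncp_scale(spec)
  power_at <- NULL
  if (!is.null(or_grid)) {
    power_at <- data.frame(or = or_grid, power = mr_power(spec, or_grid))
  }
  structure(list(detectable_or_upper = exp(lor),
                 detectable_or_lower = exp(-lor),
                 power_at = power_at, spec = spec),
            class = "mr_power_result")
}

#' @export
print.mr_power_result <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "MR power (N = %d cases + %d controls, R2 = %.3f, alpha = %.3g, power = %.2f)\n",
    s$n_cases, s$n_controls, s$r2, s$alpha, s$target_power))
  cat(sprintf("  detectable OR bounds: < %.3f or > %.3f\n",
              x$detectable_or_lower, x$detectable_or_upper))
  if (!is.null(x$power_at)) {
    print(x$power_at, row.names = FALSE, ...)
  }
  invisible(x)
}
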