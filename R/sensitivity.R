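# Heterogeneity and robustness diagnostics for harmonized instrument sets.

#' Cochran's Q heterogeneity test
#'
#' Measures dispersion of the per-variant Wald ratios around the
#' fixed-effect IVW estimate using IVW weights on the ratio scale,
#' `w = x^2 / sy^2`: `Q = sum(w * (theta - beta_ivw)^2)`, which equals
#' the weighted residual sum of squares of the zero-intercept IVW
#' regression. `Q` is referred to a chi-square distribution with
#' `k - 1` degrees of freedom; `I^2 = max(0, 100 * (Q - df) / Q)`
#' (Higgins convention, floored at zero, reported as a percentage).
#'
#' @param pairs An `instrument_set` or harmonized-pair `data.frame`
#'   with at least 2 instruments.
#' @return An `mr_heterogeneity` object: list `q`, `df`, `pvalue`, `i2`.
#' @export
cochran_q <- function(pairs) {
  p <- as_pairs(pairs)
  k <- nrow(p)
  if (k < 2) stopf("Cochran's Q requires at least 2 instruments (got %d)", k)
  if (any(p$x == 0)) stopf("degenerate instrument with zero exposure effect")
  theta <- p$y / p$x
  w <- p$x^2 / p$sy^2
  beta <- sum(w * theta) / sum(w)
  q <- sum(w * (theta - beta)^2)
  df <- k - 1
  i2 <- if (q > 0) max(0, 100 * (q - df) / q) else 0
  structure(list(q = q, df = df,
                 pvalue = stats::pchisq(q, df, lower.tail = FALSE),
                 i2 = i2),
            class = "mr_heterogeneity")
}

#' @export
print.mr_heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f (df %d), p = %.3g, I^2 = %.1f%%\n",
              x$q, x$df, x$pvalue, x$i2))
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the pooled causal effect omitting each instrument in
#' turn, using the same primary estimator as the full set
#' (correlation-adjusted IVW when an LD matrix is supplied, plain
#' fixed-effect IVW otherwise). Rows whose confidence interval
#' excludes the full-set point estimate are flagged.
#'
#' @param pairs An `instrument_set` or harmonized-pair `data.frame`
#'   with at least 3 instruments.
#' @param corr Optional LD correlation matrix (sub-matrices are
#'   extracted per left-out variant); defaults to the instrument set's
#'   attached matrix.
#' @return An `mr_loo` object: list with `rows` (`data.frame`
#'   `variant_id`, `n_snps`, `beta`, `se`, `ci_low`, `ci_high`,
#'   `pvalue`, `excludes_full`) and `full` (the all-instrument
#'   `mr_estimate`).
#' @export
leave_one_out <- function(pairs, corr = NULL) {
  if (is.null(corr) && inherits(pairs, "instrument_set")) {
    corr <- pairs$correlation
  }
  p <- as_pairs(pairs)
  k <- nrow(p)
  if (k < 3) stopf("leave-one-out requires at least 3 instruments (got %d)", k)
  corr <- align_corr(corr, p$variant_id)
  fit <- function(sub, sub_corr) {
    if (is.null(sub_corr)) mr_ivw(sub) else mr_ivw_correlated(sub, sub_corr)
  }
  full <- fit(p, corr)
  rows <- lapply(seq_len(k), function(i) {
    est <- fit(p[-i, , drop = FALSE],
               if (is.null(corr)) NULL else corr[-i, -i, drop = FALSE])
    data.frame(variant_id = p$variant_id[i], n_snps = est$n_snps,
               beta = est$beta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high,
               pvalue = est$pvalue,
               excludes_full = full$beta < est$ci_low | full$beta > est$ci_high,
               stringsAsFactors = FALSE)
  })
  structure(list(rows = do.call(rbind, rows), full = full),
            class = "mr_loo")
}

#' @export
print.mr_loo <- function(x, ...) {
  cat(sprintf("Leave-one-out (full-set beta = %.4f, %s)\n",
              x$full$beta, x$full$method))
  print(x$rows, ...)
  invisible(x)
}
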