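# Causal-effect estimators on harmonized instrument sets. All methods
# operate on the (x, sx, y, sy) parametrization: x is the variant's
# effect on the exposure, y its effect on the outcome, both per the
# same effect allele after harmonization.

new_mr_estimate <- function(method, beta, se, n_snps, pvalue = NULL,
                            ci_level = 0.95) {
  beta <- unname(beta)
  se <- unname(se)
  if (!is.finite(se) || se <= 0) stopf("estimate standard error must be > 0")
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  if (is.null(pvalue)) pvalue <- two_sided_p(beta / se)
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - z * se, ci_high = beta + z * se,
                 pvalue = pvalue, n_snps = n_snps, ci_level = ci_level),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate (%s, %d SNP%s)\n", x$method, x$n_snps,
              if (x$n_snps == 1) "" else "s"))
  cat(sprintf("  beta = %.4f (se %.4f), %d%% CI [%.4f, %.4f], p = %.3g\n",
              x$beta, x$se, round(100 * x$ci_level), x$ci_low, x$ci_high,
              x$pvalue))
  if (!is.null(x$or)) {
    cat(sprintf("  OR = %.3f, %d%% CI [%.3f, %.3f]\n", x$or,
                round(100 * x$ci_level), x$or_ci_low, x$or_ci_high))
  }
  invisible(x)
}

#' Express a causal estimate on the odds-ratio scale
#'
#' Exponentiates the beta-scale estimate and its confidence bounds;
#' meaningful when the outcome effects are log odds ratios.
#'
#' @param est An `mr_estimate`.
#' @return The estimate with `or`, `or_ci_low`, `or_ci_high` added.
#' @export
as_odds_ratio <- function(est) {
  stopifnot(inherits(est, "mr_estimate"))
  est$or <- exp(est$beta)
  est$or_ci_low <- exp(est$ci_low)
  est$or_ci_high <- exp(est$ci_high)
  est
}

#' Per-variant Wald ratio estimates
#'
#' The Wald ratio divides the variant-outcome effect by the
#' variant-exposure effect, `theta = y / x`, with first-order standard
#' error `sy / |x|` and a two-sided normal p-value.
#'
#' @param pairs An `instrument_set` or harmonized-pair `data.frame`.
#' @return `data.frame` with one row per variant: `variant_id`,
#'   `theta`, `se_theta`, `pvalue`.
#' @export
wald_ratio <- function(pairs) {
  p <- as_pairs(pairs)
  zero <- p$x == 0
  if (any(zero)) {
    stopf("degenerate instrument(s) with zero exposure effect: %s",
          paste(p$variant_id[zero], collapse = ", "))
  }
  theta <- p$y / p$x
  se_theta <- p$sy / abs(p$x)
  data.frame(variant_id = p$variant_id, theta = theta, se_theta = se_theta,
             pvalue = two_sided_p(theta / se_theta),
             stringsAsFactors = FALSE)
}

#' Fixed-effect inverse-variance weighted estimate
#'
#' Pools the per-variant Wald ratios with inverse-variance weights:
#' `beta = sum(x * y / sy^2) / sum(x^2 / sy^2)` with standard error
#' `1 / sqrt(sum(x^2 / sy^2))` — algebraically the zero-intercept
#' weighted least-squares regression of `y` on `x` with weights
#' `1 / sy^2`. An optional multiplicative random-effects scaling
#' `max(1, sqrt(Q / (k - 1)))` inflates the standard error under
#' heterogeneity; the fixed-effect form is the default.
#'
#' @param pairs An `instrument_set` or harmonized-pair `data.frame`.
#' @param random_effects Apply multiplicative random-effects scaling
#'   to the standard error (default `FALSE`).
#' @return An `mr_estimate` with `method = "ivw"`.
#' @export
mr_ivw <- function(pairs, random_effects = FALSE) {
  p <- as_pairs(pairs)
  k <- nrow(p)
  if (k < 1) stopf("IVW requires at least one instrument")
  w <- 1 / p$sy^2
  denom <- sum(p$x^2 * w)
  beta <- sum(p$x * p$y * w) / denom
  se <- 1 / sqrt(denom)
  if (random_effects && k >= 2) {
    q <- sum(w * (p$y - beta * p$x)^2)
    se <- se * max(1, sqrt(q / (k - 1)))
  }
  new_mr_estimate("ivw", beta, se, k)
}

#' Correlation-adjusted (generalized least squares) IVW estimate
#'
#' When instruments are in linkage disequilibrium their outcome-effect
#' estimates are correlated; the pooled estimate is then the
#' generalized least-squares regression of `y` on `x` through the
#' origin with covariance `Omega[j, k] = sy[j] * sy[k] * r[j, k]`:
#' `beta = (x' Omega^-1 y) / (x' Omega^-1 x)`,
#' `se = sqrt(1 / (x' Omega^-1 x))`. With an identity matrix this
#' reduces exactly to [mr_ivw()].
#'
#' @param pairs An `instrument_set` (its attached correlation is used
#'   when `corr` is missing) or harmonized-pair `data.frame`.
#' @param corr Square LD correlation matrix aligned to the pairs
#'   (reordered by dimnames when present).
#' @return An `mr_estimate` with `method = "ivw_correlated"`.
#' @export
mr_ivw_correlated <- function(pairs, corr = NULL) {
  if (is.null(corr) && inherits(pairs, "instrument_set")) {
    corr <- pairs$correlation
  }
  p <- as_pairs(pairs)
  if (is.null(corr)) stopf("a correlation matrix is required")
  corr <- align_corr(corr, p$variant_id)
  omega <- outer(p$sy, p$sy) * corr
  ch <- tryCatch(chol(omega), error = function(e) NULL)
  if (is.null(ch)) {
    stopf(paste("instrument covariance is singular; prune perfectly",
                "correlated instruments before the adjusted IVW"))
  }
  oi_x <- backsolve(ch, forwardsolve(t(ch), p$x))
  oi_y <- backsolve(ch, forwardsolve(t(ch), p$y))
  denom <- sum(p$x * oi_x)
  beta <- sum(p$x * oi_y) / denom
  se <- sqrt(1 / denom)
  new_mr_estimate("ivw_correlated", beta, se, nrow(p))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome on exposure effects with a
#' free intercept, each instrument oriented so its exposure effect is
#' non-negative (x and y negated jointly when `x < 0`). The slope is a
#' pleiotropy-adjusted causal estimate under the InSIDE assumption;
#' a non-zero intercept indicates directional (unbalanced) horizontal
#' pleiotropy. Standard errors use multiplicative residual scaling
#' `max(1, sqrt(RSS_w / (k - 2)))`; the intercept test uses a
#' t-distribution with `k - 2` degrees of freedom.
#'
#' @param pairs An `instrument_set` or harmonized-pair `data.frame`
#'   with at least 3 instruments.
#' @return An `mr_egger` object: list with `slope` (an `mr_estimate`,
#'   `method = "egger_slope"`), `intercept` (list `value`, `se`,
#'   `pvalue`, `df`) and `residual_scale`.
#' @export
mr_egger <- function(pairs) {
  p <- as_pairs(pairs)
  k <- nrow(p)
  if (k < 3) stopf("MR-Egger requires at least 3 instruments (got %d)", k)
  s <- ifelse(p$x < 0, -1, 1)
  x <- s * p$x
  y <- s * p$y
  w <- 1 / p$sy^2
  xmat <- cbind(intercept = 1, slope = x)
  xtwx <- crossprod(xmat, w * xmat)
  coef <- solve(xtwx, crossprod(xmat, w * y))
  res <- y - xmat %*% coef
  rss_w <- sum(w * res^2)
  phi2 <- max(1, rss_w / (k - 2))
  covm <- solve(xtwx) * phi2
  se <- sqrt(diag(covm))
  slope <- new_mr_estimate("egger_slope", coef["slope", 1], se["slope"], k)
  t_int <- unname(coef["intercept", 1] / se["intercept"])
  intercept <- list(value = unname(coef["intercept", 1]),
                    se = unname(se["intercept"]),
                    pvalue = 2 * stats::pt(-abs(t_int), df = k - 2),
                    df = k - 2)
  structure(list(slope = slope, intercept = intercept,
                 residual_scale = sqrt(phi2)),
            class = "mr_egger")
}

#' @export
print.mr_egger <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  Egger intercept = %.4f (se %.4f), p = %.3g [t, %d df]\n",
              x$intercept$value, x$intercept$se, x$intercept$pvalue,
              x$intercept$df))
  invisible(x)
}

# Weighted median of values `v` with weights `w`: sort by (v, id), form
# standardized mid-point cumulative weights and interpolate at 0.5.
weighted_median_point <- function(v, w, ids = seq_along(v)) {
  ord <- order(v, ids)
  v <- v[ord]; w <- w[ord]
  pk <- (cumsum(w) - w / 2) / sum(w)
  if (length(v) == 1) return(v)
  stats::approx(pk, v, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted median estimate
#'
#' Consistent causal estimate when instruments carrying more than half
#' of the weight are valid. Per-variant ratios `theta = y / x` receive
#' inverse-variance weights `x^2 / sy^2` (first-order ratio variance
#' `sy^2 / x^2`); the estimate interpolates the ratio at standardized
#' cumulative weight 0.5. The standard error is a parametric
#' bootstrap: each replicate redraws `x ~ N(x, sx)` and `y ~ N(y, sy)`
#' per instrument and recomputes the weighted median; the reported SE
#' is the standard deviation across replicates, deterministic for a
#' given `seed`.
#'
#' @param pairs An `instrument_set` or harmonized-pair `data.frame`
#'   with at least 3 instruments.
#' @param n_boot Bootstrap replicates (default 10000).
#' @param seed RNG seed for the bootstrap (default 1), recorded in the
#'   result.
#' @return An `mr_estimate` with `method = "weighted_median"` and a
#'   `boot` element recording `n_boot` and `seed`.
#' @export
mr_weighted_median <- function(pairs, n_boot = 10000, seed = 1) {
  p <- as_pairs(pairs)
  k <- nrow(p)
  if (k < 3) stopf("weighted median requires at least 3 instruments (got %d)", k)
  if (n_boot < 1) stopf("n_boot must be >= 1")
  if (any(p$x == 0)) stopf("degenerate instrument with zero exposure effect")
  theta <- p$y / p$x
  w <- p$x^2 / p$sy^2
  est <- weighted_median_point(theta, w, p$variant_id)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      xb <- stats::rnorm(k, p$x, p$sx)
      yb <- stats::rnorm(k, p$y, p$sy)
      weighted_median_point(yb / xb, xb^2 / p$sy^2, p$variant_id)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  out <- new_mr_estimate("weighted_median", est, se, k)
  out$boot <- list(n_boot = n_boot, seed = seed)
  out
}
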