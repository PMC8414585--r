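# Fixture builders and independent oracles shared across tests.

make_pairs <- function(x, y, sx = rep(0.05, length(x)),
                       sy = rep(0.05, length(x)),
                       ids = sprintf("rs%d", seq_along(x))) {
  data.frame(variant_id = ids, x = x, sx = sx, y = y, sy = sy,
             flipped = FALSE, stringsAsFactors = FALSE)
}

random_pairs <- function(k) {
  make_pairs(x = stats::runif(k, 0.1, 0.6) * sample(c(-1, 1), k, replace = TRUE),
             y = stats::rnorm(k, 0, 0.1),
             sx = stats::runif(k, 0.01, 0.08),
             sy = stats::runif(k, 0.01, 0.08))
}

# Zero-intercept weighted regression oracle via lm's QR path; the
# fixed-effect SE strips lm's residual-variance scaling.
ivw_oracle <- function(pairs) {
  fit <- stats::lm(y ~ 0 + x, data = pairs, weights = 1 / pairs$sy^2)
  s <- summary(fit)
  list(beta = unname(stats::coef(fit)["x"]),
       se = unname(s$coefficients["x", "Std. Error"] / s$sigma))
}

# GLS through the origin via explicit solve() on the full covariance.
gls_oracle <- function(pairs, corr) {
  omega <- outer(pairs$sy, pairs$sy) * corr
  oi <- solve(omega)
  denom <- drop(t(pairs$x) %*% oi %*% pairs$x)
  list(beta = drop(t(pairs$x) %*% oi %*% pairs$y) / denom,
       se = sqrt(1 / denom))
}

write_sumstats_text <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

simple_sumstats <- function(ids, beta, se, pvalue,
                            ea = rep("A", length(ids)),
                            oa = rep("G", length(ids)),
                            eaf = rep(0.3, length(ids))) {
  data.frame(variant_id = ids, chrom = "1", pos = seq_along(ids),
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pvalue = pvalue, n = 1000,
             stringsAsFactors = FALSE)
}
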