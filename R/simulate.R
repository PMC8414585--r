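# Synthetic GWAS summary-statistic generator. Summary statistics are
# simulated directly (no individual-level genotypes): per-variant
# effects are drawn around a known causal model and perturbed with
# sampling noise at the large-sample standard errors, which is what a
# two-sample MR analysis actually consumes and keeps generation at
# fractions of a second.

#' Configure a synthetic two-sample MR study
#'
#' Defines the ground truth of a simulated exposure GWAS (continuous
#' trait in SD units) and outcome GWAS (binary trait, log-OR scale):
#' a causal effect, a per-variant direct (pleiotropic) effect
#' distribution, instrument strengths pinned to a total
#' explained-variance target, allele frequencies, sample sizes, and an
#' optional uniform LD correlation between instruments. Defaults mirror
#' a five-instrument serum-biomarker exposure explaining 21.5% of
#' variance in 5,440 individuals against a case-control outcome GWAS of
#' 21,982 cases and 41,944 controls.
#'
#' @param n_snps Number of instruments (>= 1).
#' @param causal_beta True causal effect (log-OR per SD of exposure).
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the per-variant
#'   direct effect on the outcome; `(0, 0)` means no pleiotropy.
#' @param maf_range Interval for effect-allele frequencies, inside
#'   (0, 0.5).
#' @param n_exposure Exposure-GWAS sample size.
#' @param n_outcome_cases,n_outcome_controls Outcome-GWAS counts.
#' @param r2_target Total exposure variance explained by the true
#'   instrument effects, in (0, 1); default 0.215.
#' @param ld_block_r Uniform correlation between all instruments
#'   (single LD block), `|ld_block_r| < 1`; 0 for independence.
#' @param seed RNG seed; the study is reproducible bit-for-bit from
#'   the config.
#' @return An `mr_sim_config` list.
#' @export
simulation_config <- function(n_snps = 5, causal_beta = 0,
                              pleiotropy_mean = 0, pleiotropy_sd = 0,
                              maf_range = c(0.10, 0.40),
                              n_exposure = 5440,
                              n_outcome_cases = 21982,
                              n_outcome_controls = 41944,
                              r2_target = 0.215,
                              ld_block_r = 0, seed = 1) {
  if (n_snps < 1) stopf("n_snps must be >= 1")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] >= 0.5 ||
      maf_range[1] > maf_range[2]) {
    stopf("maf_range must lie inside (0, 0.5)")
  }
  if (n_exposure <= 0 || n_outcome_cases <= 0 || n_outcome_controls <= 0) {
    stopf("sample sizes must be positive")
  }
  if (r2_target <= 0 || r2_target >= 1) {
    stopf("explained-variance target r2_target must lie in (0, 1); %g is unattainable",
          r2_target)
  }
  if (pleiotropy_sd < 0) stopf("pleiotropy_sd must be >= 0")
  if (abs(ld_block_r) >= 1) stopf("|ld_block_r| must be < 1")
  structure(list(n_snps = n_snps, causal_beta = causal_beta,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 maf_range = maf_range, n_exposure = n_exposure,
                 n_outcome_cases = n_outcome_cases,
                 n_outcome_controls = n_outcome_controls,
                 r2_target = r2_target, ld_block_r = ld_block_r,
                 seed = seed),
            class = "mr_sim_config")
}

# Correlated standard normals with uniform correlation r (one block).
corr_noise <- function(k, r) {
  z <- stats::rnorm(k)
  if (r == 0 || k == 1) return(z)
  m <- matrix(r, k, k); diag(m) <- 1
  drop(crossprod(chol(m), z))
}

#' Simulate a two-sample MR study
#'
#' Draws allele frequencies uniformly in `maf_range`; true exposure
#' effects `b_k = sqrt(r2_k / (2 f_k (1 - f_k)))` where the `r2_k` are
#' a random partition of `r2_target` (so the total explained variance
#' `sum(2 f_k (1 - f_k) b_k^2)` hits the target exactly); observed
#' exposure effects `~ N(b_k, se_x)` with
#' `se_x = 1 / sqrt(2 f (1 - f) n_exposure)`; true outcome effects
#' `causal_beta * b_k + alpha_k` with pleiotropy
#' `alpha_k ~ N(pleiotropy_mean, pleiotropy_sd^2)`; observed outcome
#' effects `~ N(truth, se_y)` with the binary-trait SE
#' `se_y = 1 / sqrt(2 f (1 - f) N K (1 - K))`. Sampling noise is
#' correlated across instruments when `ld_block_r` is set. P-values
#' are two-sided normal.
#'
#' @param config An `mr_sim_config`.
#' @return An `mr_sim_study`: list with `exposure` and `outcome`
#'   summary-statistic `data.frame`s (same variant ids, standard
#'   columns), `correlation` (the LD matrix used for the noise),
#'   `truth` (the config), and the realized `true_beta_x` and
#'   `true_pleiotropy` vectors.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "mr_sim_config"))
  k <- config$n_snps
  with_seed(config$seed, {
    f <- stats::runif(k, config$maf_range[1], config$maf_range[2])
    u <- stats::runif(k, 0.5, 1.5)
    r2_k <- config$r2_target * u / sum(u)
    het <- 2 * f * (1 - f)
    b <- sqrt(r2_k / het)
    n_out <- config$n_outcome_cases + config$n_outcome_controls
    kk <- config$n_outcome_cases / n_out
    se_x <- 1 / sqrt(het * config$n_exposure)
    se_y <- 1 / sqrt(het * n_out * kk * (1 - kk))
    alpha <- stats::rnorm(k, config$pleiotropy_mean, config$pleiotropy_sd)
    beta_x <- b + se_x * corr_noise(k, config$ld_block_r)
    beta_y <- config$causal_beta * b + alpha +
      se_y * corr_noise(k, config$ld_block_r)
    ids <- sprintf("rs%07d", 1000000 + seq_len(k))
    allele_pool <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                        c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
    alleles <- allele_pool[1 + (seq_len(k) - 1) %% length(allele_pool)]
    ea <- vapply(alleles, `[`, character(1), 1)
    oa <- vapply(alleles, `[`, character(1), 2)
    make_stats <- function(beta, se, n) {
      data.frame(variant_id = ids, chrom = "1",
                 pos = 1000000L + 10000L * seq_len(k),
                 effect_allele = ea, other_allele = oa, eaf = f,
                 beta = beta, se = se,
                 pvalue = two_sided_p(beta / se), n = n,
                 stringsAsFactors = FALSE)
    }
    corr <- matrix(config$ld_block_r, k, k, dimnames = list(ids, ids))
    diag(corr) <- 1
    structure(list(exposure = make_stats(beta_x, se_x, config$n_exposure),
                   outcome = make_stats(beta_y, se_y, n_out),
                   correlation = corr, truth = config,
                   true_beta_x = b, true_pleiotropy = alpha),
              class = "mr_sim_study")
  })
}

#' Reference five-instrument study fixture
#'
#' A fixed-seed synthetic study shaped like a serum-biomarker MR
#' against a late-onset neurodegenerative disease: 5 instruments
#' jointly explaining 21.5% of exposure variance in a 5,440-person
#' exposure GWAS, against an outcome GWAS of 21,982 cases and 41,944
#' controls, with a modest true causal effect `log(1.14)`.
#'
#' @param seed RNG seed (default 101).
#' @param causal_beta True causal effect (default `log(1.14)`).
#' @return An `mr_sim_study`.
#' @export
reference_study <- function(seed = 101, causal_beta = log(1.14)) {
  simulate_study(simulation_config(n_snps = 5, causal_beta = causal_beta,
                                   seed = seed))
}

#' Write a simulated study to disk in the standard delimited formats
#'
#' Materializes `exposure.tsv`, `outcome.tsv` and `ld_matrix.tsv`
#' under `dir`, readable back with [read_sumstats()] and
#' [read_correlation_matrix()].
#'
#' @param study An `mr_sim_study`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "mr_sim_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"),
             outcome = file.path(dir, "outcome.tsv"),
             ld = file.path(dir, "ld_matrix.tsv"))
  write_sumstats(study$exposure, paths["exposure"])
  write_sumstats(study$outcome, paths["outcome"])
  write_correlation_matrix(study$correlation, paths["ld"])
  invisible(paths)
}

#' Named simulation scenarios
#'
#' Convenience configurations for the canonical validation scenarios:
#' `"null"` (no causal effect, no pleiotropy), `"causal"`
#' (`causal_beta = log(1.14)`), `"balanced_pleiotropy"`
#' (`causal_beta = 0`, zero-mean pleiotropy), `"directional_pleiotropy"`
#' (causal effect plus mean-0.05 pleiotropy; InSIDE holds by
#' construction), and `"correlated_instruments"` (uniform LD r = 0.3).
#'
#' @param name Scenario name.
#' @param seed RNG seed.
#' @return An `mr_sim_config`.
#' @export
scenario_config <- function(name = c("null", "causal", "balanced_pleiotropy",
                                     "directional_pleiotropy",
                                     "correlated_instruments"),
                            seed = 1) {
  name <- match.arg(name)
  switch(name,
    null = simulation_config(seed = seed),
    causal = simulation_config(causal_beta = log(1.14), seed = seed),
    balanced_pleiotropy = simulation_config(pleiotropy_sd = 0.05, seed = seed),
    directional_pleiotropy = simulation_config(causal_beta = log(1.14),
                                               pleiotropy_mean = 0.05,
                                               pleiotropy_sd = 0.02,
                                               seed = seed),
    correlated_instruments = simulation_config(causal_beta = log(1.14),
                                               ld_block_r = 0.3, seed = seed))
}
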