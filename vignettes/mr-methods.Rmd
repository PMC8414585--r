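---
title: "Methods: two-sample Mendelian randomization in gwasmr"
author: "gwasmr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in gwasmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasmr)
```

## The problem and the model

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure (here the
motivating case is a circulating biomarker such as serum GDF-15,
measured in SD units, with 1 SD of GDF-15 approximately 625 pg/ml;
see `sd_to_pgml()`) on an outcome (a binary disease trait on the
log-odds scale). Because allele assignment is randomized at
conception, a variant that (i) robustly associates with the exposure,
(ii) is independent of confounders, and (iii) affects the outcome only
through the exposure identifies the causal effect even when
observational associations are confounded.

In the *two-sample* design the variant–exposure effects
$X_k \pm \sigma_{X_k}$ and variant–outcome effects
$Y_k \pm \sigma_{Y_k}$ come from different GWAS, and only summary
statistics are needed. After harmonization (below), each instrument
supplies a Wald ratio $\hat\theta_k = Y_k / X_k$ with first-order
standard error $\sigma_{Y_k} / |X_k|$.

### Pooled estimators

* **IVW** (`mr_ivw()`): the fixed-effect inverse-variance weighted
  estimate
  $\hat\beta = \sum_k X_k Y_k \sigma_{Y_k}^{-2} \big/ \sum_k X_k^2 \sigma_{Y_k}^{-2}$,
  $\hat\sigma = \big(\sum_k X_k^2 \sigma_{Y_k}^{-2}\big)^{-1/2}$ —
  algebraically the zero-intercept weighted least-squares regression of
  $Y$ on $X$ with weights $\sigma_Y^{-2}$. The fixed-effect form is
  the default; a multiplicative random-effects scaling
  $\max(1, \sqrt{Q/(k-1)})$ is available behind
  `random_effects = TRUE` for heterogeneous sets.
* **Correlation-adjusted IVW** (`mr_ivw_correlated()`): instruments in
  linkage disequilibrium have correlated outcome-effect estimates.
  With an LD $r$-matrix, the pooled estimate is generalized least
  squares through the origin with
  $\Omega_{jk} = \sigma_{Y_j}\sigma_{Y_k} r_{jk}$:
  $\hat\beta = (X^\top\Omega^{-1}X)^{-1}X^\top\Omega^{-1}Y$,
  $\hat\sigma = \sqrt{(X^\top\Omega^{-1}X)^{-1}}$. With an identity
  matrix it reduces exactly to the IVW formula (a tested invariant).
  The solve goes through a Cholesky factorization; a singular
  $\Omega$ (e.g. two copies of the same variant at $r = 1$) is
  reported as an error suggesting pruning.
* **MR-Egger** (`mr_egger()`): weighted regression of $Y$ on $X$ with
  a free intercept, each instrument first oriented so $X_k \ge 0$
  (negating $X$ and $Y$ jointly). Under the InSIDE assumption the
  slope is a pleiotropy-adjusted causal estimate and the intercept
  estimates the average direct (pleiotropic) effect; a non-zero
  intercept flags directional pleiotropy. Standard errors carry the
  multiplicative residual scale $\max(1, \sqrt{RSS_w/(k-2)})$, and
  the intercept test uses a $t$ reference with $k-2$ degrees of
  freedom. Confidence intervals elsewhere are normal
  ($\pm 1.96\,\hat\sigma$), matching common MR-package behavior.
* **Weighted median** (`mr_weighted_median()`): consistent when
  instruments carrying more than 50% of the weight are valid.
  Ratios are weighted by the first-order inverse variance
  $X_k^2/\sigma_{Y_k}^2$, sorted (stable tie-break on
  `(ratio, variant_id)`), and the estimate interpolates the ratio at
  standardized cumulative weight $p_k = (\sum_{j\le k} w_j - w_k/2) / \sum_j w_j = 0.5$.
  The standard error is a parametric bootstrap: each replicate redraws
  $X_k \sim N(X_k, \sigma_{X_k})$, $Y_k \sim N(Y_k, \sigma_{Y_k})$
  and recomputes the estimate; defaults are 10,000 replicates and
  seed 1, both recorded in the result so runs are reproducible. The
  second-order ratio-variance weight variant is deliberately not
  offered; the first-order weight is consistent with the Wald-ratio
  SE used everywhere else.

### Sensitivity analyses

* **Cochran's Q / I²** (`cochran_q()`): with ratio-scale IVW weights
  $w_k = X_k^2/\sigma_{Y_k}^2$,
  $Q = \sum_k w_k (\hat\theta_k - \hat\beta_{IVW})^2$, which equals
  the weighted residual sum of squares of the zero-intercept IVW
  regression (a tested identity). $Q$ is referred to
  $\chi^2_{k-1}$; $I^2 = \max(0, 100\,(Q - df)/Q)$ — the Higgins
  convention, floored at zero and reported as a percentage.
* **Leave-one-out** (`leave_one_out()`): re-estimates the pooled
  effect omitting each instrument in turn, re-using the primary
  estimator (correlation-adjusted IVW with the corresponding LD
  sub-matrix when a matrix is attached) and flagging rows whose CI
  excludes the full-set point estimate.

### Power for binary outcomes

`mr_power()` and `detectable_or()` implement the
non-centrality-parameter normal approximation used by mRnd-style
calculators: with outcome-GWAS size $N$, case fraction $K$ and
instrument $R^2$,
$z = \sqrt{N R^2 K(1-K)}\,|\log OR|$ and
$\text{power} = \Phi(z - z_{1-\alpha/2})$; inverting at the target
power gives
$\log OR = (z_{1-\alpha/2} + z_{power}) / \sqrt{N R^2 K(1-K)}$.
The two detectable bounds are exact reciprocals. With $R^2 = 0.215$
and the three motivating case-control designs this reproduces upper
bounds of about 1.035 (33,674/449,056), 1.050 (20,806/59,804) and
1.052 (21,982/41,944). The first two match the corresponding
published intervals to the printed precision; for the largest-effect
design the published figure is 1.057, about 0.5% higher on the OR
scale, consistent with a slightly different calculator input (for
example a binary-outcome attenuation term or a different effective
sample size); we keep the transparent closed form rather than tuning
to the published figure. Discovery-phase case/control counts are used
for $K$, and $\alpha$ is two-sided throughout.

## Harmonization

Public GWAS report effects against arbitrarily chosen effect alleles,
so exposure and outcome records must be aligned before any ratio is
taken. `harmonize()` applies the standard two-sample convention:

* identical allele coding: copy effects;
* swapped labels: negate the outcome effect (`flipped = TRUE`);
* strand-complement coding (non-palindromic variants only):
  complement, then align as above;
* palindromic variants (A/T, C/G), for which label swap and strand
  flip are indistinguishable: retained only when both effect-allele
  frequencies are present, fall on the same side of 0.5 after label
  alignment, and lie outside `[limit, 1 − limit]` with
  `palindrome_eaf_limit = 0.42` by default (a common MR-package
  default). Everything else — including opposite-side frequencies,
  which some pipelines would interpret as a strand flip — is dropped
  as `palindromic_ambiguous`. We chose the conservative drop because
  frequency-based strand inference is exactly the step that silently
  corrupts estimates when one study's frequencies are mislabeled.
* Variants missing from the outcome are dropped
  (`missing_in_outcome`); matching is by rsID only, with chrom/pos
  carried as untouched metadata (no liftover).

Instrument selection (`select_instruments()`) uses a strict
`p < 5e-8` by default; a `strict = FALSE` flag gives `<=` since
published materials write the threshold both ways.

## The synthetic-data generator

`simulate_study()` generates summary statistics directly — no
individual-level genotypes — because the analysis consumes only
summary data and direct simulation keeps a full replicate suite at
seconds. Per instrument $k$:

* allele frequency $f_k \sim U(\text{maf\_range})$, default
  $U(0.10, 0.40)$ (common variants, as instrument panels for
  circulating proteins typically are);
* true exposure effects $b_k = \sqrt{r^2_k / (2 f_k (1-f_k))}$ with
  $r^2_k$ a random partition of the explained-variance target
  (default 0.215), so $\sum_k 2 f_k (1-f_k) b_k^2$ hits the target
  exactly. Effects are drawn as positive magnitudes — the convention
  of coding the effect allele as the exposure-increasing allele —
  which keeps the sign of directional pleiotropy meaningful under
  MR-Egger's $x \ge 0$ orientation;
* observed exposure effect $\sim N(b_k, 1/\sqrt{2 f_k (1-f_k) n_x})$
  (large-sample SE for a continuous trait in SD units);
* true outcome effect $\beta_{causal} b_k + \alpha_k$ with direct
  effects $\alpha_k \sim N(\mu_\alpha, \sigma_\alpha^2)$ drawn
  independently of $b_k$, so InSIDE holds by construction;
* observed outcome effect $\sim N(\cdot, 1/\sqrt{2 f_k (1-f_k) N K (1-K)})$
  (large-sample SE for a log-OR from a case-control GWAS of size $N$
  and case fraction $K$);
* optional uniform LD: with `ld_block_r` set, sampling noise is drawn
  with a single-block compound-symmetric correlation (via Cholesky),
  and the same matrix is emitted as the study's LD matrix.

All randomness flows from one seeded generator per study
(`with_seed` restores the caller's RNG state), so a study is
reproducible bit-for-bit from its config; replicate suites advance the
seed deterministically. Default sample sizes (5 instruments, exposure
$n = 5440$, outcome 21,982 cases / 41,944 controls) mirror a
realistic serum-biomarker-versus-late-onset-disease design;
`reference_study()` freezes that shape at seed 101 with a modest true
effect $\log(1.14)$.

What the generator does *not* emulate: sample overlap between the two
GWAS, winner's curse in instrument selection, allele-frequency
mismatch between studies, population stratification, and non-normal
effect-size noise. Passing calibration tests therefore validates the
estimators and pipeline plumbing under the stated model, not
robustness to those real-data pathologies.

### What the simulation suite establishes

The acceptance tests run (sizes chosen to keep the suite at a few
seconds while leaving Monte-Carlo error well inside the asserted
bands): 1,000 null replicates (type-I error $0.05 \pm 0.02$ and 95%
CI coverage $0.95 \pm 0.02$ for IVW), 500 causal replicates (mean
bias below 5% of the true effect; the residual attenuation from noise
in $X$ is of order $1/(n_x r^2_k) \approx 0.4\%$ here), and 500
directional-pleiotropy replicates (mean Egger intercept within 3
Monte-Carlo SEs of the true mean direct effect while IVW is
detectably biased — the canonical Egger/IVW discrimination property).

## Pipeline and multiplicity

`analysis_plan()` / `run_plan()` orchestrate any number of
exposure–outcome pairs — e.g. three diseases in both directions, six
pairs — applying per pair: selection, harmonization, Wald ratios, the
primary pooled estimate (correlation-adjusted IVW when an LD matrix
is supplied, plain IVW otherwise, mirroring the common asymmetry
where an $r$-matrix is only available for the forward instruments),
weighted median and MR-Egger when $k \ge 3$, Q/I², leave-one-out,
and an optional detectable-OR power calculation. Significance is
Bonferroni family-wise: a pair is flagged only when its primary
p-value is below $\alpha / n_{pairs}$ (0.05/6 ≈ 0.00833 for the
six-pair design). Binary-outcome estimates are exponentiated to ORs
per 1 SD of exposure; continuous (reverse-direction) estimates stay
on the beta scale, an SD change per unit log-OR. A failed pair is
recorded and the run continues. `write_report()` emits tidy tables
(forest/estimates, Wald, heterogeneity + Egger intercept,
leave-one-out, power) plus a YAML manifest with versions, seeds and
thresholds for provenance.

## Numerical choices and degenerate inputs

* Correlation matrices are validated to unit diagonal and symmetry
  within 1e-6 (then symmetrized by averaging); non-PSD matrices
  warn. GLS uses Cholesky; singularity is an error, not a silent
  pseudo-inverse.
* A zero exposure effect makes the Wald ratio undefined and is
  reported as a degenerate-instrument error naming the variant.
* $I^2$ is floored at 0; $Q = 0$ gives $I^2 = 0$, $p = 1$.
* Weighted-median ties break on `(ratio, variant_id)` so results do
  not depend on input order.
* p-values are kept at full precision; any 3-decimal rounding is
  presentation only.

## Known limitations

Estimates are only as good as the instruments: the package implements
no MR-PRESSO, mode-based, multivariable or Steiger extensions, no LD
clumping (the $r$-matrix is supplied, not computed), no proxy-SNP
lookup, and no GWAS-VCF parsing. The power formula is the simple NCP
approximation; calculators that model binary-outcome attenuation can
give slightly wider bounds (see above).
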