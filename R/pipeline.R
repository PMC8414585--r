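# Plan-driven orchestration of bidirectional analyses across
# exposure-outcome pairs, with family-wise Bonferroni correction and
# tidy report tables backing forest / scatter / leave-one-out displays.

#' Define an analysis plan
#'
#' A plan lists exposure-outcome pairs to analyze and the family-wise
#' significance policy. Each pair is a list with elements:
#' \describe{
#'   \item{exposure, outcome}{summary-statistic `data.frame`s or file
#'     paths readable by [read_sumstats()] (mandatory)}
#'   \item{label}{pair label (defaults to the list name or
#'     `"pair<i>"`)}
#'   \item{correlation}{optional LD matrix or file path}
#'   \item{binary}{outcome is binary, so estimates are exponentiated
#'     to odds ratios (default `TRUE`)}
#'   \item{p_threshold, strict}{instrument-selection threshold
#'     (default `5e-8`, strict `<`)}
#'   \item{palindrome_eaf_limit}{harmonization ambiguity band
#'     (default 0.42)}
#'   \item{n_boot, seed}{weighted-median bootstrap configuration
#'     (defaults 10000 and 1)}
#'   \item{power}{optional list `n_cases`, `n_controls`, `r2` (plus
#'     optional `alpha`, `target_power`) for the detectable-OR
#'     calculation}
#' }
#' The family-wise threshold is Bonferroni: `alpha / length(pairs)`.
#'
#' @param pairs List of pair specifications.
#' @param alpha Base significance level (default 0.05).
#' @return An `mr_plan`.
#' @export
analysis_plan <- function(pairs, alpha = 0.05) {
  if (!is.list(pairs) || length(pairs) < 1) {
    stopf("an analysis plan needs at least one exposure-outcome pair")
  }
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  labels <- names(pairs)
  if (is.null(labels)) labels <- rep("", length(pairs))
  pairs <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    if (is.null(p$exposure) || is.null(p$outcome)) {
      stopf("pair %d lacks an exposure or outcome dataset", i)
    }
    defaults <- list(label = if (nzchar(labels[i])) labels[i] else
                       sprintf("pair%d", i),
                     correlation = NULL, binary = TRUE,
                     p_threshold = 5e-8, strict = TRUE,
                     palindrome_eaf_limit = 0.42,
                     n_boot = 10000, seed = 1, power = NULL)
    for (nm in names(defaults)) if (is.null(p[[nm]])) p[[nm]] <- defaults[[nm]]
    p
  })
  structure(list(pairs = pairs, alpha = alpha,
                 alpha_family = alpha / length(pairs)),
            class = "mr_plan")
}

#' Read an analysis plan from a YAML file
#'
#' The file holds `alpha` (optional) and `pairs`, a map of pair
#' specifications as in [analysis_plan()]; `exposure`, `outcome` and
#' `correlation` entries are file paths resolved relative to the plan
#' file's directory.
#'
#' @param path Path to the YAML plan.
#' @return An `mr_plan`.
#' @export
read_plan <- function(path) {
  doc <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.character(p) && !file.exists(p)) file.path(base, p) else p
  }
  pairs <- lapply(doc$pairs, function(p) {
    for (nm in c("exposure", "outcome", "correlation")) {
      if (!is.null(p[[nm]])) p[[nm]] <- resolve(p[[nm]])
    }
    p
  })
  analysis_plan(pairs, alpha = if (is.null(doc$alpha)) 0.05 else doc$alpha)
}

load_dataset <- function(x) {
  if (is.character(x)) read_sumstats(x) else x
}

run_pair <- function(p, alpha_family) {
  exposure <- load_dataset(p$exposure)
  outcome <- load_dataset(p$outcome)
  instruments <- select_instruments(exposure, p$p_threshold, p$strict)
  iset <- harmonize(instruments, outcome,
                    palindrome_eaf_limit = p$palindrome_eaf_limit,
                    exposure_name = paste0(p$label, ":exposure"),
                    outcome_name = paste0(p$label, ":outcome"))
  corr <- p$correlation
  if (is.character(corr)) {
    corr <- read_correlation_matrix(corr, iset$pairs$variant_id)
  }
  if (!is.null(corr)) iset <- set_correlation(iset, corr)
  k <- nrow(iset$pairs)
  primary <- if (is.null(iset$correlation)) mr_ivw(iset) else
    mr_ivw_correlated(iset)
  estimates <- list(primary)
  egger <- NULL
  if (k >= 3) {
    wm <- mr_weighted_median(iset, n_boot = p$n_boot, seed = p$seed)
    egger <- mr_egger(iset)
    estimates <- c(estimates, list(wm, egger$slope))
  }
  if (p$binary) estimates <- lapply(estimates, as_odds_ratio)
  heterogeneity <- if (k >= 2) cochran_q(iset) else NULL
  loo <- if (k >= 3) leave_one_out(iset) else NULL
  power <- NULL
  if (!is.null(p$power)) {
    pw <- p$power
    spec <- power_spec(pw$n_cases, pw$n_controls, pw$r2,
                       alpha = if (is.null(pw$alpha)) 0.05 else pw$alpha,
                       target_power = if (is.null(pw$target_power)) 0.80 else
                         pw$target_power)
    power <- detectable_or(spec)
  }
  list(label = p$label, binary = p$binary, instruments = iset,
       wald = wald_ratio(iset), estimates = estimates, egger = egger,
       heterogeneity = heterogeneity, leave_one_out = loo, power = power,
       significant = primary$pvalue < alpha_family,
       seed = p$seed, n_boot = p$n_boot, error = NULL)
}

#' Run an analysis plan
#'
#' For each pair: select instruments, harmonize, compute per-variant
#' Wald ratios, the primary pooled estimate (correlation-adjusted IVW
#' when an LD matrix is supplied, fixed-effect IVW otherwise), the
#' weighted median and MR-Egger (when at least 3 instruments),
#' Cochran's Q, leave-one-out, and the optional power calculation.
#' A pair that fails (e.g. no overlapping instruments) is recorded with
#' its error message and the run continues. Significance flags use the
#' Bonferroni family-wise threshold `alpha / n_pairs` on the primary
#' estimate.
#'
#' @param plan An `mr_plan`.
#' @return An `mr_report`: list with `pairs` (per-pair result lists),
#'   `alpha`, `alpha_family`, `n_pairs`, `n_failed`.
#' @export
run_plan <- function(plan) {
  stopifnot(inherits(plan, "mr_plan"))
  results <- lapply(plan$pairs, function(p) {
    tryCatch(run_pair(p, plan$alpha_family), error = function(e) {
      message(sprintf("pair '%s' failed: %s", p$label, conditionMessage(e)))
      list(label = p$label, binary = p$binary, error = conditionMessage(e))
    })
  })
  names(results) <- vapply(results, `[[`, character(1), "label")
  structure(list(pairs = results, alpha = plan$alpha,
                 alpha_family = plan$alpha_family,
                 n_pairs = length(results),
                 n_failed = sum(vapply(results,
                                       function(r) !is.null(r$error),
                                       logical(1)))),
            class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("MR study report: %d pair(s), %d failed, family-wise alpha = %.5f\n",
              x$n_pairs, x$n_failed, x$alpha_family))
  ft <- forest_table(x)
  print(ft, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Forest-plot table of pooled estimates
#'
#' One row per (pair, method) with beta-scale and, for binary
#' outcomes, exponentiated odds-ratio columns — the content of a
#' forest display of IVW, weighted-median and MR-Egger estimates.
#'
#' @param report An `mr_report`.
#' @return `data.frame` with columns `label`, `method`, `n_snps`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `pvalue`, `or`, `or_ci_low`,
#'   `or_ci_high` (OR columns `NA` for non-binary pairs),
#'   `significant`.
#' @export
forest_table <- function(report) {
  stopifnot(inherits(report, "mr_report"))
  rows <- list()
  for (r in report$pairs) {
    if (!is.null(r$error)) next
    for (est in r$estimates) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = r$label, method = est$method, n_snps = est$n_snps,
        beta = est$beta, se = est$se,
        ci_low = est$ci_low, ci_high = est$ci_high, pvalue = est$pvalue,
        or = if (r$binary) est$or else NA_real_,
        or_ci_low = if (r$binary) est$or_ci_low else NA_real_,
        or_ci_high = if (r$binary) est$or_ci_high else NA_real_,
        significant = r$significant && est$method %in%
          c("ivw", "ivw_correlated"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    stopf("report contains no successful pairs")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Leave-one-out table across pairs
#'
#' @param report An `mr_report`.
#' @return `data.frame` with one row per (pair, left-out variant):
#'   `label`, `variant_id`, `n_snps`, `beta`, `ci_low`, `ci_high`,
#'   `excludes_full`, plus the full-set estimate per pair.
#' @export
loo_table <- function(report) {
  stopifnot(inherits(report, "mr_report"))
  rows <- list()
  for (r in report$pairs) {
    if (is.null(r$leave_one_out)) next
    tab <- r$leave_one_out$rows
    tab <- cbind(label = r$label, tab,
                 full_beta = r$leave_one_out$full$beta,
                 stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- tab
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a study report as tidy delimited tables
#'
#' Emits `estimates.tsv` (the forest table), `wald.tsv`,
#' `heterogeneity.tsv` (Q, df, p, I^2 and the Egger intercept test per
#' pair), `leave_one_out.tsv`, `power.tsv` and a `manifest.yaml`
#' recording the package version, thresholds and seeds.
#'
#' @param report An `mr_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mr_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(x, name) {
    if (is.null(x) || !nrow(x)) return(invisible(NULL))
    utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(forest_table(report), "estimates.tsv")
  wald <- do.call(rbind, lapply(report$pairs, function(r) {
    if (is.null(r$wald)) return(NULL)
    cbind(label = r$label, r$wald, stringsAsFactors = FALSE)
  }))
  wt(wald, "wald.tsv")
  het <- do.call(rbind, lapply(report$pairs, function(r) {
    if (is.null(r$heterogeneity)) return(NULL)
    h <- r$heterogeneity
    data.frame(label = r$label, q = h$q, df = h$df, pvalue = h$pvalue,
               i2 = h$i2,
               egger_intercept = if (is.null(r$egger)) NA_real_ else
                 r$egger$intercept$value,
               egger_intercept_se = if (is.null(r$egger)) NA_real_ else
                 r$egger$intercept$se,
               egger_intercept_p = if (is.null(r$egger)) NA_real_ else
                 r$egger$intercept$pvalue,
               stringsAsFactors = FALSE)
  }))
  wt(het, "heterogeneity.tsv")
  wt(loo_table(report), "leave_one_out.tsv")
  pw <- do.call(rbind, lapply(report$pairs, function(r) {
    if (is.null(r$power)) return(NULL)
    s <- r$power$spec
    data.frame(label = r$label, n_cases = s$n_cases,
               n_controls = s$n_controls, r2 = s$r2, alpha = s$alpha,
               target_power = s$target_power,
               detectable_or_lower = r$power$detectable_or_lower,
               detectable_or_upper = r$power$detectable_or_upper,
               stringsAsFactors = FALSE)
  }))
  wt(pw, "power.tsv")
  manifest <- list(
    package = "gwasmr",
    version = as.character(utils::packageVersion("gwasmr")),
    alpha = report$alpha, alpha_family = report$alpha_family,
    n_pairs = report$n_pairs, n_failed = report$n_failed,
    pairs = lapply(report$pairs, function(r) {
      if (!is.null(r$error)) return(list(label = r$label, error = r$error))
      list(label = r$label, binary = r$binary,
           n_instruments = nrow(r$instruments$pairs),
           weighted_median_seed = r$seed, weighted_median_n_boot = r$n_boot)
    }))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
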