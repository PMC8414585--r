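#' Default column map for summary-statistic tables
#'
#' Maps the standard field names used throughout the package to the
#' column names expected in a delimited summary-statistic file.
#' `chrom`, `pos`, `eaf` and `n` are optional; the remaining fields are
#' mandatory.
#'
#' @return Named character vector `standard field -> column name`.
#' @export
default_column_map <- function() {
  c(variant_id = "SNP", chrom = "chrom", pos = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", pvalue = "pval", n = "n")
}

MANDATORY_FIELDS <- c("variant_id", "effect_allele", "other_allele",
                      "beta", "se", "pvalue")

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or comma-delimited table (auto-detected from the header
#' line) of per-variant association statistics. Alleles are uppercased.
#' Rows with unparseable or invalid values (non-numeric beta/se,
#' `se <= 0`, p-value outside (0, 1], alleles not a single A/C/G/T, or
#' identical effect and other alleles) are dropped; the counts are
#' reported via [message()] and attached as the `"n_dropped"` attribute.
#'
#' @param path Path to the delimited file (header row required).
#' @param column_map Named character vector mapping standard fields to
#'   column names; see [default_column_map()].
#' @return A `data.frame` with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`,
#'   `n` (optional fields are `NA` when absent from the file).
#' @export
read_sumstats <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) stopf("summary-statistic file not found: %s", path)
  sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  map_col <- function(field) {
    if (field %in% names(column_map)) column_map[[field]] else NA_character_
  }
  for (field in MANDATORY_FIELDS) {
    col <- map_col(field)
    if (is.na(col)) {
      stopf("column map does not define mandatory field '%s'", field)
    }
    if (!col %in% names(raw)) {
      stopf("mandatory column '%s' (field '%s') not found in %s",
            col, field, path)
    }
  }
  get_col <- function(field, as = "character") {
    col <- map_col(field)
    if (is.na(col) || !col %in% names(raw)) {
      return(rep(NA, nrow(raw)))
    }
    v <- raw[[col]]
    if (as == "numeric") suppressWarnings(as.numeric(v)) else as.character(v)
  }
  out <- data.frame(
    variant_id = get_col("variant_id"),
    chrom = as.character(get_col("chrom")),
    pos = suppressWarnings(as.integer(get_col("pos", "numeric"))),
    effect_allele = toupper(get_col("effect_allele")),
    other_allele = toupper(get_col("other_allele")),
    eaf = get_col("eaf", "numeric"),
    beta = get_col("beta", "numeric"),
    se = get_col("se", "numeric"),
    pvalue = get_col("pvalue", "numeric"),
    n = get_col("n", "numeric"),
    stringsAsFactors = FALSE
  )
  bad_num <- is.na(out$beta) | is.na(out$se)
  bad_se <- !bad_num & out$se <= 0
  bad_p <- !is.na(out$pvalue) & (out$pvalue <= 0 | out$pvalue > 1)
  bad_p <- bad_p | is.na(out$pvalue)
  ok_allele <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  bad_allele <- !(ok_allele(out$effect_allele) & ok_allele(out$other_allele)) |
    out$effect_allele == out$other_allele
  bad_eaf <- !is.na(out$eaf) & (out$eaf < 0 | out$eaf > 1)
  drop <- bad_num | bad_se | bad_p | bad_allele | bad_eaf
  n_drop <- sum(drop)
  if (n_drop > 0) {
    message(sprintf(
      "read_sumstats: %d/%d row(s) dropped (%d unparseable beta/se, %d se<=0, %d bad p, %d bad alleles, %d bad eaf)",
      n_drop, nrow(out), sum(bad_num), sum(bad_se), sum(bad_p & !bad_num),
      sum(bad_allele), sum(bad_eaf)))
  }
  message(sprintf("read_sumstats: %s: %d row(s) read, %d retained",
                  basename(path), nrow(out), nrow(out) - n_drop))
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_drop
  out
}

#' Write summary statistics to a delimited text file
#'
#' Inverse of [read_sumstats()] under the default column map.
#'
#' @param x Summary-statistic `data.frame` (standard columns).
#' @param path Output path.
#' @param sep Field separator, tab by default.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path, sep = "\t") {
  map <- default_column_map()
  out <- data.frame(
    SNP = x$variant_id, chrom = x$chrom, pos = x$pos,
    effect_allele = x$effect_allele, other_allele = x$other_allele,
    eaf = x$eaf, beta = x$beta, se = x$se, pval = x$pvalue, n = x$n,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  names(out) <- unname(map[c("variant_id", "chrom", "pos", "effect_allele",
                             "other_allele", "eaf", "beta", "se", "pvalue", "n")])
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select instrumental variables by p-value threshold
#'
#' Keeps variants whose exposure association p-value falls below the
#' genome-wide significance threshold, preserving input order.
#'
#' @param assocs Summary-statistic `data.frame`.
#' @param p_threshold Significance threshold in (0, 1); default `5e-8`.
#' @param strict Use strict `<` (default). `FALSE` uses `<=`.
#' @return The retained rows of `assocs`.
#' @export
select_instruments <- function(assocs, p_threshold = 5e-8, strict = TRUE) {
  if (!is.numeric(p_threshold) || length(p_threshold) != 1 ||
      is.na(p_threshold) || p_threshold <= 0 || p_threshold >= 1) {
    stopf("p_threshold must be a single number in (0, 1)")
  }
  keep <- if (strict) assocs$pvalue < p_threshold else assocs$pvalue <= p_threshold
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) {
    stopf("no instruments: no variant has p %s %g",
          if (strict) "<" else "<=", p_threshold)
  }
  out <- assocs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) COMPLEMENT[[ea]] == oa

#' Harmonize exposure and outcome associations to a common effect allele
#'
#' Aligns each shared variant's outcome association onto the exposure's
#' effect allele: swapped allele labels negate the outcome effect
#' (`flipped = TRUE`); non-palindromic variants coded on the opposite
#' strand are complemented and then aligned. Palindromic variants (A/T
#' or C/G), whose strand cannot be resolved from allele labels, are
#' retained only when both allele frequencies are present, fall on the
#' same side of 0.5 after label alignment, and lie outside
#' `[palindrome_eaf_limit, 1 - palindrome_eaf_limit]`; otherwise they
#' are dropped with reason `"palindromic_ambiguous"`. Variants absent
#' from the outcome are dropped with reason `"missing_in_outcome"`;
#' irreconcilable allele pairs with `"allele_mismatch"`.
#'
#' @param exposure,outcome Summary-statistic `data.frame`s keyed by
#'   `variant_id`.
#' @param palindrome_eaf_limit Ambiguity band half-width in (0, 0.5);
#'   default 0.42.
#' @param exposure_name,outcome_name Labels carried into the result.
#' @return An `instrument_set`: list with `exposure`, `outcome`,
#'   `pairs` (data.frame `variant_id`, `x`, `sx`, `y`, `sy`, `flipped`),
#'   `dropped` (data.frame `variant_id`, `dropped_reason`) and
#'   `correlation` (`NULL` until [set_correlation()] is called).
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_limit = 0.42,
                      exposure_name = "exposure", outcome_name = "outcome") {
  if (!is.numeric(palindrome_eaf_limit) || palindrome_eaf_limit <= 0 ||
      palindrome_eaf_limit >= 0.5) {
    stopf("palindrome_eaf_limit must lie in (0, 0.5)")
  }
  if (anyDuplicated(exposure$variant_id) || anyDuplicated(outcome$variant_id)) {
    stopf("variant_id must be unique within each dataset")
  }
  o_idx <- match(exposure$variant_id, outcome$variant_id)
  pairs <- list()
  dropped <- list()
  add_drop <- function(id, reason) {
    dropped[[length(dropped) + 1L]] <<- data.frame(
      variant_id = id, dropped_reason = reason, stringsAsFactors = FALSE)
  }
  band_lo <- palindrome_eaf_limit
  band_hi <- 1 - palindrome_eaf_limit
  for (i in seq_len(nrow(exposure))) {
    id <- exposure$variant_id[i]
    j <- o_idx[i]
    if (is.na(j)) { add_drop(id, "missing_in_outcome"); next }
    ea <- exposure$effect_allele[i]; oa <- exposure$other_allele[i]
    oe <- outcome$effect_allele[j]; oo <- outcome$other_allele[j]
    y <- outcome$beta[j]; o_eaf <- outcome$eaf[j]
    flipped <- FALSE
    if (is_palindromic(ea, oa)) {
      # label swap and strand flip are indistinguishable; align by labels
      # then require unambiguous frequencies on a common side of 0.5
      if (identical(c(oe, oo), c(ea, oa))) {
        # as-is
      } else if (identical(c(oe, oo), c(oa, ea))) {
        y <- -y; flipped <- TRUE
        if (!is.na(o_eaf)) o_eaf <- 1 - o_eaf
      } else {
        add_drop(id, "allele_mismatch"); next
      }
      x_eaf <- exposure$eaf[i]
      ambiguous <- is.na(x_eaf) || is.na(o_eaf) ||
        (x_eaf >= band_lo && x_eaf <= band_hi) ||
        (o_eaf >= band_lo && o_eaf <= band_hi) ||
        ((x_eaf < 0.5) != (o_eaf < 0.5))
      if (ambiguous) { add_drop(id, "palindromic_ambiguous"); next }
    } else {
      ce <- COMPLEMENT[[oe]]; co <- COMPLEMENT[[oo]]
      if (identical(c(oe, oo), c(ea, oa))) {
        # as-is
      } else if (identical(c(oe, oo), c(oa, ea))) {
        y <- -y; flipped <- TRUE
      } else if (identical(c(ce, co), c(ea, oa))) {
        # opposite strand, same orientation
      } else if (identical(c(ce, co), c(oa, ea))) {
        y <- -y; flipped <- TRUE
      } else {
        add_drop(id, "allele_mismatch"); next
      }
    }
    pairs[[length(pairs) + 1L]] <- data.frame(
      variant_id = id, x = exposure$beta[i], sx = exposure$se[i],
      y = y, sy = outcome$se[j], flipped = flipped,
      stringsAsFactors = FALSE)
  }
  pairs_df <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(variant_id = character(), x = numeric(), sx = numeric(),
               y = numeric(), sy = numeric(), flipped = logical())
  dropped_df <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(variant_id = character(), dropped_reason = character())
  if (nrow(pairs_df) == 0) {
    stopf("no overlapping instruments between %s and %s after harmonization",
          exposure_name, outcome_name)
  }
  message(sprintf("harmonize: %s vs %s: %d instrument(s) retained, %d dropped",
                  exposure_name, outcome_name, nrow(pairs_df), nrow(dropped_df)))
  structure(list(exposure = exposure_name, outcome = outcome_name,
                 pairs = pairs_df, dropped = dropped_df, correlation = NULL),
            class = "instrument_set")
}

#' Attach an LD correlation matrix to an instrument set
#'
#' Restricts and reorders the matrix to the retained instruments so its
#' row/column order matches the pair order.
#'
#' @param iset An `instrument_set` from [harmonize()].
#' @param corr Square correlation matrix with variant ids as dimnames.
#' @return The updated `instrument_set`.
#' @export
set_correlation <- function(iset, corr) {
  stopifnot(inherits(iset, "instrument_set"))
  iset$correlation <- align_corr(corr, iset$pairs$variant_id)
  iset
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set: %s -> %s\n", x$exposure, x$outcome))
  cat(sprintf("  %d harmonized instrument(s), %d dropped%s\n",
              nrow(x$pairs), nrow(x$dropped),
              if (!is.null(x$correlation)) ", LD matrix attached" else ""))
  print(x$pairs, ...)
  invisible(x)
}

#' Read an LD correlation (r-value) matrix
#'
#' Reads a square delimited table with variant ids as header row and
#' first column, validates it (unit diagonal and symmetry to 1e-6,
#' entries in \[-1, 1\]), symmetrizes by averaging, and reorders it to
#' `ids`. A warning is emitted if the matrix is not positive
#' semi-definite within numerical tolerance.
#'
#' @param path Path to the delimited matrix file.
#' @param ids Ordered variant ids the matrix must be aligned to.
#' @return Numeric matrix with `ids` as dimnames.
#' @export
read_correlation_matrix <- function(path, ids) {
  if (!file.exists(path)) stopf("correlation matrix file not found: %s", path)
  sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(raw)
  if (nrow(m) != ncol(m)) stopf("correlation matrix must be square")
  if (!setequal(rownames(m), colnames(m))) {
    stopf("correlation matrix row and column ids differ")
  }
  missing <- setdiff(ids, rownames(m))
  if (length(missing)) {
    stopf("correlation matrix lacks variant(s): %s", paste(missing, collapse = ", "))
  }
  m <- m[ids, ids, drop = FALSE]
  if (any(abs(diag(m) - 1) > 1e-6)) {
    stopf("correlation matrix diagonal deviates from 1 beyond 1e-6")
  }
  asym <- abs(m - t(m))
  if (any(asym > 1e-6)) {
    stopf("correlation matrix asymmetry exceeds 1e-6 (max %.3g)", max(asym))
  }
  m <- (m + t(m)) / 2
  diag(m) <- 1
  if (any(m < -1 - 1e-12) || any(m > 1 + 1e-12)) {
    stopf("correlation entries must lie in [-1, 1]")
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    warning(sprintf("correlation matrix is not positive semi-definite (min eigenvalue %.3g)",
                    min(ev)), call. = FALSE)
  }
  m
}

#' Write an LD correlation matrix
#'
#' Inverse of [read_correlation_matrix()].
#'
#' @param m Square correlation matrix with dimnames.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_correlation_matrix <- function(m, path, sep = "\t") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert exposure effects from SD units to pg/ml
#'
#' One standard deviation of circulating GDF-15 corresponds to
#' approximately 625.0 pg/ml; effects estimated per SD can be rescaled
#' to concentration units for interpretation.
#'
#' @param x_sd Effect in SD units.
#' @param sd_pgml pg/ml per SD (default 625.0).
#' @return `x_sd * sd_pgml`.
#' @export
sd_to_pgml <- function(x_sd, sd_pgml = 625.0) {
  x_sd * sd_pgml
}
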