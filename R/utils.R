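# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so seeded routines never perturb user code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Accept either an instrument_set or a bare data.frame of harmonized pairs.
as_pairs <- function(pairs) {
  if (inherits(pairs, "instrument_set")) pairs <- pairs$pairs
  if (!is.data.frame(pairs)) {
    stopf("expected an instrument_set or a data.frame of harmonized pairs")
  }
  needed <- c("variant_id", "x", "sx", "y", "sy")
  missing <- setdiff(needed, names(pairs))
  if (length(missing)) {
    stopf("harmonized pairs lack column(s): %s", paste(missing, collapse = ", "))
  }
  if (any(pairs$sx <= 0) || any(pairs$sy <= 0)) {
    stopf("harmonized pairs must have strictly positive standard errors")
  }
  pairs
}

# Align a correlation matrix to the pair order, by dimnames when present.
align_corr <- function(corr, ids) {
  if (is.null(corr)) return(NULL)
  if (!is.matrix(corr) || nrow(corr) != ncol(corr)) {
    stopf("correlation must be a square matrix")
  }
  if (!is.null(rownames(corr))) {
    missing <- setdiff(ids, rownames(corr))
    if (length(missing)) {
      stopf("correlation matrix lacks variant(s): %s", paste(missing, collapse = ", "))
    }
    corr <- corr[ids, ids, drop = FALSE]
  } else if (nrow(corr) != length(ids)) {
    stopf("unnamed correlation matrix has dimension %d but %d instruments",
          nrow(corr), length(ids))
  }
  corr
}

two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))
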