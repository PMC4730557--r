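#' Standardize a numeric vector to zero mean and unit SD
#'
#' @param x numeric vector.
#' @return `(x - mean(x)) / sd(x)`; errors if `x` is constant.
#' @keywords internal
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps) {
    stop("cannot standardize a constant (or degenerate) variable")
  }
  (x - mean(x)) / s
}

# Column-wise z-scoring of a matrix / data.frame, returning a matrix.
zscore_cols <- function(x) {
  x <- as.matrix(x)
  apply(x, 2, zscore)
}

# Derive a reproducible 32-bit sub-seed from a base seed and a stream index.
# Keeps results independent across participants while fully determined by
# the configured seed.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 2017 + as.numeric(stream) * 7919) %%
               2147483647)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  }
  invisible(x)
}
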