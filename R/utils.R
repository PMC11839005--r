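#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# log(sum(exp(x))) without overflow; -Inf for empty input.
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference
# underflows or b >= a (numerically empty set).
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# Column-wise average ranks, then centered and scaled to unit SD.
# Columns with zero rank variance become NA columns (flagged upstream).
rank_standardize <- function(X) {
  R <- apply(X, 2L, rank, ties.method = "average")
  if (is.null(dim(R))) R <- matrix(R, ncol = ncol(X), dimnames = dimnames(X))
  R <- scale(R)
  R[, attr(R, "scaled:scale") == 0] <- NA_real_
  R
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
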