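# Shared numeric and RNG helpers.

#' Round half away from zero at a fixed number of decimals
#'
#' Commercial ("half-up") rounding, used everywhere a printed table cell is
#' reproduced. Base R's `round()` rounds half to even, which cannot reproduce
#' values such as an entity share of 50.65% printed as 50.7%.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(2.5)        # 3, where round(2.5) == 2
#' round_half_up(3.0678, 2)  # 3.07
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # pre-round at 9 decimals to absorb binary representation error (e.g.
  # 0.5 stored as 0.49999999999) before the floor-based half-up step
  floor(round(x * p, 9) + 0.5) / p
}

# log(sum(exp(x))) with max-shift; returns -Inf for empty/all -Inf input
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Column-wise logsumexp of a matrix
col_logsumexp <- function(m) {
  mx <- apply(m, 2L, max)
  ok <- is.finite(mx)
  out <- mx
  if (any(ok)) {
    sh <- sweep(m[, ok, drop = FALSE], 2L, mx[ok], "-")
    out[ok] <- mx[ok] + log(colSums(exp(sh)))
  }
  out
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
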