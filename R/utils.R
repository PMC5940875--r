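# Internal helpers shared across modules.

# Round half away from zero (all image/metric quantities here are >= 0, so
# this is round-half-up). base::round() rounds half to even, which would not
# reproduce the reporting arithmetic.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Mean filter with a (2r+1) x (2r+1) box, normalized by the number of cells
# actually inside the image, so edges are averaged over the truncated window.
box_blur <- function(m, r) {
  if (r <= 0) return(m)
  sums <- running_sum_2d(m, r)
  cnts <- running_sum_2d(matrix(1, nrow(m), ncol(m)), r)
  sums / cnts
}

# Sum of each (2r+1)-box via cumulative sums along rows then columns.
running_sum_2d <- function(m, r) {
  m <- apply_running_sum(m, r)
  t(apply_running_sum(t(m), r))
}

apply_running_sum <- function(m, r) {
  n <- nrow(m)
  cs <- apply(m, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = n)
  upper <- cs[pmin(seq_len(n) + r, n), , drop = FALSE]
  lowidx <- seq_len(n) - r - 1
  lower <- matrix(0, n, ncol(m))
  keep <- lowidx >= 1
  lower[keep, ] <- cs[lowidx[keep], , drop = FALSE]
  upper - lower
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so generation never perturbs an enclosing simulation.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
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

stop_egsvm <- function(...) {
  stop(..., call. = FALSE)
}
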