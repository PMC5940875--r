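# Independent straight-line oracles for the feature-extraction chain.
# Deliberately share no code with the package: histograms via table(),
# explicit loops, naive arithmetic. Used to cross-check the implementation.

oracle_round_half_up <- function(x) trunc(x + 0.5)  # all inputs >= 0 here

oracle_entropy <- function(img) {
  tab <- table(as.vector(img))
  p <- as.numeric(tab) / sum(tab)
  h <- 0
  for (pi in p) h <- h - pi * log(pi, base = 2)
  h
}

oracle_equalize <- function(img) {
  v <- as.vector(img)
  n <- length(v)
  out <- numeric(n)
  lvls <- sort(unique(v))
  cdf <- vapply(lvls, function(l) sum(v <= l), numeric(1))
  cdf_min <- min(cdf)
  if (n == cdf_min) return(img)
  for (i in seq_len(n)) {
    ci <- sum(v <= v[i])
    out[i] <- oracle_round_half_up(255 * (ci - cdf_min) / (n - cdf_min))
  }
  matrix(out, nrow(img), ncol(img))
}

oracle_normalize <- function(sub) {
  m <- max(sub)
  if (m == 0) return(sub)
  out <- sub
  for (i in seq_along(sub)) {
    out[i] <- min(255, oracle_round_half_up(sub[i] * 255 / m))
  }
  out
}

# Enumerate the centered expanding windows by the stated rule: window k is
# max(1, round-half-up(k * dim / n)) pixels in each dimension, centered with
# the odd leftover row/column pushed to the bottom/right.
oracle_windows <- function(H, W, n) {
  out <- vector("list", n)
  for (k in 1:n) {
    h <- max(1, oracle_round_half_up(k * H / n))
    w <- max(1, oracle_round_half_up(k * W / n))
    top <- floor((H - h) / 2)
    left <- floor((W - w) / 2)
    out[[k]] <- c(top = top, left = left, bottom = top + h, right = left + w)
  }
  out
}

oracle_extract_features <- function(img, n = 50) {
  wins <- oracle_windows(nrow(img), ncol(img), n)
  h1 <- numeric(n)
  h2 <- numeric(n)
  for (k in 1:n) {
    w <- wins[[k]]
    sub <- img[(w["top"] + 1):w["bottom"], (w["left"] + 1):w["right"],
               drop = FALSE]
    nm <- oracle_normalize(sub)
    h1[k] <- oracle_entropy(nm)
    h2[k] <- oracle_entropy(oracle_equalize(nm))
  }
  grad <- function(h) {
    g <- numeric(length(h) - 1)
    for (k in seq_along(g)) g[k] <- h[k + 1] - h[k]
    g
  }
  c(grad(h1), grad(h2))
}

# Small deterministic test image with a mix of gray levels.
fixture_image <- function(h = 20, w = 20, seed = 20, levels = 0:255) {
  set.seed(seed)
  matrix(sample(levels, h * w, replace = TRUE), h, w)
}
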