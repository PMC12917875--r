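# Independent brute-force oracles used across the suite.

# All binary monotone matrices of a (small) shape, by filtering every binary
# matrix. Exponential in I*J; keep I*J <= 16.
brute_force_contours <- function(I, J) {
  n <- I * J
  out <- list()
  for (k in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(k))[seq_len(n)]
    m <- matrix(bits, I, J, byrow = TRUE)
    ok <- TRUE
    if (I > 1) ok <- ok && all(m[-1, ] >= m[-I, , drop = FALSE])
    if (ok && J > 1) ok <- ok && all(m[, -1] >= m[, -J, drop = FALSE])
    if (ok) out[[length(out) + 1L]] <- m
  }
  out
}

# Direct double-loop evaluation of the contour posterior.
brute_force_contour_posterior <- function(p, mats) {
  w <- vapply(mats, function(C) {
    v <- 1
    for (i in seq_len(nrow(C))) for (j in seq_len(ncol(C))) {
      v <- v * if (C[i, j] == 1) 1 - p[i, j] else p[i, j]
    }
    v
  }, numeric(1))
  w / sum(w)
}

# Random monotone matrix with entries in [lo, hi] (cumulative sums of
# nonnegative increments, rescaled).
random_monotone_matrix <- function(I, J, lo = 0, hi = 1) {
  inc_r <- matrix(stats::rexp(I * J), I, J)
  m <- t(apply(apply(inc_r, 2, cumsum), 1, cumsum))
  lo + (hi - lo) * (m - min(m)) / (max(m) - min(m) + 1e-12)
}

# A small mid-trial state with the default 3x3 fixture prior.
make_state <- function(n, y, ...) {
  st <- new_trial_state(dim(n), ...)
  st$n <- n
  st$y <- y
  st
}
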