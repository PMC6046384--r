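# Independent reference implementations used as oracles.

# Brute-force all-pairs sample entropy, O(N^2), written directly from the
# definition: B counts template pairs of length m within tolerance under
# the Chebyshev metric (self-matches excluded), A the pairs still within
# tolerance at length m + 1; SampEn = -log(A/B).
brute_sampen <- function(x, m, r_frac) {
  n <- length(x)
  tol <- r_frac * sd(x)
  nt <- n - m
  B <- 0L
  A <- 0L
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= tol) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= tol) A <- A + 1L
      }
    }
  }
  if (B == 0L || A == 0L) return(NA_real_)
  -log(A / B)
}

# Reference single-forward-pass central-window scan operating on an
# explicit keep/drop mask over the original series rather than on a
# shrinking vector.
reference_window_scan <- function(x, hw, frac) {
  alive <- rep(TRUE, length(x))
  # position = index among currently-alive elements of the window centre
  pos <- hw + 1L
  repeat {
    idx <- which(alive)
    if (pos + hw > length(idx)) break
    centre <- idx[pos]
    nb <- c(idx[(pos - hw):(pos - 1L)], idx[(pos + 1L):(pos + hw)])
    m <- mean(x[nb])
    if (abs(x[centre] - m) > frac * m) {
      alive[centre] <- FALSE
    } else {
      pos <- pos + 1L
    }
  }
  x[alive]
}

# Sample skewness (m3 / m2^(3/2)).
skewness <- function(x) {
  z <- x - mean(x)
  mean(z^3) / mean(z^2)^1.5
}
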