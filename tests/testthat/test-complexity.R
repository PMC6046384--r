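test_that("aggregation sums non-overlapping blocks and drops remainders", {
  expect_equal(aggregate_series(1:6, 2), c(3, 7, 11))
  expect_equal(aggregate_series(1:6, 1), 1:6)
  expect_equal(aggregate_series(1:5, 2), c(3, 7))
  expect_error(aggregate_series(1:5, 0), ">= 1")
  expect_error(aggregate_series(1:5, 6), "exceeds")
})

test_that("coarse-graining averages non-overlapping windows", {
  expect_equal(coarse_grain(1:6, 2), c(1.5, 3.5, 5.5))
  expect_equal(coarse_grain(1:6, 1), 1:6)
  set.seed(2)
  x <- rnorm(101)
  # linearity: mean of the coarse-grained series = mean of the truncated input
  expect_equal(mean(coarse_grain(x, 4)), mean(x[1:100]))
})

test_that("DFA recovers the scaling exponent of known processes", {
  # uncorrelated data: alpha ~ 0.5
  a_white <- vapply(1:8, function(s)
    dfa_slope(dfa(gen_series("white", n = 9000, seed = s)$intervals), 4:64),
    numeric(1))
  expect_lt(abs(mean(a_white) - 0.5), 0.05)

  # fractional Gaussian noise: alpha ~ H
  for (H in c(0.5, 0.7, 0.9)) {
    a <- vapply(1:12, function(s)
      dfa_slope(dfa(gen_series("fgn", n = 9000, hurst = H,
                               seed = 100 * H + s)$intervals), 4:64),
      numeric(1))
    expect_lt(abs(mean(a) - H), 0.05)
  }
})

test_that("DFA fits alpha1/alpha2 over their box ranges and rejects degenerate input", {
  res <- dfa(gen_series("fgn", n = 6000, hurst = 0.8, seed = 1)$intervals)
  expect_equal(res$alpha1, dfa_slope(res, 4:11))
  expect_equal(res$alpha2, dfa_slope(res, 12:64))
  expect_true(all(res$fluctuation$f > 0))
  expect_error(dfa(rep(800, 9000)), "constant")
  expect_error(dfa(rnorm(100, 800, 10)), "too short")
  expect_error(dfa_config(short_range = 4:11, long_range = 10:64),
               "disjoint")
})

test_that("allometric aggregation recovers the two scaling anchors", {
  h_white <- vapply(1:5, function(s)
    allometric_exponent(gen_series("white", n = 9000,
                                   seed = s)$intervals)$h, numeric(1))
  expect_true(all(h_white > 0.44 & h_white < 0.56))
  expect_equal(mean(h_white), 0.50, tolerance = 0.03)

  res_ramp <- allometric_exponent(1:9000)
  expect_equal(res_ramp$h, 1, tolerance = 0.03)

  # FD = 2 - h exactly, for every computed result
  for (res in list(res_ramp,
                   allometric_exponent(gen_series("white", n = 9000,
                                                  seed = 77)$intervals))) {
    expect_identical(res$fd, 2 - res$h)
    expect_false(is.unsorted(res$levels$mean)) # mean grows with level
  }
})

test_that("allometric edge cases are handled", {
  expect_error(allometric_exponent(rnorm(500)), "too short")
  expect_warning(
    expect_error(allometric_exponent(rep(1, 2000),
                                     allometric_config(c(1, 2, 4, 8))),
                 "usable"),
    "zero SD")
})

test_that("sample entropy equals the brute-force oracle exactly", {
  set.seed(10)
  for (rep in 1:12) {
    n <- sample(60:200, 1)
    x <- rnorm(n)
    m <- sample(1:2, 1)
    r <- sample(c(0.1, 0.15, 0.2), 1)
    # both sides flag an undefined (no-match) entropy as NA
    expect_equal(suppressWarnings(sample_entropy(x, m, r)),
                 brute_sampen(x, m, r), tolerance = 1e-12)
  }
})

test_that("sample entropy orders regularity correctly", {
  # strict periodicity with period <= m is perfectly predictable
  per <- gen_series("periodic", n = 400, period = 2, seed = 1)$intervals
  expect_equal(sample_entropy(per, m = 2, r = 0.15), 0)

  # white noise is less predictable than a strongly autocorrelated series
  w <- gen_series("white", n = 1500, seed = 3)$intervals
  a <- gen_series("ar1", n = 1500, phi = 0.95, seed = 3)$intervals
  expect_gt(sample_entropy(w, 2, 0.2), sample_entropy(a, 2, 0.2))

  expect_error(sample_entropy(rep(1, 100)), "constant")
  expect_warning(
    expect_true(is.na(sample_entropy(c(1, 10, 100, 1000, 2, 20, 200),
                                     m = 1, r = 0.001,
                                     r_type = "absolute"))),
    "undefined")
})

test_that("multiscale entropy uses a fixed tolerance and flags per-scale failures", {
  x <- gen_series("white", n = 4000, seed = 6)$intervals
  mse <- multiscale_entropy(x)
  # white noise: entropy decreases with the scale factor
  expect_true(all(diff(mse$sampen) < 0))

  # scale set (1) reduces to plain sample entropy
  one <- multiscale_entropy(x, mse_config(scales = 1))
  expect_equal(one$sampen, sample_entropy(x, 2, 0.15))

  expect_error(multiscale_entropy(rnorm(100), mse_config()), "too short")
})

test_that("cohorts generated with different large-scale structure keep their entropy ordering", {
  # long-range correlated series retain variability under coarse-graining
  # and so stay more entropic at scale 20 than uncorrelated series
  s20 <- function(kind, seeds) {
    vapply(seeds, function(s) {
      x <- gen_series(kind, n = 4000, hurst = 0.9, seed = s)$intervals
      multiscale_entropy(x)$sampen[5]
    }, numeric(1))
  }
  expect_gt(mean(s20("fgn", 1:6)), mean(s20("white", 1:6)))
})

test_that("complexity_measures bundles all per-subject columns", {
  x <- gen_series("fgn", n = 4000, hurst = 0.85, seed = 5)$intervals
  cc <- complexity_measures(x)
  expect_named(cc, c("dfa_alpha1", "dfa_alpha2", "allometric_h", "fd",
                     "mse_s1", "mse_s5", "mse_s10", "mse_s15", "mse_s20"))
  expect_identical(cc$fd, 2 - cc$allometric_h)
  expect_true(all(vapply(cc, is.finite, logical(1))))
})
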