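test_that("generated series match their requested moments and are reproducible", {
  rec <- gen_series("white", n = 9000, mean_ibi = 650, sd_ibi = 40,
                    seed = 1)
  expect_equal(mean(rec$intervals), 650, tolerance = 2 / 650)
  expect_lt(abs(sd(rec$intervals) - 40), 2)

  rec2 <- gen_series("white", n = 9000, mean_ibi = 650, sd_ibi = 40,
                     seed = 1)
  expect_identical(rec$intervals, rec2$intervals)

  # duration-specified generation lands near the requested length
  rec3 <- gen_series("white", duration_minutes = 120, mean_ibi = 650,
                     seed = 2)
  expect_equal(duration_minutes(rec3), 120, tolerance = 0.02)

  expect_error(gen_series("white", n = 100, mean_ibi = 2000), "mean_ibi")
  expect_error(gen_series("fgn", n = 100, hurst = 1.2), "hurst")
  expect_error(gen_series("ar1", n = 100, phi = 1.5), "phi")
  expect_error(gen_series("white"), "duration_minutes")
})

test_that("fractional Gaussian noise has the theoretical lag-1 autocorrelation", {
  H <- 0.9
  theory <- 0.5 * (2^(2 * H) - 2)
  est <- vapply(1:10, function(s) {
    x <- gen_series("fgn", n = 9000, hurst = H, mean_ibi = 650,
                    sd_ibi = 40, seed = s)$intervals - 650
    sum(x[-1] * x[-length(x)]) / sum(x^2)
  }, numeric(1))
  expect_equal(mean(est), theory, tolerance = 0.05 / theory)
})

test_that("planted artifacts are isolated and at the requested rate", {
  rec <- gen_series("white", n = 9000, seed = 4, artifact_rate = 0.02)
  idx <- rec$artifact_index
  expect_equal(length(idx), round(0.02 * 9000))
  expect_true(all(diff(idx) >= 12))
  # every artifact is at least 30% off the local level
  loc <- vapply(idx, function(i)
    mean(rec$intervals[c((i - 5):(i - 1), (i + 1):(i + 5))]), numeric(1))
  expect_true(all(abs(rec$intervals[idx] - loc) / loc > 0.3))
})

test_that("generated cohorts have the configured structure", {
  coh <- gen_cohort(n_female = 86, n_male = 80, missing_rate = 0, seed = 3)
  expect_equal(nrow(coh), 166)
  expect_equal(sum(coh$sex_code == 2), 86)
  expect_false(anyNA(coh))
  expect_identical(coh, gen_cohort(n_female = 86, n_male = 80,
                                   missing_rate = 0, seed = 3))

  # missingness masks whole symptom rows at the requested rate
  coh_m <- gen_cohort(seed = 5, missing_rate = 0.3)
  frac <- mean(is.na(coh_m$depression))
  expect_gt(frac, 0.15)
  expect_lt(frac, 0.45)
  expect_equal(is.na(coh_m$depression), is.na(coh_m$panic))

  # group means track the configured per-group distribution
  spec <- cohort_measure_defaults()
  rm_m <- mean(coh$rmssd[coh$sex_code == 1])
  expect_equal(rm_m, spec$mean_male[spec$measure == "rmssd"],
               tolerance = 5 / 38)
})

test_that("cohort generation gives HR-signed correlations the adjuster can detect", {
  coh <- gen_cohort(seed = 11, missing_rate = 0)
  suppressWarnings(adj <- hr_adjust(
    coh, setdiff(cohort_measure_defaults()$measure, "hr")))
  ops <- setNames(adj$report$operation, adj$report$measure)
  expect_equal(unname(ops["dfa_alpha1"]), "multiplied_by_hr")
  expect_true(all(ops[setdiff(names(ops), "dfa_alpha1")] ==
                    "divided_by_hr"))
})

test_that("configured effect sizes and symptom slopes are recovered on average", {
  spec <- cohort_measure_defaults()
  i <- which(spec$measure == "rmssd")
  d_true <- cohens_d(spec$mean_male[i], spec$sd_male[i], 80,
                     spec$mean_female[i], spec$sd_female[i], 86)
  set.seed(71)
  d_hat <- vapply(1:200, function(r) {
    coh <- gen_cohort(missing_rate = 0, symptom_spec = NULL)
    compare_groups(coh, "rmssd")$cohens_d
  }, numeric(1))
  expect_lt(abs(mean(d_hat) - d_true), 0.05)
})

test_that("end-to-end: modulation amplitudes drive the HF/LF ordering", {
  hf_heavy <- preprocess(gen_series("modulated", duration_minutes = 20,
                                    hf_amp = 30, lf_amp = 5, noise_sd = 3,
                                    seed = 9),
                         filter_config(trim_minutes = 1))
  h <- hrv_measures(hf_heavy)
  expect_gt(h$hf, h$lf)

  lf_heavy <- preprocess(gen_series("modulated", duration_minutes = 20,
                                    hf_amp = 5, lf_amp = 30, noise_sd = 3,
                                    seed = 9),
                         filter_config(trim_minutes = 1))
  h2 <- hrv_measures(lf_heavy)
  expect_gt(h2$lf, h2$hf)
})

test_that("end-to-end: DFA on preprocessed fGn recovers the Hurst exponent", {
  a <- vapply(1:6, function(s) {
    cln <- preprocess(gen_series("fgn", n = 9000, hurst = 0.8, seed = s),
                      filter_config(trim_minutes = 0))
    dfa_slope(dfa(cln), 4:64)
  }, numeric(1))
  expect_equal(mean(a), 0.8, tolerance = 0.05 / 0.8)
})

test_that("from_series cohorts derive measures through the full pipeline", {
  coh <- gen_cohort(n_female = 3, n_male = 3, seed = 23,
                    from_series = TRUE, series_minutes = 22,
                    filter_cfg = filter_config(trim_minutes = 1))
  expect_equal(nrow(coh), 6)
  expect_true(all(c("hr", "rmssd", "ln_hf", "dfa_alpha1", "fd",
                    "mse_s20", "n_output", "depression") %in% names(coh)))
  expect_true(all(is.na(coh$error)))
  expect_true(all(coh$hr > 50 & coh$hr < 140))
  expect_true(all(coh$fd + coh$allometric_h == 2))
})
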