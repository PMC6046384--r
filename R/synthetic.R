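# Synthetic interbeat-interval series and two-group cohorts with the
# statistical structure the analysis pipeline assumes, so every stage is
# testable without real recordings.

# Exact fractional Gaussian noise (unit variance) by circulant embedding
# of the fGn autocovariance; valid for 0 < H < 1.
fgn_sim <- function(n, hurst) {
  if (!(hurst > 0 && hurst < 1)) stop("hurst must be in (0, 1)")
  k <- 0:n
  gam <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                  abs(k - 1)^(2 * hurst))
  row <- c(gam[1:n], gam[n + 1], gam[n:2])
  m <- 2 * n
  lam <- Re(fft(row))
  lam[lam < 0] <- 0 # numerically tiny negatives only
  w <- complex(real = rnorm(m), imaginary = rnorm(m))
  Re(fft(sqrt(lam) * w))[seq_len(n)] / sqrt(m)
}

#' Generate a synthetic interbeat-interval recording
#'
#' Produces an IBI series (ms) emulating the output of an ambulatory
#' single-lead recorder: roughly 9,000-12,000 intervals for a
#' two-hour recording at adolescent heart rates. Available generating
#' processes:
#' \describe{
#'   \item{white}{i.i.d. Gaussian intervals.}
#'   \item{fgn}{fractional Gaussian noise with Hurst exponent `hurst`
#'     (exact autocovariance via circulant embedding), scaled to
#'     `mean_ibi` / `sd_ibi`.}
#'   \item{ar1}{first-order autoregressive intervals with coefficient
#'     `phi`, stationary SD `sd_ibi`.}
#'   \item{modulated}{mean interval plus sinusoidal respiratory-band
#'     (`hf_freq`, `hf_amp`) and slow (`lf_freq`, `lf_amp`) modulation on
#'     the cumulative beat-time axis, plus white noise of SD `noise_sd`.}
#'   \item{ramp}{linear drift from `mean_ibi - sqrt(3) sd_ibi` to
#'     `mean_ibi + sqrt(3) sd_ibi`.}
#'   \item{periodic}{strictly periodic pattern
#'     `mean_ibi + sd_ibi cos(2 pi i / period)`.}
#' }
#' With `artifact_rate > 0`, isolated artifacts are planted at that
#' proportion of beats: half out-of-band values (above 1100 or below 400
#' ms), half in-band spikes about 40 percent off the local level. Planted
#' positions are recorded in the `artifact_index` element.
#'
#' @param kind generating process, see Details.
#' @param n number of intervals; alternatively give `duration_minutes`.
#' @param duration_minutes target duration; `n` is derived from
#'   `mean_ibi` when `n` is missing.
#' @param mean_ibi mean interval, ms; must lie in (400, 1100).
#' @param sd_ibi interval SD, ms.
#' @param hurst Hurst exponent for `fgn` (0 < H < 1).
#' @param phi AR(1) coefficient, |phi| < 1.
#' @param hf_freq,hf_amp,lf_freq,lf_amp modulation frequencies (Hz) and
#'   amplitudes (ms) for `modulated`.
#' @param noise_sd additive white-noise SD (ms) for `modulated`.
#' @param period pattern length in beats for `periodic`.
#' @param artifact_rate proportion of beats replaced by planted artifacts.
#' @param seed integer seed; the series is bit-reproducible given the
#'   seed.
#' @param subject_id identifier for the generated recording.
#' @return a [raw_ibi()] recording, with an `artifact_index` element when
#'   artifacts were planted.
#' @examples
#' rec <- gen_series("modulated", duration_minutes = 5, seed = 1)
#' @export
gen_series <- function(kind = c("white", "fgn", "ar1", "modulated",
                                "ramp", "periodic"),
                       n = NULL, duration_minutes = NULL,
                       mean_ibi = 650, sd_ibi = 40,
                       hurst = 0.9, phi = 0.5,
                       hf_freq = 0.25, hf_amp = 25,
                       lf_freq = 0.1, lf_amp = 10,
                       noise_sd = 5, period = 2,
                       artifact_rate = 0,
                       seed = NULL, subject_id = "sim") {
  kind <- match.arg(kind)
  if (!(mean_ibi > 400 && mean_ibi < 1100))
    stop("mean_ibi must be in (400, 1100) ms")
  if (is.null(n)) {
    if (is.null(duration_minutes))
      stop("give either n or duration_minutes")
    n <- round(duration_minutes * 60000 / mean_ibi)
  }
  n <- as.integer(n)
  if (n < 2) stop("n must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  x <- switch(kind,
    white = rnorm(n, mean_ibi, sd_ibi),
    fgn = mean_ibi + sd_ibi * fgn_sim(n, hurst),
    ar1 = {
      if (abs(phi) >= 1) stop("|phi| must be < 1")
      innov_sd <- sd_ibi * sqrt(1 - phi^2)
      e <- rnorm(n, 0, innov_sd)
      z <- numeric(n)
      z[1] <- rnorm(1, 0, sd_ibi)
      for (i in 2:n) z[i] <- phi * z[i - 1] + e[i]
      mean_ibi + z
    },
    modulated = {
      out <- numeric(n)
      t_s <- 0
      noise <- rnorm(n, 0, noise_sd)
      for (i in seq_len(n)) {
        out[i] <- mean_ibi +
          hf_amp * sin(2 * pi * hf_freq * t_s) +
          lf_amp * sin(2 * pi * lf_freq * t_s) + noise[i]
        t_s <- t_s + out[i] / 1000
      }
      out
    },
    ramp = seq(mean_ibi - sqrt(3) * sd_ibi, mean_ibi + sqrt(3) * sd_ibi,
               length.out = n),
    periodic = mean_ibi + sd_ibi * cos(2 * pi * seq_len(n) / period))
  # keep the clean series inside physiological bounds
  x <- pmin(pmax(x, 401), 1099)
  artifact_index <- integer(0)
  if (artifact_rate > 0) {
    k <- max(1L, round(artifact_rate * n))
    # isolated positions away from the edges, >= 12 beats apart
    cand <- sort(sample(13:(n - 12), size = min(4L * k, n - 24L)))
    sel <- integer(0)
    last <- -Inf
    for (p in cand) {
      if (p - last >= 12) {
        sel <- c(sel, p)
        last <- p
      }
      if (length(sel) == k) break
    }
    artifact_index <- sel
    for (j in seq_along(artifact_index)) {
      i <- artifact_index[j]
      if (j %% 2 == 0) {
        x[i] <- if (runif(1) < 0.5) runif(1, 1150, 1350) else runif(1, 310, 380)
      } else {
        # in-band spike ~40% off the local level
        local <- mean(x[c((i - 5):(i - 1), (i + 1):(i + 5))])
        x[i] <- local * (if (runif(1) < 0.5) 1.4 else 0.62)
      }
    }
  }
  rec <- raw_ibi(x, subject_id)
  rec$artifact_index <- artifact_index
  rec
}

#' Default per-group distribution of the cardiac measures
#'
#' One row per measure: group means and SDs for boys and girls typical of
#' a mid-adolescent ambulatory cohort (about 90 bpm mean HR, moderate
#' vagal tone, short-term DFA exponent near 1.4), and the assumed
#' cross-subject correlation of the measure with mean HR used when
#' drawing measures directly at the measure level. The short-term DFA
#' exponent is the only measure assumed to correlate positively with HR;
#' the correlation magnitudes are configurable assumptions.
#'
#' @return data frame with columns `measure`, `mean_male`, `sd_male`,
#'   `mean_female`, `sd_female`, `hr_cor`.
#' @export
cohort_measure_defaults <- function() {
  data.frame(
    measure = c("hr", "rmssd", "lf", "ln_hf", "dfa_alpha1", "dfa_alpha2",
                "fd", "mse_s1", "mse_s5", "mse_s10", "mse_s15", "mse_s20"),
    mean_male = c(89.33, 38.16, 1913.67, 6.26, 1.40, 0.98,
                  1.10, 0.90, 1.51, 1.53, 1.51, 1.49),
    sd_male = c(11.006, 13.89, 767.09, 0.69, 0.14, 0.08,
                0.03, 0.23, 0.19, 0.13, 0.12, 0.12),
    mean_female = c(93.421, 33.24, 1614.65, 5.96, 1.42, 0.96,
                    1.08, 0.87, 1.47, 1.49, 1.45, 1.43),
    sd_female = c(10.407, 12.31, 686.96, 0.76, 0.13, 0.07,
                  0.02, 0.19, 0.17, 0.13, 0.12, 0.12),
    hr_cor = c(1, -0.3, -0.3, -0.3, 0.3, -0.3,
               -0.3, -0.3, -0.3, -0.3, -0.3, -0.3),
    stringsAsFactors = FALSE)
}

#' Default symptom-generation model
#'
#' Per internalizing-symptom subscale: an intercept and residual scale on
#' the subscale-total metric (0-3-scored items summed), plus standardized
#' slopes on standardized predictors. Slopes are expressed in
#' standardized units (outcome SDs per predictor SD); predictors named
#' `"sex"` use the standardized 1/2 sex code, any other name refers to a
#' cardiac-measure column.
#'
#' @return named list of subscale specs, each a list with `intercept`,
#'   `sd` and a named numeric `slopes` vector.
#' @export
cohort_symptom_defaults <- function() {
  sub <- function(intercept, sd, sex, hr, ln_hf)
    list(intercept = intercept, sd = sd,
         slopes = c(sex = sex, hr = hr, ln_hf = ln_hf))
  list(
    social_anxiety = sub(8.85, 5.53, 0.18, 0.16, -0.17),
    generalized_anxiety = sub(5.82, 3.61, 0.03, 0.06, -0.10),
    separation_anxiety = sub(1.56, 2.49, -0.04, 0.16, -0.09),
    panic = sub(4.71, 4.85, -0.02, 0.20, -0.15),
    obsessive_compulsive = sub(3.11, 3.35, -0.03, 0.29, -0.16),
    depression = sub(8.04, 5.64, 0.10, 0.20, -0.17),
    total_anxiety = sub(24.06, 16.21, 0.05, 0.21, -0.17))
}

#' Generate a synthetic two-group cohort
#'
#' Draws a cohort of girls (sex code 2) and boys (sex code 1) with the
#' configured per-group distribution of cardiac measures and
#' symptom-subscale totals generated from a standardized linear model.
#' By default measures are drawn directly at the measure level, each with
#' the configured cross-subject correlation with mean HR (so the
#' HR-adjustment rule has signed correlations to detect). With
#' `from_series = TRUE`, an actual IBI series is generated per subject
#' and the full preprocessing/HRV/complexity pipeline is run on it
#' (slower; intended for end-to-end checks at reduced n).
#'
#' Symptom totals are built as
#' `intercept + sd * (sum of slope_j * z_j + residual)`, rounded and
#' floored at zero, where the `z_j` are the cohort-standardized
#' predictors and the residual SD is set so the outcome variance is `sd^2`
#' when the predictors are uncorrelated. Whole symptom rows are then
#' masked missing completely at random at `missing_rate`.
#'
#' @param n_female,n_male group sizes (defaults 86 and 80).
#' @param measure_spec data frame as [cohort_measure_defaults()].
#' @param symptom_spec list as [cohort_symptom_defaults()], or `NULL` to
#'   skip symptom generation.
#' @param missing_rate proportion of subjects with missing symptom data
#'   (default 0.07, matching typical questionnaire non-completion).
#' @param seed integer seed.
#' @param from_series generate per-subject IBI series and derive measures
#'   through the full pipeline instead of drawing them directly.
#' @param series_minutes recording length per subject in `from_series`
#'   mode (default 20; trimming is scaled down via `filter_cfg`).
#' @param filter_cfg [filter_config()] used in `from_series` mode.
#' @return data frame, one row per subject: `subject_id`, `sex_code`,
#'   `age`, `bmi`, one column per measure, one per symptom subscale.
#' @examples
#' coh <- gen_cohort(n_female = 20, n_male = 20, seed = 1)
#' @export
gen_cohort <- function(n_female = 86, n_male = 80,
                       measure_spec = cohort_measure_defaults(),
                       symptom_spec = cohort_symptom_defaults(),
                       missing_rate = 0.07,
                       seed = NULL,
                       from_series = FALSE,
                       series_minutes = 20,
                       filter_cfg = filter_config(trim_minutes = 1)) {
  if (n_female < 2 || n_male < 2) stop("group sizes must be >= 2")
  if (!(missing_rate >= 0 && missing_rate < 1))
    stop("missing_rate must be in [0, 1)")
  if (any(c(measure_spec$sd_male, measure_spec$sd_female) <= 0))
    stop("measure SDs must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- n_male + n_female
  sex <- c(rep(1L, n_male), rep(2L, n_female))
  coh <- data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    sex_code = sex,
    age = round(rnorm(n, 14.96, 0.4), 2),
    bmi = round(rnorm(n, ifelse(sex == 1, 18.19, 17.68),
                      ifelse(sex == 1, 3.35, 2.74)), 2),
    stringsAsFactors = FALSE)

  if (from_series) {
    rows <- lapply(seq_len(n), function(i) {
      g <- if (sex[i] == 1) "male" else "female"
      hr_i <- rnorm(1, measure_spec[[paste0("mean_", g)]][1],
                    measure_spec[[paste0("sd_", g)]][1])
      hr_i <- min(max(hr_i, 60), 130)
      rec <- gen_series("modulated", duration_minutes = series_minutes,
                        mean_ibi = 60000 / hr_i,
                        hf_amp = if (sex[i] == 1) 30 else 24,
                        lf_amp = 12, noise_sd = 8,
                        subject_id = coh$subject_id[i])
      run_subject(rec, filter_cfg = filter_cfg)
    })
    meas <- do.call(rbind, rows)
    coh <- cbind(coh, meas[, setdiff(names(meas), "subject_id")])
  } else {
    z_hr <- rnorm(n)
    for (j in seq_len(nrow(measure_spec))) {
      mname <- measure_spec$measure[j]
      mu <- ifelse(sex == 1, measure_spec$mean_male[j],
                   measure_spec$mean_female[j])
      sdv <- ifelse(sex == 1, measure_spec$sd_male[j],
                    measure_spec$sd_female[j])
      rho <- measure_spec$hr_cor[j]
      z <- if (mname == "hr") z_hr
           else rho * z_hr + sqrt(1 - rho^2) * rnorm(n)
      coh[[mname]] <- mu + sdv * z
    }
  }

  if (!is.null(symptom_spec)) {
    zscore <- function(v) (v - mean(v)) / sd(v)
    for (sname in names(symptom_spec)) {
      sp <- symptom_spec[[sname]]
      lin <- numeric(n)
      for (pred in names(sp$slopes)) {
        v <- if (pred == "sex") coh$sex_code else coh[[pred]]
        if (is.null(v)) stop("symptom predictor '", pred, "' not in cohort")
        lin <- lin + sp$slopes[[pred]] * zscore(v)
      }
      resid_sd <- sqrt(max(0, 1 - sum(sp$slopes^2)))
      y <- sp$intercept + sp$sd * (lin + rnorm(n, 0, resid_sd))
      coh[[sname]] <- pmax(0, round(y))
    }
    if (missing_rate > 0) {
      drop <- runif(n) < missing_rate
      coh[drop, names(symptom_spec)] <- NA
    }
  }
  coh
}
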