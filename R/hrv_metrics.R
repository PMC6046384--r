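# Time-domain and frequency-domain heart rate variability measures.

#' Time-domain HRV measures
#'
#' Computes AVNN (mean NN interval, ms), mean heart rate
#' (HR = 60000 / AVNN, beats per minute) and RMSSD (root mean square of
#' successive NN differences, ms) from a clean NN series.
#'
#' @param x a `clean_ibi` object or numeric NN vector (ms), length >= 2.
#' @return list with `avnn`, `hr`, `rmssd`.
#' @examples
#' time_domain(c(800, 810, 800, 810))
#' @export
time_domain <- function(x) {
  v <- ibi_values(x)
  if (length(v) < 2) stop("need at least 2 intervals (RMSSD undefined)")
  avnn <- mean(v)
  list(avnn = avnn,
       hr = 60000 / avnn,
       rmssd = sqrt(mean(diff(v)^2)))
}

#' Spectral estimation configuration
#'
#' @param method `"resampled_fft"` (default): the NN series is placed on
#'   its cumulative-time axis, cubic-interpolated to a uniform grid at
#'   `resample_rate`, detrended and tapered, and transformed with the FFT,
#'   with power corrected for the taper gain. `"lomb"`: Lomb-Scargle
#'   periodogram estimated directly on the unevenly sampled beat times.
#' @param resample_rate uniform sampling rate in Hz for `resampled_fft`
#'   (default 4).
#' @param lf_band,hf_band low- and high-frequency bands in Hz; the default
#'   LF 0.04-0.15 Hz and HF 0.15-0.40 Hz. Band integrals use the half-open
#'   convention `[lo, hi)` so the shared 0.15 Hz edge is never counted
#'   twice.
#' @param detrend `"linear"` (default) or `"none"`.
#' @param window `"hann"` (default) or `"none"`; applies to
#'   `resampled_fft` only.
#' @return list of class `spectral_config`.
#' @export
spectral_config <- function(method = c("resampled_fft", "lomb"),
                            resample_rate = 4,
                            lf_band = c(0.04, 0.15),
                            hf_band = c(0.15, 0.40),
                            detrend = c("linear", "none"),
                            window = c("hann", "none")) {
  method <- match.arg(method)
  detrend <- match.arg(detrend)
  window <- match.arg(window)
  if (!(lf_band[1] < lf_band[2] && hf_band[1] < hf_band[2]))
    stop("band edges must be ordered")
  if (lf_band[2] != hf_band[1])
    stop("LF upper edge must equal HF lower edge")
  structure(list(method = method, resample_rate = resample_rate,
                 lf_band = lf_band, hf_band = hf_band,
                 detrend = detrend, window = window),
            class = "spectral_config")
}

#' Power spectrum of an NN series
#'
#' Estimates the one-sided power spectral density of the NN-interval
#' signal (ms^2 per Hz) on its cumulative-time axis, so that band
#' integrals ([band_power()]) are in ms^2.
#'
#' @param x a `clean_ibi` or numeric NN vector (ms).
#' @param cfg a [spectral_config()].
#' @return object of class `ibi_spectrum`: list with `freq` (Hz),
#'   `density` (ms^2/Hz), `df` (grid spacing), `signal_var` (variance of
#'   the detrended analysis signal, the Parseval reference) and `method`.
#' @export
power_spectrum <- function(x, cfg = spectral_config()) {
  stopifnot(inherits(cfg, "spectral_config"))
  v <- ibi_values(x)
  t_s <- cumsum(v) / 1000
  dur <- t_s[length(t_s)] - t_s[1]
  if (dur < 1 / cfg$lf_band[1])
    stop("series too short to resolve the lowest band edge (need >= ",
         round(1 / cfg$lf_band[1]), " s, have ", round(dur), " s)")
  if (cfg$method == "resampled_fft") {
    fs <- cfg$resample_rate
    grid <- seq(t_s[1], t_s[length(t_s)], by = 1 / fs)
    y <- spline(t_s, v, xout = grid, method = "fmm")$y
    if (cfg$detrend == "linear") {
      y <- stats::residuals(lm(y ~ grid))
    } else {
      y <- y - mean(y)
    }
    n <- length(y)
    sig_var <- mean(y^2)
    if (cfg$window == "hann") {
      w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
      gain <- mean(w^2)
      y <- y * w
    } else {
      gain <- 1
    }
    X <- fft(y)
    half <- floor(n / 2)
    k <- seq_len(half)
    density <- 2 * Mod(X[k + 1])^2 / (fs * n * gain)
    structure(list(freq = k * fs / n, density = density, df = fs / n,
                   signal_var = sig_var, method = "resampled_fft"),
              class = "ibi_spectrum")
  } else {
    y <- v
    if (cfg$detrend == "linear") {
      y <- stats::residuals(lm(y ~ t_s))
    } else {
      y <- y - mean(y)
    }
    n <- length(y)
    df <- 1 / dur
    fmax <- n / (2 * dur) # average Nyquist
    freq <- seq(df, fmax, by = df)
    p <- vapply(freq, function(f) {
      w <- 2 * pi * f
      tau <- atan2(sum(sin(2 * w * t_s)), sum(cos(2 * w * t_s))) / (2 * w)
      ct <- cos(w * (t_s - tau)); st <- sin(w * (t_s - tau))
      0.5 * (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2))
    }, numeric(1))
    # scale so that summing density * df over all frequencies ~ variance
    density <- p * 2 / (n * df)
    structure(list(freq = freq, density = density, df = df,
                   signal_var = mean(y^2), method = "lomb"),
              class = "ibi_spectrum")
  }
}

#' Integrate spectral power over a band
#'
#' @param spectrum an `ibi_spectrum` from [power_spectrum()].
#' @param band numeric `c(lo, hi)` in Hz; integration is over `[lo, hi)`.
#' @return band power in ms^2.
#' @export
band_power <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "ibi_spectrum"))
  if (band[1] > band[2]) stop("inverted band")
  if (band[1] == band[2]) return(0)
  sel <- spectrum$freq >= band[1] & spectrum$freq < band[2]
  sum(spectrum$density[sel]) * spectrum$df
}

#' Natural-log transform of a spectral power
#'
#' HF power is right-skewed across subjects; the natural log restores
#' approximate normality before parametric statistics.
#'
#' @param power spectral power, ms^2; must be strictly positive.
#' @return `log(power)`.
#' @export
ln_transform <- function(power) {
  if (any(power <= 0)) stop("power must be > 0 for the log transform")
  log(power)
}

#' All HRV measures for one subject
#'
#' Convenience wrapper: time-domain measures plus LF power, HF power and
#' lnHF from the configured spectral estimator.
#'
#' @param x a `clean_ibi` or numeric NN vector (ms).
#' @param cfg a [spectral_config()].
#' @return named list: `avnn`, `hr`, `rmssd`, `lf`, `hf`, `ln_hf`.
#' @export
hrv_measures <- function(x, cfg = spectral_config()) {
  td <- time_domain(x)
  sp <- power_spectrum(x, cfg)
  lf <- band_power(sp, cfg$lf_band)
  hf <- band_power(sp, cfg$hf_band)
  c(td, list(lf = lf, hf = hf,
             ln_hf = if (hf > 0) log(hf) else NA_real_))
}
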