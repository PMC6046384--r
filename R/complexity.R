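# Cardiac complexity: detrended fluctuation analysis, allometric
# aggregation fractal dimension, and multiscale sample entropy.

#' DFA configuration
#'
#' @param short_range box sizes (beats) for the short-term exponent
#'   alpha1; default 4:11.
#' @param long_range box sizes for the long-term exponent alpha2; default
#'   12:64 (the upper bound for "beyond 11 beats" is configurable).
#' @param detrend_order polynomial order removed per box (default 1,
#'   linear detrending).
#' @return list of class `dfa_config`.
#' @export
dfa_config <- function(short_range = 4:11, long_range = 12:64,
                       detrend_order = 1) {
  short_range <- sort(unique(as.integer(short_range)))
  long_range <- sort(unique(as.integer(long_range)))
  if (length(intersect(short_range, long_range)) > 0)
    stop("short_range and long_range must be disjoint")
  if (min(short_range, long_range) < detrend_order + 2)
    stop("minimum box size must be >= detrend_order + 2")
  structure(list(short_range = short_range, long_range = long_range,
                 detrend_order = as.integer(detrend_order)),
            class = "dfa_config")
}

# Root-mean-square fluctuation of the integrated, per-box detrended
# profile for one box size. Boxes are non-overlapping from the start of
# the series; a trailing incomplete box is dropped.
dfa_fluctuation <- function(profile, n, order = 1) {
  k <- floor(length(profile) / n)
  mat <- matrix(profile[seq_len(n * k)], nrow = n)
  X <- outer(seq_len(n), 0:order, `^`)
  Q <- qr.Q(qr(X))
  res <- mat - Q %*% crossprod(Q, mat)
  sqrt(mean(res^2))
}

#' Detrended fluctuation analysis
#'
#' Integrates the mean-centred NN series, removes a least-squares
#' polynomial trend within non-overlapping boxes of each size n, and
#' computes the RMS fluctuation F(n). The scaling exponents are the
#' least-squares slopes of log F(n) on log n: alpha1 over the short-term
#' box range and alpha2 over the long-term range. Uncorrelated data give
#' alpha = 0.5; values between 0.5 and 1 indicate persistent long-range
#' power-law correlation.
#'
#' @param x a `clean_ibi` or numeric NN vector.
#' @param cfg a [dfa_config()].
#' @return object of class `dfa_result`: list with `alpha1`, `alpha2`,
#'   and `fluctuation` (data frame: `n`, `f`).
#' @examples
#' set.seed(1)
#' dfa(rnorm(4000, 800, 30))$alpha1
#' @export
dfa <- function(x, cfg = dfa_config()) {
  v <- ibi_values(x)
  boxes <- sort(unique(c(cfg$short_range, cfg$long_range)))
  if (length(v) < 4 * max(boxes))
    stop("series too short: need >= 4 x max box size (",
         4 * max(boxes), ")")
  if (sd(v) == 0) stop("constant series: DFA exponent undefined")
  profile <- cumsum(v - mean(v))
  f <- vapply(boxes, function(n)
    dfa_fluctuation(profile, n, cfg$detrend_order), numeric(1))
  if (any(f <= 0)) stop("zero fluctuation: DFA exponent undefined")
  curve <- data.frame(n = boxes, f = f)
  structure(list(alpha1 = dfa_slope(curve, cfg$short_range),
                 alpha2 = dfa_slope(curve, cfg$long_range),
                 fluctuation = curve),
            class = "dfa_result")
}

#' Scaling exponent over an arbitrary box-size range
#'
#' Fits log F(n) on log n by unweighted least squares over the box sizes
#' in `range` present in a fitted fluctuation curve.
#'
#' @param result a `dfa_result` or its `fluctuation` data frame.
#' @param range integer box sizes to include in the fit.
#' @return the fitted slope.
#' @export
dfa_slope <- function(result, range) {
  curve <- if (inherits(result, "dfa_result")) result$fluctuation else result
  sel <- curve$n %in% range
  if (sum(sel) < 2) stop("need >= 2 box sizes in range")
  unname(coef(lm(log(curve$f[sel]) ~ log(curve$n[sel])))[2])
}

#' Aggregate a series by summing adjacent points
#'
#' Sums consecutive non-overlapping blocks of `level` points; a trailing
#' remainder shorter than `level` is discarded. `level = 1` is the
#' identity.
#'
#' @param x numeric vector.
#' @param level block size (adjacent-point count), >= 1.
#' @return numeric vector of block sums, length `floor(length(x)/level)`.
#' @examples
#' aggregate_series(1:6, 2) # 3 7 11
#' @export
aggregate_series <- function(x, level) {
  level <- as.integer(level)
  if (level < 1) stop("level must be >= 1")
  if (level > length(x)) stop("level exceeds series length")
  if (level == 1) return(as.numeric(x))
  k <- floor(length(x) / level)
  colSums(matrix(x[seq_len(level * k)], nrow = level))
}

#' Allometric aggregation configuration
#'
#' @param levels aggregation levels (adjacent points summed per block);
#'   default `c(1, 10, 20, ..., 100)`, suited to series of roughly 9000
#'   points (max level about length/10 or less).
#' @return list of class `allometric_config`.
#' @export
allometric_config <- function(levels = c(1, seq(10, 100, by = 10))) {
  levels <- as.integer(levels)
  if (any(levels < 1) || is.unsorted(levels, strictly = TRUE))
    stop("levels must be positive and strictly ascending")
  structure(list(levels = levels), class = "allometric_config")
}

#' Allometric-aggregation scaling exponent and fractal dimension
#'
#' Examines the invariance of the mean-SD relationship as the series is
#' aggregated by summing blocks of adjacent points. For each level the
#' mean and standard deviation of the aggregated series are computed; the
#' slope h of log SD against log mean across levels is the scaling
#' exponent, and the fractal dimension is FD = 2 - h. Random
#' (uncorrelated) fluctuations give h = 0.5; a deterministically regular
#' process gives h = 1.
#'
#' @param x a `clean_ibi` or numeric vector with positive mean.
#' @param cfg an [allometric_config()].
#' @return object of class `allometric_result`: list with `h`, `fd`
#'   (= 2 - h) and `levels` (data frame: `level`, `mean`, `sd`).
#' @examples
#' allometric_exponent(1:9000)$h # ~1 for a linear ramp
#' @export
allometric_exponent <- function(x, cfg = allometric_config()) {
  v <- ibi_values(x)
  if (length(v) < 10 * max(cfg$levels))
    stop("series too short: need >= 10 x max aggregation level")
  mu <- vapply(cfg$levels, function(l) mean(aggregate_series(v, l)),
               numeric(1))
  s <- vapply(cfg$levels, function(l) sd(aggregate_series(v, l)),
              numeric(1))
  usable <- s > 0
  if (any(!usable))
    warning("dropping ", sum(!usable), " aggregation level(s) with zero SD")
  if (sum(usable) < 3)
    stop("fewer than 3 usable aggregation levels")
  if (any(mu[usable] <= 0))
    stop("non-positive aggregated mean: log-log fit undefined")
  h <- unname(coef(lm(log(s[usable]) ~ log(mu[usable])))[2])
  structure(list(h = h, fd = 2 - h,
                 levels = data.frame(level = cfg$levels, mean = mu, sd = s)),
            class = "allometric_result")
}

#' Coarse-grain a series by window averaging
#'
#' Means (not sums) of consecutive non-overlapping windows of `scale`
#' points, as used by multiscale entropy. `scale = 1` is the identity.
#'
#' @param x numeric vector.
#' @param scale window length tau, >= 1.
#' @return numeric vector of window means, length `floor(length(x)/scale)`.
#' @examples
#' coarse_grain(1:6, 2) # 1.5 3.5 5.5
#' @export
coarse_grain <- function(x, scale) {
  aggregate_series(x, scale) / as.integer(scale)
}

#' Sample entropy
#'
#' SampEn(m, r): the negative natural logarithm of the conditional
#' probability that two sequences matching for m points (within tolerance
#' r, Chebyshev distance, self-matches excluded) remain matching at the
#' next point.
#'
#' @param x numeric vector, length >= m + 2, with positive SD.
#' @param m template length (default 2).
#' @param r tolerance; interpreted per `r_type`.
#' @param r_type `"fraction"` (default): tolerance is `r * sd(x)`;
#'   `"absolute"`: tolerance is `r` in the units of `x`.
#' @return SampEn value (>= 0), or `NA` with a warning when no length-m
#'   or length-(m+1) matches exist (entropy undefined).
#' @export
sample_entropy <- function(x, m = 2, r = 0.15,
                           r_type = c("fraction", "absolute")) {
  r_type <- match.arg(r_type)
  v <- ibi_values(x)
  m <- as.integer(m)
  if (m < 1) stop("m must be >= 1")
  if (length(v) < m + 2) stop("series too short for templates of length m+1")
  if (r_type == "fraction") {
    s <- sd(v)
    if (s == 0) stop("constant series: sample entropy undefined")
    tol <- r * s
  } else {
    tol <- r
  }
  if (tol <= 0) stop("tolerance must be > 0")
  counts <- sampen_counts_cpp(as.numeric(v), m, tol)
  if (counts[1] == 0 || counts[2] == 0) {
    warning("no template matches at length m or m+1: SampEn undefined")
    return(NA_real_)
  }
  -log(counts[2] / counts[1])
}

#' Multiscale entropy configuration
#'
#' @param m template length (default 2).
#' @param r tolerance as a fraction of the series SD (default 0.15).
#' @param scales coarse-graining scale factors (default 1, 5, 10, 15, 20).
#' @param r_mode `"scale1"` (default): the tolerance is fixed from the SD
#'   of the original (scale-1) series and reused at every scale, the
#'   canonical convention; `"per_scale"`: recomputed from each
#'   coarse-grained series' own SD.
#' @return list of class `mse_config`.
#' @export
mse_config <- function(m = 2, r = 0.15, scales = c(1, 5, 10, 15, 20),
                       r_mode = c("scale1", "per_scale")) {
  r_mode <- match.arg(r_mode)
  if (m < 1) stop("m must be >= 1")
  if (!(r > 0 && r < 1)) stop("r must be in (0, 1)")
  scales <- as.integer(scales)
  if (any(scales < 1)) stop("scales must be positive")
  structure(list(m = as.integer(m), r = r, scales = scales,
                 r_mode = r_mode),
            class = "mse_config")
}

#' Multiscale sample entropy
#'
#' SampEn of consecutive coarse-grained (window-averaged) versions of the
#' series at each configured scale factor. With the default `r_mode`, the
#' tolerance `r * sd` is fixed from the original series and reused at all
#' scales.
#'
#' @param x a `clean_ibi` or numeric NN vector.
#' @param cfg an [mse_config()].
#' @return data frame with columns `scale` and `sampen`; an undefined
#'   value at one scale is `NA` (with a warning) and does not affect the
#'   others.
#' @export
multiscale_entropy <- function(x, cfg = mse_config()) {
  v <- ibi_values(x)
  if (length(v) / max(cfg$scales) < 10 * (cfg$m + 1))
    stop("series too short for the largest scale factor")
  if (sd(v) == 0) stop("constant series: entropy undefined")
  tol1 <- cfg$r * sd(v)
  sampen <- vapply(cfg$scales, function(tau) {
    cg <- coarse_grain(v, tau)
    if (cfg$r_mode == "scale1") {
      sample_entropy(cg, cfg$m, tol1, r_type = "absolute")
    } else {
      sample_entropy(cg, cfg$m, cfg$r, r_type = "fraction")
    }
  }, numeric(1))
  data.frame(scale = cfg$scales, sampen = sampen)
}

#' All complexity measures for one subject
#'
#' Convenience wrapper: DFA alpha1/alpha2, allometric h and FD, and
#' multiscale entropy at the configured scales.
#'
#' @param x a `clean_ibi` or numeric NN vector.
#' @param dfa_cfg,allo_cfg,mse_cfg stage configurations.
#' @return named list of scalar measures (`dfa_alpha1`, `dfa_alpha2`,
#'   `allometric_h`, `fd`, `mse_s<scale>`...).
#' @export
complexity_measures <- function(x, dfa_cfg = dfa_config(),
                                allo_cfg = allometric_config(),
                                mse_cfg = mse_config()) {
  d <- dfa(x, dfa_cfg)
  a <- allometric_exponent(x, allo_cfg)
  m <- multiscale_entropy(x, mse_cfg)
  out <- list(dfa_alpha1 = d$alpha1, dfa_alpha2 = d$alpha2,
              allometric_h = a$h, fd = a$fd)
  for (i in seq_len(nrow(m))) out[[paste0("mse_s", m$scale[i])]] <- m$sampen[i]
  out
}
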