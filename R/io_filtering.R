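# Reading, trimming and artifact-filtering of interbeat-interval recordings.

#' Construct a raw interbeat-interval recording
#'
#' A `raw_ibi` object holds an ordered sequence of interbeat intervals
#' (IBIs, milliseconds) exactly as exported by an ambulatory recorder,
#' before any trimming or artifact filtering.
#'
#' @param intervals numeric vector of interbeat intervals in milliseconds,
#'   in recording order. All values must be finite and strictly positive.
#' @param subject_id character scalar identifying the subject.
#' @return An object of class `raw_ibi`: a list with elements
#'   `subject_id` and `intervals`. Total duration in minutes is available
#'   via [duration_minutes()].
#' @examples
#' rec <- raw_ibi(c(800, 810, 795), "s01")
#' duration_minutes(rec)
#' @export
raw_ibi <- function(intervals, subject_id = "subject") {
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0) stop("'intervals' is empty")
  bad <- which(!is.finite(intervals) | intervals <= 0)
  if (length(bad) > 0) {
    stop("non-positive or non-finite interval at position ", bad[1])
  }
  structure(list(subject_id = as.character(subject_id)[1],
                 intervals = intervals),
            class = "raw_ibi")
}

#' @export
print.raw_ibi <- function(x, ...) {
  cat(sprintf("<raw_ibi> subject %s: %d intervals, %.1f min, mean %.1f ms\n",
              x$subject_id, length(x$intervals), duration_minutes(x),
              mean(x$intervals)))
  invisible(x)
}

#' Total duration of a recording in minutes
#'
#' @param x a `raw_ibi` or `clean_ibi` object, or a numeric vector of
#'   intervals in milliseconds.
#' @return duration in minutes (sum of intervals / 60000).
#' @export
duration_minutes <- function(x) {
  sum(ibi_values(x)) / 60000
}

# Extract the interval vector from any of the accepted representations.
ibi_values <- function(x) {
  if (inherits(x, "raw_ibi") || inherits(x, "clean_ibi")) return(x$intervals)
  if (is.numeric(x)) return(as.numeric(x))
  stop("expected a raw_ibi, clean_ibi, or numeric vector")
}

#' Filter configuration for IBI preprocessing
#'
#' Bundles the trimming and artifact-filter parameters: the adaptation
#' trim at both ends, the band (absolute) thresholds, and the moving
#' central-window percentage rule.
#'
#' @param trim_minutes minutes removed from each end of the recording
#'   (default 15, so a 120-min recording yields a 90-min series).
#' @param low_pass_ms upper bound on a plausible interval, ms (default 1100).
#' @param high_pass_ms lower bound on a plausible interval, ms (default 400).
#' @param window_halfwidth intervals on each side of the central interval in
#'   the moving window (default 5, an 11-interval window).
#' @param exclusion_fraction relative deviation from the window mean beyond
#'   which the central interval is excluded (default 0.20).
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(trim_minutes = 15,
                          low_pass_ms = 1100,
                          high_pass_ms = 400,
                          window_halfwidth = 5,
                          exclusion_fraction = 0.20) {
  if (!(high_pass_ms > 0 && high_pass_ms < low_pass_ms))
    stop("need 0 < high_pass_ms < low_pass_ms")
  if (window_halfwidth < 1) stop("window_halfwidth must be >= 1")
  if (!(exclusion_fraction > 0 && exclusion_fraction < 1))
    stop("exclusion_fraction must be in (0, 1)")
  if (trim_minutes < 0) stop("trim_minutes must be >= 0")
  structure(list(trim_minutes = trim_minutes,
                 low_pass_ms = low_pass_ms,
                 high_pass_ms = high_pass_ms,
                 window_halfwidth = as.integer(window_halfwidth),
                 exclusion_fraction = exclusion_fraction),
            class = "filter_config")
}

#' Read an interbeat-interval file
#'
#' Reads plain-text RR/IBI exports. Dialect `"single_column"` is one
#' interval in milliseconds per line; `"two_column_timestamped"` is
#' `cumulative_seconds<TAB>interval_ms`. Non-numeric or non-positive
#' values are an error (naming the offending line), never silently dropped.
#'
#' @param path file path.
#' @param dialect input layout, see Details.
#' @param subject_id identifier for the recording; defaults to the file
#'   name without extension.
#' @return a [raw_ibi()] recording.
#' @export
read_ibi_file <- function(path,
                          dialect = c("single_column",
                                      "two_column_timestamped"),
                          subject_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty IBI file: ", path)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  col <- if (dialect == "single_column") 1L else 2L
  vals <- vapply(seq_along(lines), function(i) {
    fields <- strsplit(trimws(lines[i]), "[\t ,]+")[[1]]
    if (length(fields) < col)
      stop("line ", i, ": expected ", col, " field(s)")
    v <- suppressWarnings(as.numeric(fields[col]))
    if (is.na(v)) stop("line ", i, ": non-numeric interval '",
                       fields[col], "'")
    if (v <= 0) stop("line ", i, ": non-positive interval ", v)
    v
  }, numeric(1))
  raw_ibi(vals, subject_id)
}

#' Write an interbeat-interval file
#'
#' Inverse of [read_ibi_file()]; used for round-tripping generated series.
#'
#' @param x recording or numeric interval vector (ms).
#' @inheritParams read_ibi_file
#' @return `path`, invisibly.
#' @export
write_ibi_file <- function(x, path,
                           dialect = c("single_column",
                                       "two_column_timestamped")) {
  dialect <- match.arg(dialect)
  v <- ibi_values(x)
  if (dialect == "single_column") {
    writeLines(format(v, trim = TRUE, scientific = FALSE), path)
  } else {
    t_s <- cumsum(v) / 1000
    writeLines(paste(format(t_s, trim = TRUE, scientific = FALSE),
                     format(v, trim = TRUE, scientific = FALSE),
                     sep = "\t"), path)
  }
  invisible(path)
}

#' Trim the adaptation windows from a recording
#'
#' Removes `trim_minutes` from each end of the recording by cumulative
#' time (not beat count): an interval is kept iff it ends after the
#' leading trim boundary and starts before the trailing one.
#'
#' @param rec a [raw_ibi()] recording.
#' @param trim_minutes minutes removed from each end.
#' @return a trimmed `raw_ibi`.
#' @export
trim_recording <- function(rec, trim_minutes = 15) {
  v <- ibi_values(rec)
  if (trim_minutes == 0) return(rec)
  total <- sum(v)
  trim_ms <- trim_minutes * 60000
  if (total <= 2 * trim_ms)
    stop("recording (", round(total / 60000, 1),
         " min) is not longer than 2 x trim_minutes")
  ends <- cumsum(v)
  starts <- ends - v
  keep <- ends > trim_ms & starts < total - trim_ms
  raw_ibi(v[keep], if (inherits(rec, "raw_ibi")) rec$subject_id else "subject")
}

#' Band (absolute-threshold) filter
#'
#' Removes every interval above `low_pass_ms` or below `high_pass_ms`,
#' preserving the order of survivors.
#'
#' @param intervals numeric vector, ms.
#' @param low_pass_ms,high_pass_ms band thresholds, ms.
#' @return list with `intervals` (survivors) and `n_excluded`.
#' @export
band_filter <- function(intervals, low_pass_ms = 1100, high_pass_ms = 400) {
  if (!(high_pass_ms > 0 && high_pass_ms < low_pass_ms))
    stop("need 0 < high_pass_ms < low_pass_ms")
  keep <- intervals >= high_pass_ms & intervals <= low_pass_ms
  list(intervals = intervals[keep], n_excluded = sum(!keep))
}

#' Moving central-window percentage filter
#'
#' Slides a window of `2 * window_halfwidth + 1` intervals over the
#' series. The central interval is compared with the mean of its
#' neighbours (central excluded); if it deviates from that mean by more
#' than `exclusion_fraction` of the mean it is excluded and the window
#' advances to the next interval. The scan is a single forward pass over
#' the evolving series: an excluded interval no longer participates in
#' later windows. The first and last `window_halfwidth` intervals have no
#' full window and are never candidates for exclusion.
#'
#' @param intervals numeric vector, ms.
#' @param window_halfwidth intervals on each side of the centre.
#' @param exclusion_fraction relative deviation threshold.
#' @return list with `intervals` (survivors) and `n_excluded`.
#' @export
central_window_filter <- function(intervals, window_halfwidth = 5,
                                  exclusion_fraction = 0.20) {
  hw <- as.integer(window_halfwidth)
  if (hw < 1) stop("window_halfwidth must be >= 1")
  if (length(intervals) <= 2 * hw)
    stop("series too short for one full window of ", 2 * hw + 1,
         " intervals")
  x <- intervals
  i <- hw + 1L
  n_excluded <- 0L
  while (i + hw <= length(x)) {
    nb <- c(x[(i - hw):(i - 1L)], x[(i + 1L):(i + hw)])
    m <- mean(nb)
    if (abs(x[i] - m) > exclusion_fraction * m) {
      x <- x[-i]
      n_excluded <- n_excluded + 1L
      # the following interval shifts into position i; do not advance
    } else {
      i <- i + 1L
    }
  }
  list(intervals = x, n_excluded = n_excluded)
}

#' Preprocess a raw recording into a clean NN series
#'
#' Applies, in order: adaptation trim, band filter, central-window filter.
#' The exclusion report counts intervals relative to the trimmed series
#' entering the artifact filters.
#'
#' @param rec a [raw_ibi()] recording.
#' @param cfg a [filter_config()].
#' @return an object of class `clean_ibi`: list with `subject_id`,
#'   `intervals` (the NN series, ms) and `report`, a one-row data frame
#'   with columns `n_input`, `n_excluded_band`, `n_excluded_window`,
#'   `n_output`, `excluded_fraction`.
#' @examples
#' rec <- gen_series("white", duration_minutes = 120, seed = 1)
#' cln <- preprocess(rec)
#' cln$report
#' @export
preprocess <- function(rec, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  trimmed <- trim_recording(rec, cfg$trim_minutes)
  v0 <- ibi_values(trimmed)
  bf <- band_filter(v0, cfg$low_pass_ms, cfg$high_pass_ms)
  wf <- central_window_filter(bf$intervals, cfg$window_halfwidth,
                              cfg$exclusion_fraction)
  n_input <- length(v0)
  report <- data.frame(
    subject_id = if (inherits(rec, "raw_ibi")) rec$subject_id else "subject",
    n_input = n_input,
    n_excluded_band = bf$n_excluded,
    n_excluded_window = wf$n_excluded,
    n_output = length(wf$intervals),
    excluded_fraction = (bf$n_excluded + wf$n_excluded) / n_input,
    stringsAsFactors = FALSE)
  structure(list(subject_id = report$subject_id,
                 intervals = wf$intervals,
                 report = report),
            class = "clean_ibi")
}

#' @export
print.clean_ibi <- function(x, ...) {
  cat(sprintf(
    "<clean_ibi> subject %s: %d NN intervals (%.2f%% excluded)\n",
    x$subject_id, length(x$intervals), 100 * x$report$excluded_fraction))
  invisible(x)
}
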