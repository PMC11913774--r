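#' Evenly sampled signal
#'
#' Container for a uniformly resampled series, e.g. the 4 Hz inter-beat
#' interval tachogram consumed by the prewhitening and cross-correlation
#' stages. Sample `k` (1-based) sits at time `t0_s + (k - 1) / rate_hz`.
#'
#' @param values Numeric vector, no missing values.
#' @param rate_hz Sampling rate in Hz (4 by default, the rate used throughout
#'   the cross-correlation pipeline).
#' @param t0_s Time of the first sample, in seconds from the block start.
#' @return An object of class `uniform_series`.
#' @export
uniform_series <- function(values, rate_hz = 4, t0_s = 0) {
  values <- as.numeric(values)
  assert_finite(values)
  assert_scalar(rate_hz)
  assert_scalar(t0_s)
  if (rate_hz <= 0) stop("rate_hz must be positive", call. = FALSE)
  structure(
    list(values = values, rate_hz = rate_hz, t0_s = t0_s),
    class = "uniform_series"
  )
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf(
    "<uniform_series> %d samples @ %g Hz, t0 = %.3f s, span %.1f s\n",
    length(x$values), x$rate_hz, x$t0_s,
    (length(x$values) - 1) / x$rate_hz
  ))
  invisible(x)
}

#' @export
length.uniform_series <- function(x) length(x$values)

#' Sample times of a uniform series
#' @param x A `uniform_series`.
#' @return Numeric vector of sample times in seconds.
#' @export
time_points <- function(x) {
  stopifnot(inherits(x, "uniform_series"))
  x$t0_s + (seq_along(x$values) - 1) / x$rate_hz
}

#' Inter-beat interval series
#'
#' Beat-domain RR intervals: `ibi_ms[i]` is the interval ending at
#' `beat_times_s[i]` (the time of the second R-peak of the pair).
#'
#' @param beat_times_s Strictly increasing beat times in seconds.
#' @param ibi_ms Interval lengths in milliseconds, positive.
#' @param replaced Logical mask flagging interpolated (artifact-corrected)
#'   intervals.
#' @return An object of class `ibi_series`.
#' @export
ibi_series <- function(beat_times_s, ibi_ms, replaced = logical(length(ibi_ms))) {
  beat_times_s <- as.numeric(beat_times_s)
  ibi_ms <- as.numeric(ibi_ms)
  if (length(beat_times_s) != length(ibi_ms)) {
    stop("beat_times_s and ibi_ms must have the same length", call. = FALSE)
  }
  assert_finite(beat_times_s)
  assert_finite(ibi_ms)
  if (any(ibi_ms <= 0)) stop("ibi_ms must be positive", call. = FALSE)
  if (length(beat_times_s) > 1 && any(diff(beat_times_s) <= 0)) {
    stop("beat_times_s must be strictly increasing", call. = FALSE)
  }
  replaced <- as.logical(replaced)
  stopifnot(length(replaced) == length(ibi_ms))
  structure(
    list(beat_times_s = beat_times_s, ibi_ms = ibi_ms, replaced = replaced),
    class = "ibi_series"
  )
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf(
    "<ibi_series> %d intervals, mean %.0f ms, %.1f%% replaced, span %.1f s\n",
    length(x$ibi_ms), mean(x$ibi_ms), 100 * mean(x$replaced),
    diff(range(x$beat_times_s))
  ))
  invisible(x)
}

#' Raw ECG recording
#'
#' @param samples Voltage samples (arbitrary units).
#' @param fs Sampling rate in Hz; the study hardware recorded at 512 Hz.
#' @param subject,block Optional identifiers carried through the pipeline.
#' @return An object of class `ecg_recording`.
#' @export
ecg_recording <- function(samples, fs, subject = NA, block = NA) {
  samples <- as.numeric(samples)
  assert_finite(samples)
  assert_scalar(fs)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  structure(
    list(samples = samples, fs = fs, subject = subject, block = block),
    class = "ecg_recording"
  )
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf(
    "<ecg_recording> %d samples @ %g Hz (%.1f s)\n",
    length(x$samples), x$fs, length(x$samples) / x$fs
  ))
  invisible(x)
}

#' Detected R-peak series
#'
#' @param peak_times_s Strictly increasing peak times in seconds.
#' @param peak_indices 1-based sample indices of the peaks.
#' @return An object of class `rpeak_series`.
#' @export
rpeak_series <- function(peak_times_s, peak_indices) {
  peak_times_s <- as.numeric(peak_times_s)
  peak_indices <- as.integer(peak_indices)
  stopifnot(length(peak_times_s) == length(peak_indices))
  assert_finite(peak_times_s)
  if (length(peak_times_s) > 1 && any(diff(peak_times_s) <= 0)) {
    stop("peak_times_s must be strictly increasing", call. = FALSE)
  }
  structure(
    list(peak_times_s = peak_times_s, peak_indices = peak_indices),
    class = "rpeak_series"
  )
}

#' @export
print.rpeak_series <- function(x, ...) {
  cat(sprintf(
    "<rpeak_series> %d peaks, mean RR %.0f ms\n",
    length(x$peak_times_s),
    if (length(x$peak_times_s) > 1) 1000 * mean(diff(x$peak_times_s)) else NA_real_
  ))
  invisible(x)
}
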