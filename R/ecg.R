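#' Band-pass filter an ECG recording
#'
#' Zero-phase (forward-backward) second-order Butterworth filtering: a
#' high-pass at `hp_hz` removes baseline wander, a low-pass at `lp_hz`
#' removes high-frequency noise. Zero-phase filtering avoids biasing R-peak
#' times.
#'
#' @param ecg An [ecg_recording()].
#' @param hp_hz High-pass cutoff in Hz (default 0.6).
#' @param lp_hz Low-pass cutoff in Hz (default 20).
#' @return A filtered [ecg_recording()] of the same length and rate.
#' @export
bandpass_filter <- function(ecg, hp_hz = 0.6, lp_hz = 20) {
  stopifnot(inherits(ecg, "ecg_recording"))
  assert_scalar(hp_hz)
  assert_scalar(lp_hz)
  if (hp_hz <= 0 || hp_hz >= lp_hz) stop("need 0 < hp_hz < lp_hz", call. = FALSE)
  if (lp_hz >= ecg$fs / 2) {
    stop("lp_hz must be below the Nyquist frequency fs/2", call. = FALSE)
  }
  hp <- signal::butter(2, hp_hz / (ecg$fs / 2), type = "high")
  lp <- signal::butter(2, lp_hz / (ecg$fs / 2), type = "low")
  pad_hp <- round(3 * ecg$fs / hp_hz)
  pad_lp <- round(3 * ecg$fs / lp_hz)
  y <- filtfilt_padded(lp, filtfilt_padded(hp, ecg$samples, pad_hp), pad_lp)
  out <- ecg_recording(y, ecg$fs, ecg$subject, ecg$block)
  attr(out, "true_r_indices") <- attr(ecg, "true_r_indices")
  out
}

# Adaptive amplitude threshold: 0.5 x the rolling 95th percentile of the
# signal over `window_s` windows, linearly interpolated between window
# centers. Floored at a fraction of the global near-maximum amplitude so
# that edge windows containing no QRS complex cannot pull the threshold
# down to the noise floor.
adaptive_threshold <- function(x, fs, window_s = 2, fraction = 0.5,
                               global_floor = 0.3) {
  n <- length(x)
  w <- max(2L, round(window_s * fs))
  starts <- seq(1L, n, by = w)
  q <- vapply(starts, function(s) {
    stats::quantile(x[s:min(n, s + w - 1L)], 0.95, names = FALSE)
  }, numeric(1))
  centers <- pmin(starts + (w - 1L) / 2, n)
  thr <- if (length(q) == 1L) rep(fraction * q, n) else
    fraction * stats::approx(centers, q, xout = seq_len(n), rule = 2)$y
  pmax(thr, global_floor * stats::quantile(x, 0.999, names = FALSE))
}

#' Detect R-peaks in a filtered ECG
#'
#' Local maxima above an adaptive amplitude threshold (half the rolling 95th
#' percentile over 2 s windows), with a 250 ms refractory period: when two
#' candidate peaks fall closer than `min_distance_s`, the larger one is kept.
#'
#' @param ecg A band-pass filtered [ecg_recording()].
#' @param min_distance_s Minimum inter-peak distance in seconds.
#' @return An [rpeak_series()].
#' @export
detect_rpeaks <- function(ecg, min_distance_s = 0.25) {
  stopifnot(inherits(ecg, "ecg_recording"))
  x <- ecg$samples
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0) stop("no peaks: flat or empty signal", call. = FALSE)
  thr <- adaptive_threshold(x, ecg$fs)
  core <- 2:(n - 1)
  cand <- core[x[core] > x[core - 1] & x[core] >= x[core + 1] & x[core] > thr[core]]
  if (length(cand) == 0) stop("no peaks found above threshold", call. = FALSE)

  # Greedy refractory resolution: accept candidates by decreasing amplitude,
  # rejecting any within min_distance_s of an already accepted peak.
  min_gap <- min_distance_s * ecg$fs
  ord <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(n)
  for (i in ord) {
    lo <- max(1L, ceiling(i - min_gap))
    hi <- min(n, floor(i + min_gap))
    if (!any(keep[lo:hi])) keep[i] <- TRUE
  }
  idx <- which(keep)
  rpeak_series(peak_times_s = (idx - 1) / ecg$fs, peak_indices = idx)
}

#' Compute inter-beat intervals from R-peaks
#'
#' `ibi_ms[i]` is the difference in milliseconds between consecutive R-peak
#' times; each interval is stamped with the time of its second beat.
#'
#' @param rpeaks An [rpeak_series()] with at least 3 peaks.
#' @return An [ibi_series()].
#' @export
compute_ibi <- function(rpeaks) {
  stopifnot(inherits(rpeaks, "rpeak_series"))
  if (length(rpeaks$peak_times_s) < 3) {
    stop("need at least 3 R-peaks to form an IBI series", call. = FALSE)
  }
  ibi_series(
    beat_times_s = rpeaks$peak_times_s[-1],
    ibi_ms = diff(rpeaks$peak_times_s) * 1000
  )
}

#' Flag and interpolate artifactual inter-beat intervals
#'
#' An interval is flagged when it falls outside the absolute physiological
#' range `abs_range_ms`, or deviates from the 11-beat rolling median by more
#' than a fraction `rel_tol` of that median. Flagged values are replaced by a
#' natural cubic spline fit through the surviving beats as a function of beat
#' time. The replacement fraction is reported via the `replaced` mask and the
#' `replaced_fraction` attribute; a block with more than `max_fraction`
#' flagged beats is rejected as unusable.
#'
#' @param ibi An [ibi_series()].
#' @param abs_range_ms Acceptable absolute interval range in ms.
#' @param rel_tol Maximum tolerated fractional deviation from the rolling
#'   median.
#' @param max_fraction Maximum tolerated fraction of flagged beats.
#' @return A cleaned [ibi_series()] with attribute `replaced_fraction`.
#' @export
clean_ibi <- function(ibi, abs_range_ms = c(300, 2000), rel_tol = 0.25,
                      max_fraction = 0.25) {
  stopifnot(inherits(ibi, "ibi_series"))
  x <- ibi$ibi_ms
  n <- length(x)
  if (n == 0) stop("empty IBI series", call. = FALSE)
  k <- min(11L, if (n %% 2 == 0) n - 1L else n)
  med <- if (k >= 3) stats::runmed(x, k, endrule = "median") else rep(stats::median(x), n)
  bad <- x < abs_range_ms[1] | x > abs_range_ms[2] | abs(x - med) > rel_tol * med
  frac <- mean(bad)
  if (frac > max_fraction) {
    stop(sprintf("block unusable: %.0f%% of beats flagged as artifacts", 100 * frac),
         call. = FALSE)
  }
  if (any(bad)) {
    if (sum(!bad) < 4) stop("too few clean beats to interpolate", call. = FALSE)
    sf <- stats::splinefun(ibi$beat_times_s[!bad], x[!bad], method = "natural")
    x[bad] <- sf(ibi$beat_times_s[bad])
    x <- pmin(pmax(x, abs_range_ms[1]), abs_range_ms[2])
  }
  out <- ibi_series(ibi$beat_times_s, x, replaced = ibi$replaced | bad)
  attr(out, "replaced_fraction") <- frac
  out
}

#' Resample an IBI series onto a uniform grid
#'
#' Natural cubic-spline interpolation of the interval lengths as a function of
#' beat time, evaluated at `rate_hz` from the first to the last beat (no
#' extrapolation). When `align_grid` is `TRUE` the grid is anchored to
#' multiples of `1/rate_hz` from the block start so that two subjects'
#' resampled series share sample times and can be trimmed to a common grid.
#'
#' @param ibi A cleaned [ibi_series()] spanning at least `min_duration_s`.
#' @param rate_hz Target sampling rate in Hz (default 4).
#' @param align_grid Anchor grid points to multiples of `1/rate_hz`.
#' @param min_duration_s Minimum acceptable span of the series in seconds.
#' @return A [uniform_series()] of IBI values in ms.
#' @export
resample_ibi <- function(ibi, rate_hz = 4, align_grid = TRUE, min_duration_s = 10) {
  stopifnot(inherits(ibi, "ibi_series"))
  assert_scalar(rate_hz)
  if (rate_hz <= 0) stop("rate_hz must be positive", call. = FALSE)
  bt <- ibi$beat_times_s
  if (length(bt) < 4) stop("need at least 4 beats to resample", call. = FALSE)
  span <- bt[length(bt)] - bt[1]
  if (span < min_duration_s) {
    stop(sprintf("series spans %.1f s; at least %g s required", span, min_duration_s),
         call. = FALSE)
  }
  t0 <- if (align_grid) ceiling(bt[1] * rate_hz - 1e-9) / rate_hz else bt[1]
  n_out <- floor((bt[length(bt)] - t0) * rate_hz + 1e-9) + 1L
  grid <- t0 + (seq_len(n_out) - 1) / rate_hz
  sf <- stats::splinefun(bt, ibi$ibi_ms, method = "natural")
  uniform_series(sf(grid), rate_hz, t0)
}
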