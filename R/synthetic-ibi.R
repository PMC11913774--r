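#' Configuration for a coupled dyadic IBI generator
#'
#' Describes one block of two subjects' inter-beat-interval dynamics. Each
#' subject's IBI fluctuation is the sum of an AR(1) process, a linear trend, a
#' quasi-periodic respiratory-like oscillation, and `coupling_gain` times a
#' shared low-pass Gaussian driver (the latent autonomic co-fluctuation).
#' Subject 2 receives the driver delayed by `coupling_lag_samples` samples, so
#' planted coupling peaks at a positive cross-correlation lag (subject 1
#' leading).
#'
#' Defaults emulate a seated adult: mean RR around 850/820 ms, total
#' fluctuation SD 45 ms with strong lag-1 autocorrelation, a slow drift, and a
#' ~0.25 Hz respiratory oscillation. The driver bandwidth of 0.1 Hz reflects
#' the multi-second time scale at which dyadic cardiac co-fluctuation is
#' measured (lags of a few seconds).
#'
#' @param baseline_ibi_ms Length-2 numeric, mean RR interval (ms) per subject;
#'   must lie in `[300, 2000]`.
#' @param ibi_sd_ms Stationary SD of the AR(1) fluctuation component (ms).
#' @param ar_coefficient Lag-1 autoregressive coefficient, `|phi| < 1`.
#' @param trend_slope_ms_per_min Linear drift of the IBI level (ms per minute).
#' @param seasonal_period_s Period of the respiratory-like oscillation (s).
#' @param seasonal_amplitude_ms Amplitude of that oscillation (ms).
#' @param seasonal_phase_sd Per-sample SD of the oscillation's random phase
#'   walk (radians); makes the component quasi-periodic rather than strictly
#'   sinusoidal.
#' @param coupling_gain Non-negative weight of the shared driver, expressed as
#'   a multiple of `ibi_sd_ms`.
#' @param coupling_lag_samples Integer delay (in samples) of the driver into
#'   subject 2.
#' @param driver_bandwidth_hz Low-pass cutoff of the shared driver (Hz).
#' @param block_duration_s Block length in seconds.
#' @param rate_hz Sampling rate of the generated tachogram (4 Hz, the rate the
#'   cross-correlation pipeline consumes).
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return A list of class `coupling_config`.
#' @export
coupling_config <- function(baseline_ibi_ms = c(850, 820),
                            ibi_sd_ms = 45,
                            ar_coefficient = 0.8,
                            trend_slope_ms_per_min = 5,
                            seasonal_period_s = 4,
                            seasonal_amplitude_ms = 20,
                            seasonal_phase_sd = 0.05,
                            coupling_gain = 0,
                            coupling_lag_samples = 0,
                            driver_bandwidth_hz = 0.1,
                            block_duration_s = 300,
                            rate_hz = 4,
                            seed = NULL) {
  baseline_ibi_ms <- rep_len(as.numeric(baseline_ibi_ms), 2L)
  vals <- c(
    baseline_ibi_ms, ibi_sd_ms, ar_coefficient, trend_slope_ms_per_min,
    seasonal_period_s, seasonal_amplitude_ms, seasonal_phase_sd,
    coupling_gain, coupling_lag_samples, driver_bandwidth_hz,
    block_duration_s, rate_hz
  )
  if (!all(is.finite(vals))) stop("coupling_config values must be finite", call. = FALSE)
  if (any(baseline_ibi_ms < 300) || any(baseline_ibi_ms > 2000)) {
    stop("baseline_ibi_ms must lie in [300, 2000]", call. = FALSE)
  }
  if (abs(ar_coefficient) >= 1) stop("|ar_coefficient| must be < 1", call. = FALSE)
  if (coupling_gain < 0) stop("coupling_gain must be >= 0", call. = FALSE)
  if (ibi_sd_ms < 0 || seasonal_amplitude_ms < 0) {
    stop("ibi_sd_ms and seasonal_amplitude_ms must be >= 0", call. = FALSE)
  }
  if (block_duration_s <= 0 || rate_hz <= 0 || seasonal_period_s <= 0) {
    stop("durations, rates and periods must be positive", call. = FALSE)
  }
  if (driver_bandwidth_hz <= 0 || driver_bandwidth_hz >= rate_hz / 2) {
    stop("driver_bandwidth_hz must lie in (0, rate_hz / 2)", call. = FALSE)
  }
  if (coupling_lag_samples != round(coupling_lag_samples) || coupling_lag_samples < 0) {
    stop("coupling_lag_samples must be a non-negative integer", call. = FALSE)
  }
  structure(
    list(
      baseline_ibi_ms = baseline_ibi_ms,
      ibi_sd_ms = ibi_sd_ms,
      ar_coefficient = ar_coefficient,
      trend_slope_ms_per_min = trend_slope_ms_per_min,
      seasonal_period_s = seasonal_period_s,
      seasonal_amplitude_ms = seasonal_amplitude_ms,
      seasonal_phase_sd = seasonal_phase_sd,
      coupling_gain = coupling_gain,
      coupling_lag_samples = as.integer(coupling_lag_samples),
      driver_bandwidth_hz = driver_bandwidth_hz,
      block_duration_s = block_duration_s,
      rate_hz = rate_hz,
      seed = seed
    ),
    class = "coupling_config"
  )
}

# Unit-SD low-pass Gaussian driver of length n (zero-phase Butterworth).
lowpass_driver <- function(n, cutoff_hz, rate_hz) {
  raw <- stats::rnorm(n)
  bf <- signal::butter(2, cutoff_hz / (rate_hz / 2), type = "low")
  d <- filtfilt_padded(bf, raw, pad = round(3 * rate_hz / cutoff_hz))
  s <- stats::sd(d)
  if (s == 0) rep(0, n) else (d - mean(d)) / s
}

#' Generate one block of coupled dyadic IBI series
#'
#' Draws two 4 Hz IBI tachograms whose fluctuations share a low-pass latent
#' driver weighted by `coupling_gain`. With `coupling_gain = 0` the two series
#' are independent. Values are clamped to the physiological range
#' `[300, 2000]` ms (the clamp is inactive under default settings).
#'
#' @param config A [coupling_config()].
#' @return A list with elements `s1`, `s2` (each a [uniform_series()] of IBI
#'   values in ms) and `truth` (the config plus the realized driver and each
#'   subject's driver contribution).
#' @export
generate_dyad_ibi <- function(config) {
  stopifnot(inherits(config, "coupling_config"))
  with_seed(config$seed, {
    n <- max(2L, round(config$block_duration_s * config$rate_hz))
    lag <- config$coupling_lag_samples
    t_s <- (seq_len(n) - 1) / config$rate_hz

    drv <- lowpass_driver(n + lag, config$driver_bandwidth_hz, config$rate_hz)
    drv1 <- drv[(lag + 1):(lag + n)] # subject 1 sees the driver directly
    drv2 <- drv[1:n]                 # subject 2 sees it delayed by `lag`

    one_subject <- function(drv_i, base) {
      innov_sd <- config$ibi_sd_ms * sqrt(1 - config$ar_coefficient^2)
      ar <- as.numeric(stats::filter(
        stats::rnorm(n, sd = innov_sd),
        config$ar_coefficient,
        method = "recursive"
      ))
      trend <- config$trend_slope_ms_per_min * t_s / 60
      phase <- cumsum(stats::rnorm(n, sd = config$seasonal_phase_sd)) +
        stats::runif(1, 0, 2 * pi)
      seasonal <- config$seasonal_amplitude_ms *
        sin(2 * pi * t_s / config$seasonal_period_s + phase)
      coupled <- config$coupling_gain * config$ibi_sd_ms * drv_i
      pmin(pmax(base + ar + trend + seasonal + coupled, 300), 2000)
    }

    s1 <- one_subject(drv1, config$baseline_ibi_ms[1])
    s2 <- one_subject(drv2, config$baseline_ibi_ms[2])
    list(
      s1 = uniform_series(s1, config$rate_hz, 0),
      s2 = uniform_series(s2, config$rate_hz, 0),
      truth = list(
        config = config,
        driver_s1 = drv1,
        driver_s2 = drv2
      )
    )
  })
}

#' Convert a uniform IBI tachogram to a beat-domain series
#'
#' Integrates the instantaneous IBI signal into a sequence of beat times:
#' starting at the first grid point, each next beat falls one current-IBI
#' later, with the tachogram linearly interpolated at the current beat time.
#' This is the inverse of the resampling step and feeds the beat-domain parts
#' of the pipeline (ECG synthesis, rMSSD).
#'
#' @param us A [uniform_series()] of IBI values in ms.
#' @return An [ibi_series()].
#' @export
uniform_to_beats <- function(us) {
  stopifnot(inherits(us, "uniform_series"))
  tp <- time_points(us)
  t_end <- tp[length(tp)]
  f <- stats::approxfun(tp, us$values, rule = 2)
  # Worst case one beat per 300 ms.
  beats <- numeric(ceiling((t_end - tp[1]) / 0.3) + 2L)
  beats[1] <- tp[1]
  k <- 1L
  repeat {
    nxt <- beats[k] + f(beats[k]) / 1000
    if (nxt > t_end) break
    k <- k + 1L
    beats[k] <- nxt
  }
  if (k < 3L) stop("series too short to contain three beats", call. = FALSE)
  beats <- beats[1:k]
  ibi_series(beat_times_s = beats[-1], ibi_ms = diff(beats) * 1000)
}
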