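#' Noise configuration for synthetic ECG
#'
#' @param qrs_amplitude Peak amplitude of the R wave (arbitrary units).
#' @param t_wave_amplitude Amplitude of the T wave relative template.
#' @param wander_amplitude Amplitude (SD) of the baseline wander, a low-pass
#'   (< 0.6 Hz) random drift the band-pass stage is designed to remove.
#' @param broadband_amplitude Amplitude (SD) of high-frequency (> 20 Hz)
#'   measurement noise.
#' @param wander_cutoff_hz Low-pass cutoff of the wander component.
#' @return A list of class `ecg_noise_config`.
#' @export
ecg_noise_config <- function(qrs_amplitude = 1,
                             t_wave_amplitude = 0.12,
                             wander_amplitude = 0.3,
                             broadband_amplitude = 0.05,
                             wander_cutoff_hz = 0.15) {
  vals <- c(qrs_amplitude, t_wave_amplitude, wander_amplitude,
            broadband_amplitude, wander_cutoff_hz)
  if (!all(is.finite(vals)) || any(vals < 0)) {
    stop("ecg_noise_config values must be finite and non-negative", call. = FALSE)
  }
  if (qrs_amplitude <= 0) stop("qrs_amplitude must be positive", call. = FALSE)
  structure(
    list(
      qrs_amplitude = qrs_amplitude,
      t_wave_amplitude = t_wave_amplitude,
      wander_amplitude = wander_amplitude,
      broadband_amplitude = broadband_amplitude,
      wander_cutoff_hz = wander_cutoff_hz
    ),
    class = "ecg_noise_config"
  )
}

# QRS-like waveform sampled at fs around an R peak: narrow positive R wave
# flanked by small Q and S deflections, plus an optional broad T wave.
qrs_template <- function(fs, qrs_amplitude, t_wave_amplitude) {
  t <- seq(-0.08, 0.36, by = 1 / fs)
  w <- qrs_amplitude * (
    exp(-(t / 0.012)^2) -
      0.15 * exp(-((t + 0.028) / 0.010)^2) -
      0.25 * exp(-((t - 0.028) / 0.010)^2)
  ) + t_wave_amplitude * qrs_amplitude * exp(-((t - 0.22) / 0.05)^2)
  list(values = w, center = which.min(abs(t)))
}

#' Synthesize an ECG trace from known R-peak times
#'
#' Places a QRS-like template at each requested R time and adds baseline
#' wander (below the band-pass high-pass cutoff) and broadband noise (above
#' the low-pass cutoff). The true R sample indices are attached as attribute
#' `true_r_indices`, giving downstream peak detection a ground truth.
#'
#' @param r_times_s Strictly increasing R-peak times in seconds; successive
#'   peaks must be at least 250 ms apart.
#' @param fs Sampling rate in Hz, at least 128.
#' @param noise An [ecg_noise_config()].
#' @param seed Optional seed for the noise components.
#' @return An [ecg_recording()] with attribute `true_r_indices`.
#' @export
generate_ecg_from_rpeaks <- function(r_times_s, fs = 512,
                                     noise = ecg_noise_config(),
                                     seed = NULL) {
  r_times_s <- as.numeric(r_times_s)
  assert_finite(r_times_s)
  if (length(r_times_s) < 2) stop("need at least two R times", call. = FALSE)
  if (any(diff(r_times_s) <= 0)) stop("r_times_s must be strictly increasing", call. = FALSE)
  if (any(diff(r_times_s) < 0.25)) {
    stop("r_times_s closer than 250 ms are not physiological", call. = FALSE)
  }
  assert_scalar(fs)
  if (fs < 128) stop("fs must be at least 128 Hz", call. = FALSE)
  stopifnot(inherits(noise, "ecg_noise_config"))

  with_seed(seed, {
    n <- ceiling((max(r_times_s) + 0.5) * fs) + 1L
    x <- numeric(n)
    tpl <- qrs_template(fs, noise$qrs_amplitude, noise$t_wave_amplitude)
    idx_r <- round(r_times_s * fs) + 1L
    for (i in idx_r) {
      lo <- i - tpl$center + 1L
      hi <- lo + length(tpl$values) - 1L
      sl <- max(1L, lo):min(n, hi)
      x[sl] <- x[sl] + tpl$values[sl - lo + 1L]
    }
    if (noise$wander_amplitude > 0) {
      bf <- signal::butter(2, noise$wander_cutoff_hz / (fs / 2), type = "low")
      w <- filtfilt_padded(bf, stats::rnorm(n),
                           pad = round(3 * fs / noise$wander_cutoff_hz))
      s <- stats::sd(w)
      if (s > 0) x <- x + noise$wander_amplitude * w / s
    }
    if (noise$broadband_amplitude > 0) {
      bf <- signal::butter(2, 22 / (fs / 2), type = "high")
      hf <- filtfilt_padded(bf, stats::rnorm(n), pad = round(fs / 4))
      s <- stats::sd(hf)
      if (s > 0) x <- x + noise$broadband_amplitude * hf / s
    }
    out <- ecg_recording(x, fs)
    attr(out, "true_r_indices") <- idx_r
    out
  })
}
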