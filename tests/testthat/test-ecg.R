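test_that("synthetic ECG places template peaks at the requested times", {
  r <- 0:59
  ecg <- generate_ecg_from_rpeaks(r + 0.5, fs = 512,
                                  noise = ecg_noise_config(wander_amplitude = 0,
                                                           broadband_amplitude = 0),
                                  seed = 1)
  idx <- attr(ecg, "true_r_indices")
  expect_length(idx, 60)
  expect_true(all(diff(idx) == 512))
  # zero-noise: argmax within each beat window is the true R sample
  for (i in idx[c(1, 30, 60)]) {
    win <- (i - 50):(i + 50)
    expect_equal(win[which.max(ecg$samples[win])], i)
  }
})

test_that("synthetic ECG rejects non-physiological R times", {
  expect_error(generate_ecg_from_rpeaks(c(0, 0.1), fs = 512), "250 ms")
  expect_error(generate_ecg_from_rpeaks(c(1, 0.5), fs = 512), "increasing")
  expect_error(generate_ecg_from_rpeaks(c(0, 1), fs = 64), "128")
})

test_that("band-pass filter removes DC and out-of-band components", {
  fs <- 512
  t <- seq(0, 20, by = 1 / fs)
  # constant input -> all-zero output
  flat <- bandpass_filter(ecg_recording(rep(3, length(t)), fs))
  expect_lt(max(abs(flat$samples)), 1e-4)
  # 5 Hz sits in the passband: < 5% attenuation
  s5 <- bandpass_filter(ecg_recording(sin(2 * pi * 5 * t), fs))
  mid <- seq(2 * fs, 18 * fs)
  expect_gt(max(s5$samples[mid]), 0.95)
  # 0.1 Hz sits below the high-pass cutoff: > 90% attenuation
  s01 <- bandpass_filter(ecg_recording(sin(2 * pi * 0.1 * t), fs))
  expect_lt(max(abs(s01$samples[mid])), 0.1)
  expect_error(bandpass_filter(ecg_recording(t, fs = 30)), "Nyquist")
})

test_that("R-peak detection is exact on a clean 60 bpm trace", {
  ecg <- generate_ecg_from_rpeaks(seq(0.5, 59.5), fs = 512,
                                  noise = ecg_noise_config(wander_amplitude = 0,
                                                           broadband_amplitude = 0),
                                  seed = 2)
  pk <- detect_rpeaks(bandpass_filter(ecg))
  expect_length(pk$peak_indices, 60)
  expect_true(all(abs(diff(pk$peak_times_s) - 1) < 2 / 512))
})

test_that("detection survives heavy baseline wander after band-passing", {
  set.seed(3)
  r <- cumsum(pmax(0.5, rnorm(50, 0.85, 0.05)))
  ecg <- generate_ecg_from_rpeaks(r, fs = 512,
                                  noise = ecg_noise_config(wander_amplitude = 3),
                                  seed = 3)
  pk <- detect_rpeaks(bandpass_filter(ecg))
  truth <- attr(ecg, "true_r_indices")
  expect_length(pk$peak_indices, length(truth))
  expect_true(all(abs(pk$peak_indices - truth) <= 2))
})

test_that("flat or empty traces raise a no-peak error", {
  expect_error(detect_rpeaks(ecg_recording(rep(0, 1000), 512)), "flat")
})

test_that("compute_ibi turns peak times into millisecond intervals", {
  expect_equal(
    compute_ibi(rpeak_series(c(0, 1, 2), c(1, 513, 1025)))$ibi_ms,
    c(1000, 1000)
  )
  out <- compute_ibi(rpeak_series(c(0, 0.8, 1.7), c(1, 410, 871)))
  expect_equal(out$ibi_ms, c(800, 900))
  expect_equal(out$beat_times_s, c(0.8, 1.7))
  expect_error(compute_ibi(rpeak_series(c(0, 1), c(1, 513))), "at least 3")
})

test_that("clean_ibi replaces isolated outliers by their neighbourhood", {
  x <- rep(1000, 20)
  x[10] <- 2500
  ibi <- ibi_series(seq_along(x), x)
  out <- clean_ibi(ibi)
  expect_equal(out$ibi_ms[10], 1000, tolerance = 1e-6)
  expect_equal(sum(out$replaced), 1)
  expect_equal(attr(out, "replaced_fraction"), 1 / 20)
})

test_that("clean_ibi leaves clean series untouched and is idempotent", {
  set.seed(4)
  x <- 900 + cumsum(rnorm(50, 0, 5))
  ibi <- ibi_series(cumsum(x / 1000), x)
  out <- clean_ibi(ibi)
  expect_equal(out$ibi_ms, x)
  expect_equal(attr(out, "replaced_fraction"), 0)
  twice <- clean_ibi(out)
  expect_equal(twice$ibi_ms, out$ibi_ms)
  expect_equal(sum(twice$replaced), sum(out$replaced))
})

test_that("clean_ibi rejects blocks with too many artifacts", {
  x <- rep(1000, 20)
  x[1:6] <- 2600 # 30% flagged
  expect_error(clean_ibi(ibi_series(seq_along(x), x)), "unusable")
})

test_that("resample_ibi reproduces constant and linear tachograms", {
  n <- 61
  const <- ibi_series(seq(0, 60, length.out = n), rep(1000, n))
  u <- resample_ibi(const)
  expect_equal(length(u$values), 241)
  expect_true(all(abs(u$values - 1000) < 1e-9))
  ramp_t <- seq(0, 60, length.out = n)
  ramp <- ibi_series(ramp_t, 800 + ramp_t / 60 * 200)
  ur <- resample_ibi(ramp)
  expected <- 800 + time_points(ur) / 60 * 200
  expect_true(all(abs(ur$values - expected) < 1e-6))
  expect_error(resample_ibi(const, rate_hz = 0), "positive")
  short <- ibi_series(c(0, 1, 2, 3), rep(1000, 4))
  expect_error(resample_ibi(short), "10")
})

test_that("resampling preserves the mean of smooth series within 1%", {
  set.seed(5)
  p <- quick_dyad(dur = 60, seed = 6)
  b <- uniform_to_beats(p$s1)
  u <- resample_ibi(b)
  expect_lt(abs(mean(u$values) - mean(b$ibi_ms)) / mean(b$ibi_ms), 0.01)
})

test_that("ECG round trip recovers the generating IBI series", {
  set.seed(7)
  mae <- vapply(1:5, function(i) {
    rr <- pmax(0.5, rnorm(70, 0.85, 0.05))
    r <- cumsum(rr)
    ecg <- generate_ecg_from_rpeaks(r, fs = 512, seed = 70 + i)
    ibi <- compute_ibi(detect_rpeaks(bandpass_filter(ecg)))
    truth <- diff(r) * 1000
    expect_length(ibi$ibi_ms, length(truth))
    mean(abs(ibi$ibi_ms - truth))
  }, numeric(1))
  expect_lt(mean(mae), 2)
})
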