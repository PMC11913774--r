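test_that("CCF of a series with itself peaks at lag zero with value 1", {
  set.seed(1)
  x <- rnorm(300)
  ccf <- cross_correlation(x, x, max_lag = 12)
  expect_equal(ccf$values[ccf$lags == 0], 1)
  expect_equal(which.max(ccf$values), which(ccf$lags == 0))
  expect_length(ccf$values, 25)
})

test_that("a delayed copy moves the CCF peak to the delay", {
  set.seed(2)
  x <- rnorm(400)
  y <- c(rep(0, 3), x[1:397]) # subject 2 follows subject 1 by 3 samples
  ccf <- cross_correlation(x, y, max_lag = 12)
  expect_equal(ccf$lags[which.max(ccf$values)], 3)
})

test_that("independent white noise stays inside the normal-approximation band", {
  set.seed(3)
  n <- 1200
  frac_ok <- mean(vapply(1:30, function(i) {
    ccf <- cross_correlation(rnorm(n), rnorm(n), max_lag = 12)
    all(abs(ccf$values) < 4 / sqrt(n))
  }, logical(1)))
  expect_gte(frac_ok, 0.99 - 0.05)
})

test_that("every lag value matches the naive double-loop oracle", {
  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(150)
    y <- rnorm(150)
    ccf <- cross_correlation(x, y, max_lag = 12)
    expect_lt(max(abs(ccf$values - naive_ccf(x, y, 12))), 1e-10)
  }
})

test_that("reversing the roles reverses the lag axis", {
  set.seed(5)
  a <- rnorm(300)
  b <- rnorm(300)
  ab <- cross_correlation(a, b, max_lag = 12)
  ba <- cross_correlation(b, a, max_lag = 12)
  expect_equal(ab$values, rev(ba$values), tolerance = 1e-12)
})

test_that("cross_correlation rejects degenerate inputs", {
  expect_error(cross_correlation(rep(1, 300), rnorm(300)), "zero-variance")
  expect_error(cross_correlation(rnorm(50), rnorm(50), max_lag = 12), "overlap")
  expect_error(cross_correlation(rnorm(100), rnorm(99)), "equal length")
})

test_that("uniform series are aligned to their common grid before the CCF", {
  set.seed(6)
  v <- rnorm(300)
  a <- uniform_series(v, 4, t0_s = 0)
  # same values shifted 1 s later: after alignment, subject 2 lags by 4 samples
  b <- uniform_series(v, 4, t0_s = 1)
  ccf <- cross_correlation(a, b, max_lag = 12)
  expect_equal(ccf$lags[which.max(ccf$values)], 4)
  expect_error(align_series(a, uniform_series(v, 8)), "sampling rate")
  expect_error(align_series(a, uniform_series(v, 4, t0_s = 0.1)), "lattice")
})

test_that("lag groups partition the 25 lags as negative/zero/positive", {
  flat <- new_ccf_result(-12:12, rep(0.2, 25), 300)
  gm <- lag_group_means(flat)
  expect_equal(unlist(gm), c(negative = 0.2, zero = 0.2, positive = 0.2))

  spike <- numeric(25)
  spike[13] <- 1 # lag 0
  gm2 <- lag_group_means(new_ccf_result(-12:12, spike, 300))
  expect_equal(gm2$zero, 1 / 9)
  expect_equal(gm2$negative, 0)
  expect_equal(gm2$positive, 0)

  ramp <- seq(-0.3, 0.3, length.out = 25)
  gm3 <- lag_group_means(new_ccf_result(-12:12, ramp, 300))
  expect_true(gm3$negative < gm3$zero && gm3$zero < gm3$positive)

  expect_error(lag_group_means(cross_correlation(rnorm(200), rnorm(200), max_lag = 10)),
               "25-lag")
})

test_that("average_ccf is the plain mean of the signed values", {
  set.seed(7)
  v <- runif(25, -0.5, 0.5)
  ccf <- new_ccf_result(-12:12, v, 300)
  expect_equal(average_ccf(ccf), sum(v) / 25)
  alt <- c(rep(c(0.1, -0.1), 12), 0.1)
  expect_equal(average_ccf(new_ccf_result(-12:12, alt, 300)), 0.1 / 25)
})

test_that("fisher_z matches atanh and its symmetry", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  expect_error(fisher_z(1), "< 1")
  # strictly increasing
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_true(all(diff(vapply(r, fisher_z, numeric(1))) > 0))
})

test_that("scaled synchrony is exactly 100 x Fisher Z", {
  set.seed(8)
  ccf <- cross_correlation(rnorm(300), rnorm(300))
  expect_equal(ccf$scaled, 100 * ccf$fisher_z)
  expect_equal(ccf$fisher_z, atanh(ccf$average_ccf))
})

test_that("dyad_block_synchrony is deterministic and detects planted coupling", {
  p <- quick_dyad(gain = 2, dur = 60, seed = 9)
  s1 <- dyad_block_synchrony(p$s1, p$s2, fast_cfg())
  s2 <- dyad_block_synchrony(p$s1, p$s2, fast_cfg())
  expect_identical(s1$scaled, s2$scaled)
  expect_true(all(s1$converged))

  # strong coupling exceeds the null's upper tail in most replicates
  set.seed(10)
  null_vals <- replicate(40, {
    q <- quick_dyad(gain = 0, dur = 45)
    dyad_block_synchrony(q$s1, q$s2, fast_cfg())$average_ccf
  })
  coup_vals <- replicate(25, {
    q <- quick_dyad(gain = 2, dur = 45)
    dyad_block_synchrony(q$s1, q$s2, fast_cfg())$average_ccf
  })
  thr <- quantile(null_vals, 0.95)
  expect_gte(mean(coup_vals > thr), 0.8)
})

test_that("a planted driver delay orients the CCF toward subject 1 leading", {
  set.seed(11)
  # raw tachograms with a broadband driver: its autocorrelation is narrow,
  # so the CCF peak sits exactly at the planted delay
  raw_peaks <- replicate(10, {
    p <- generate_dyad_ibi(coupling_config(
      block_duration_s = 120, coupling_gain = 3, coupling_lag_samples = 3,
      driver_bandwidth_hz = 0.8
    ))
    ccf <- cross_correlation(p$s1, p$s2)
    ccf$lags[which.max(ccf$values)]
  })
  expect_true(all(raw_peaks == 3))
  # after prewhitening the smooth driver's delay survives as an asymmetry:
  # positive-lag group above negative-lag group on average
  asym <- replicate(20, {
    p <- quick_dyad(gain = 3, dur = 120, lag = 4)
    s <- dyad_block_synchrony(p$s1, p$s2, fast_cfg())
    gm <- s$ccf$lag_group_means
    gm$positive - gm$negative
  })
  expect_gt(mean(asym), 0)
})
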