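#' Trim two uniform series to a common time grid
#'
#' Both series must share the sampling rate and have grid points on the same
#' lattice (multiples of `1/rate_hz`, as produced by [resample_ibi()] with
#' `align_grid = TRUE`). Returns both series restricted to the overlapping
#' span.
#'
#' @param a,b [uniform_series()] objects.
#' @return A list with trimmed `a` and `b` of equal length.
#' @export
align_series <- function(a, b) {
  stopifnot(inherits(a, "uniform_series"), inherits(b, "uniform_series"))
  if (abs(a$rate_hz - b$rate_hz) > 1e-9) {
    stop("series must share the sampling rate", call. = FALSE)
  }
  r <- a$rate_hz
  off <- (b$t0_s - a$t0_s) * r
  if (abs(off - round(off)) > 1e-6) {
    stop("series grids are not on a common lattice", call. = FALSE)
  }
  off <- round(off)
  t_start <- max(a$t0_s, b$t0_s)
  t_end <- min(a$t0_s + (length(a$values) - 1) / r,
               b$t0_s + (length(b$values) - 1) / r)
  if (t_end <= t_start) stop("series do not overlap in time", call. = FALSE)
  ia <- round((t_start - a$t0_s) * r) + 1
  ib <- round((t_start - b$t0_s) * r) + 1
  n <- round((t_end - t_start) * r) + 1
  list(
    a = uniform_series(a$values[ia:(ia + n - 1)], r, t_start),
    b = uniform_series(b$values[ib:(ib + n - 1)], r, t_start)
  )
}

#' Lagged cross-correlation between two residual series
#'
#' Computes the cross-correlation function at integer lags `-max_lag ..
#' +max_lag` between subject 1's series and subject 2's series, sliding
#' subject 2 over subject 1: the value at lag `k` is the correlation between
#' `res1(t)` and `res2(t + k)`, so a positive lag means subject 1 leads.
#' Each lag uses the biased (full-length-normalized) estimator: products are
#' summed over the overlap and divided by `n * sd1 * sd2` with means and
#' population SDs computed on the full common series, which bounds every
#' value in `[-1, 1]` and keeps the estimate stable at the largest lags.
#'
#' At the 4 Hz pipeline rate the default `max_lag = 12` spans lags of +/- 3 s
#' and yields the 25-value CCF summarized by [lag_group_means()],
#' [average_ccf()] and [fisher_z()].
#'
#' @param res1,res2 [uniform_series()] (aligned automatically) or plain
#'   numeric vectors of equal length.
#' @param max_lag Maximum lag in samples (default 12).
#' @return An object of class `ccf_result`: `lags`, `values`,
#'   `lag_group_means` (for 25-lag CCFs), `average_ccf`, `fisher_z`, `scaled`
#'   (`100 * fisher_z`, the reporting convention), `n` and `orientation`.
#' @export
cross_correlation <- function(res1, res2, max_lag = 12) {
  if (inherits(res1, "uniform_series") && inherits(res2, "uniform_series")) {
    al <- align_series(res1, res2)
    x <- al$a$values
    y <- al$b$values
  } else {
    x <- as.numeric(res1)
    y <- as.numeric(res2)
    if (length(x) != length(y)) {
      stop("numeric inputs must have equal length", call. = FALSE)
    }
  }
  n <- length(x)
  if (max_lag < 1 || max_lag != round(max_lag)) {
    stop("max_lag must be a positive integer", call. = FALSE)
  }
  if (n < 10 * max_lag) {
    stop("insufficient overlap: need at least 10 * max_lag samples", call. = FALSE)
  }
  sx <- sqrt(mean((x - mean(x))^2))
  sy <- sqrt(mean((y - mean(y))^2))
  if (sx == 0 || sy == 0) stop("zero-variance input", call. = FALSE)
  xc <- (x - mean(x)) / sx
  yc <- (y - mean(y)) / sy

  lags <- (-max_lag):max_lag
  vals <- vapply(lags, function(k) {
    if (k >= 0) {
      sum(xc[1:(n - k)] * yc[(1 + k):n]) / n
    } else {
      sum(xc[(1 - k):n] * yc[1:(n + k)]) / n
    }
  }, numeric(1))
  new_ccf_result(lags, vals, n)
}

new_ccf_result <- function(lags, values, n) {
  avg <- mean(values)
  structure(
    list(
      lags = lags,
      values = values,
      lag_group_means = if (length(lags) == 25) ccf_lag_groups(values) else NULL,
      average_ccf = avg,
      fisher_z = atanh(avg),
      scaled = 100 * atanh(avg),
      n = n,
      orientation = "subject 2 slid over subject 1 (positive lag: subject 1 leads)"
    ),
    class = "ccf_result"
  )
}

#' @export
print.ccf_result <- function(x, ...) {
  cat(sprintf(
    "<ccf_result> %d lags, average CCF %.4f, Fisher Z %.4f (scaled %.2f)\n",
    length(x$lags), x$average_ccf, x$fisher_z, x$scaled
  ))
  invisible(x)
}

# Partition of the 25 lags: negative -12..-5, zero -4..+4, positive +5..+12.
# The three bands hold 8 + 9 + 8 values.
ccf_lag_groups <- function(values) {
  stopifnot(length(values) == 25)
  idx <- function(lags) lags + 13
  list(
    negative = mean(values[idx(-12:-5)]),
    zero = mean(values[idx(-4:4)]),
    positive = mean(values[idx(5:12)])
  )
}

#' Lag-group means of a 25-lag CCF
#'
#' Averages the CCF within three lag bands: "negative" (lags -12..-5),
#' "zero" (-4..+4) and "positive" (+5..+12). This is the unique
#' non-overlapping partition of the 25 lags whose central band spans -4..+4:
#' concurrent synchrony raises the zero band, while leader-follower dynamics
#' would load a side band.
#'
#' @param ccf A [cross_correlation()] result with exactly 25 lags.
#' @return A list with elements `negative`, `zero`, `positive`.
#' @export
lag_group_means <- function(ccf) {
  stopifnot(inherits(ccf, "ccf_result"))
  if (length(ccf$lags) != 25) {
    stop("lag groups are defined for the 25-lag (+/- 12) CCF", call. = FALSE)
  }
  ccf_lag_groups(ccf$values)
}

#' Averaged cross-correlation synchrony index
#'
#' Arithmetic mean of all signed CCF values across lags - one synchrony value
#' per block. Signs are retained so in-phase (positive) and antiphase
#' (negative) co-fluctuation remain distinguishable.
#'
#' @param ccf A [cross_correlation()] result.
#' @return The mean of the CCF values.
#' @export
average_ccf <- function(ccf) {
  stopifnot(inherits(ccf, "ccf_result"))
  mean(ccf$values)
}

#' Fisher Z transformation
#'
#' Variance-stabilizing transform `atanh(r)` applied to the averaged CCF
#' before it enters regression models.
#'
#' @param r A correlation with `|r| < 1`.
#' @return `atanh(r)`.
#' @export
fisher_z <- function(r) {
  assert_scalar(r)
  if (abs(r) >= 1) stop("fisher_z requires |r| < 1", call. = FALSE)
  atanh(r)
}

#' Pipeline configuration for block-level synchrony
#'
#' @param rate_hz Resampling rate in Hz.
#' @param max_lag Maximum CCF lag in samples (12 at 4 Hz = +/- 3 s).
#' @param search An [arima_search()] used to prewhiten both subjects.
#' @param clean Apply [clean_ibi()] before resampling.
#' @return A list of class `synchrony_config`.
#' @export
synchrony_config <- function(rate_hz = 4, max_lag = 12,
                             search = arima_search(), clean = TRUE) {
  structure(
    list(rate_hz = rate_hz, max_lag = max_lag, search = search, clean = clean),
    class = "synchrony_config"
  )
}

#' Block-level physiological synchrony for one dyad
#'
#' End-to-end composition: artifact cleaning, 4 Hz resampling, ARIMA
#' prewhitening of each subject, lagged cross-correlation of the residuals,
#' averaging across lags and Fisher Z transformation.
#'
#' @param ibi1,ibi2 [ibi_series()] for subjects 1 and 2 of the same block, or
#'   already-resampled [uniform_series()].
#' @param cfg A [synchrony_config()].
#' @return A list of class `dyad_synchrony`: `ccf` (full [cross_correlation()]
#'   result), `average_ccf`, `fisher_z`, `scaled`, and `fits` (the two
#'   prewhitening fits, with convergence flags).
#' @export
dyad_block_synchrony <- function(ibi1, ibi2, cfg = synchrony_config()) {
  stopifnot(inherits(cfg, "synchrony_config"))
  prep <- function(obj) {
    if (inherits(obj, "uniform_series")) return(obj)
    stopifnot(inherits(obj, "ibi_series"))
    if (cfg$clean) obj <- clean_ibi(obj)
    resample_ibi(obj, rate_hz = cfg$rate_hz)
  }
  u1 <- prep(ibi1)
  u2 <- prep(ibi2)
  f1 <- fit_auto_arima(u1, cfg$search)
  f2 <- fit_auto_arima(u2, cfg$search)
  ccf <- cross_correlation(f1$residuals, f2$residuals, max_lag = cfg$max_lag)
  structure(
    list(
      ccf = ccf,
      average_ccf = ccf$average_ccf,
      fisher_z = ccf$fisher_z,
      scaled = ccf$scaled,
      fits = list(s1 = f1, s2 = f2),
      converged = c(s1 = f1$converged, s2 = f2$converged)
    ),
    class = "dyad_synchrony"
  )
}

#' @export
print.dyad_synchrony <- function(x, ...) {
  cat(sprintf(
    "<dyad_synchrony> average CCF %.4f, scaled Fisher Z %.3f (converged: %s/%s)\n",
    x$average_ccf, x$scaled, x$converged[1], x$converged[2]
  ))
  invisible(x)
}
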