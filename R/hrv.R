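#' Root mean square of successive differences (rMSSD)
#'
#' Vagally mediated heart-rate-variability index:
#' `sqrt(mean(diff(ibi_ms)^2))`, computed on the cleaned beat-domain IBI
#' series of a block. The 4 Hz resampled series is deliberately not used
#' here, since resampling distorts successive beat-to-beat differences.
#'
#' @param ibi An [ibi_series()] or numeric vector of intervals in ms, with at
#'   least 3 intervals.
#' @return rMSSD in ms.
#' @export
rmssd <- function(ibi) {
  x <- if (inherits(ibi, "ibi_series")) ibi$ibi_ms else as.numeric(ibi)
  assert_finite(x)
  if (length(x) < 3) stop("need at least 3 intervals for rMSSD", call. = FALSE)
  sqrt(mean(diff(x)^2))
}

#' HRV change from the resting baseline
#'
#' Block rMSSD minus baseline rMSSD for the same subject; positive values
#' indicate a task-related HRV increase.
#'
#' @param block_ibi,baseline_ibi [ibi_series()] (or numeric IBI vectors) for
#'   the task block and the resting baseline.
#' @return A list with `rmssd_block_ms`, `rmssd_baseline_ms` and `change_ms`.
#' @export
hrv_change <- function(block_ibi, baseline_ibi) {
  if (missing(baseline_ibi) || is.null(baseline_ibi)) {
    stop("baseline IBI series is required", call. = FALSE)
  }
  rb <- rmssd(block_ibi)
  r0 <- rmssd(baseline_ibi)
  list(rmssd_block_ms = rb, rmssd_baseline_ms = r0, change_ms = rb - r0)
}
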