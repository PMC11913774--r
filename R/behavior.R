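#' Per-trial behavioral synchrony differences
#'
#' Converts a long trials table (one row per dyad, block, trial and subject)
#' into per-trial absolute differences between the two subjects' grasp-contact
#' times and start-button-release times. Smaller values indicate higher
#' behavioral synchrony. Trials lacking one subject's row are skipped with a
#' message.
#'
#' @param trials Data frame with columns `dyad`, `block`, `trial`, `subject`
#'   (1 or 2), `start_time_ms`, `grasp_time_ms`; times must be positive and
#'   each subject's grasp time must not precede their start time.
#' @return Data frame with one row per paired trial: `dyad`, `block`,
#'   `trial`, `grasp_diff_ms`, `start_diff_ms`.
#' @export
trial_differences <- function(trials) {
  need <- c("dyad", "block", "trial", "subject", "start_time_ms", "grasp_time_ms")
  stopifnot(all(need %in% names(trials)))
  if (any(trials$start_time_ms <= 0) || any(trials$grasp_time_ms <= 0)) {
    stop("trial times must be positive", call. = FALSE)
  }
  if (any(trials$grasp_time_ms < trials$start_time_ms)) {
    stop("grasp time must not precede start time", call. = FALSE)
  }
  s1 <- trials[trials$subject == 1, ]
  s2 <- trials[trials$subject == 2, ]
  key <- function(df) paste(df$dyad, df$block, df$trial, sep = ".")
  k1 <- key(s1)
  k2 <- key(s2)
  common <- intersect(k1, k2)
  n_skipped <- (nrow(s1) - length(common)) + (nrow(s2) - length(common))
  if (n_skipped > 0) {
    message(sprintf("skipping %d unpaired trial rows", n_skipped))
  }
  i1 <- match(common, k1)
  i2 <- match(common, k2)
  out <- data.frame(
    dyad = s1$dyad[i1],
    block = s1$block[i1],
    trial = s1$trial[i1],
    grasp_diff_ms = abs(s1$grasp_time_ms[i1] - s2$grasp_time_ms[i2]),
    start_diff_ms = abs(s1$start_time_ms[i1] - s2$start_time_ms[i2])
  )
  out[order(out$dyad, out$block, out$trial), , drop = FALSE]
}

# Logical mask of values inside the Tukey fences.
tukey_keep <- function(values, k = 1.5) {
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  values >= q[1] - k * iqr & values <= q[2] + k * iqr
}

#' Tukey interquartile-range outlier filter
#'
#' Drops values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles
#' computed by linear interpolation. Idempotent in the sense tested here:
#' values retained once are retained again.
#'
#' @param values Numeric vector with at least 4 values.
#' @param k Fence multiplier (1.5 by convention).
#' @return The retained values, in input order.
#' @export
tukey_filter <- function(values, k = 1.5) {
  values <- as.numeric(values)
  assert_finite(values)
  if (length(values) < 4) stop("need at least 4 values", call. = FALSE)
  values[tukey_keep(values, k)]
}

#' Block-level behavioral synchrony summary
#'
#' Averages the retained per-trial absolute differences into one grasp-time
#' and one start-time difference per block. The Tukey filter is applied per
#' measure across the whole trial pool by default (`scope = "study"`),
#' mirroring a single global retained range per measure; `scope = "block"`
#' filters within each block instead, and `scope = "none"` disables
#' filtering.
#'
#' @param diffs A [trial_differences()] table.
#' @param scope Outlier-filter scope: `"study"`, `"block"` or `"none"`.
#' @return Data frame with one row per dyad x block: the two mean
#'   differences and retained-trial counts.
#' @export
block_average <- function(diffs, scope = c("study", "block", "none")) {
  scope <- match.arg(scope)
  need <- c("dyad", "block", "grasp_diff_ms", "start_diff_ms")
  stopifnot(all(need %in% names(diffs)))
  if (nrow(diffs) < 1) stop("no trials to average", call. = FALSE)

  keep <- list(grasp = rep(TRUE, nrow(diffs)), start = rep(TRUE, nrow(diffs)))
  if (scope == "study") {
    keep$grasp <- tukey_keep(diffs$grasp_diff_ms)
    keep$start <- tukey_keep(diffs$start_diff_ms)
  } else if (scope == "block") {
    grp <- paste(diffs$dyad, diffs$block, sep = ".")
    for (g in unique(grp)) {
      i <- grp == g
      if (sum(i) >= 4) {
        keep$grasp[i] <- tukey_keep(diffs$grasp_diff_ms[i])
        keep$start[i] <- tukey_keep(diffs$start_diff_ms[i])
      }
    }
  }

  agg <- function(mask, col) {
    d <- diffs[mask, ]
    if (nrow(d) == 0) stop("no trials retained after filtering", call. = FALSE)
    stats::aggregate(d[[col]], by = list(dyad = d$dyad, block = d$block),
                     FUN = function(v) c(mean = mean(v), n = length(v)))
  }
  g <- agg(keep$grasp, "grasp_diff_ms")
  s <- agg(keep$start, "start_diff_ms")
  out <- merge(
    data.frame(dyad = g$dyad, block = g$block,
               grasp_time_difference_ms = g$x[, "mean"],
               n_trials_grasp = g$x[, "n"]),
    data.frame(dyad = s$dyad, block = s$block,
               start_time_difference_ms = s$x[, "mean"],
               n_trials_start = s$x[, "n"]),
    by = c("dyad", "block"), all = TRUE
  )
  if (any(is.na(out$grasp_time_difference_ms)) || any(is.na(out$start_time_difference_ms))) {
    stop("a block lost all trials to filtering", call. = FALSE)
  }
  out[order(out$dyad, out$block), , drop = FALSE]
}
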