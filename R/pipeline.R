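# Study-level drivers: residual caching, block synchrony, REAL vs PSEUDO,
# HRV and behavioral tables. These compose the per-block operations over a
# `synthetic_study` (or any study stored in the same layout).

# Signal -> 4 Hz uniform series, respecting the study's storage domain.
as_uniform <- function(sig, cfg) {
  if (inherits(sig, "uniform_series")) return(sig)
  stopifnot(inherits(sig, "ibi_series"))
  if (cfg$clean) sig <- clean_ibi(sig)
  resample_ibi(sig, rate_hz = cfg$rate_hz)
}

#' Prewhiten every subject-block series of a study
#'
#' Runs the cleaning/resampling/ARIMA path once per subject and block and
#' caches the residual series, so that real-dyad and pseudo-dyad
#' cross-correlations can reuse identical residuals.
#'
#' @param study A `synthetic_study` (or compatible list with `blocks` and
#'   `signals`).
#' @param cfg A [synchrony_config()].
#' @return A list with `residuals` (named list of [uniform_series()] keyed by
#'   dyad/block/subject) and `fits` (per-series report: selected orders,
#'   lambda, information criteria, residual Ljung-Box p, convergence flag).
#' @export
prewhiten_study <- function(study, cfg = synchrony_config()) {
  stopifnot(inherits(cfg, "synchrony_config"))
  blocks <- study$blocks
  n <- nrow(blocks) * 2L
  residuals <- vector("list", n)
  keys <- character(n)
  rows <- vector("list", n)
  j <- 0L
  for (i in seq_len(nrow(blocks))) {
    for (s in 1:2) {
      j <- j + 1L
      key <- signal_key(blocks$dyad[i], blocks$block[i], s)
      sig <- study$signals[[key]]
      if (is.null(sig)) stop("missing signal for ", key, call. = FALSE)
      fit <- fit_auto_arima(as_uniform(sig, cfg), cfg$search)
      lb <- ljung_box(fit$residuals)
      keys[j] <- key
      residuals[[j]] <- fit$residuals
      sp <- fit$spec
      rows[[j]] <- data.frame(
        dyad = blocks$dyad[i], block = blocks$block[i], subject = s,
        p = sp$p, d = sp$d, q = sp$q, P = sp$P, D = sp$D, Q = sp$Q, m = sp$m,
        lambda = if (is.finite(sp$lambda)) sp$lambda else NA_real_,
        aicc = fit$ic$aicc, aic = fit$ic$aic, bic = fit$ic$bic,
        ljung_box_p = lb$p_value, converged = fit$converged
      )
    }
  }
  names(residuals) <- keys
  list(residuals = residuals, fits = do.call(rbind, rows))
}

#' Block-level synchrony table for a whole study
#'
#' Cross-correlates the two subjects' residuals of every block and returns
#' one row per dyad x block with the averaged-CCF synchrony, its Fisher Z
#' (and x100 scaled value), lag-group means, and the block's condition
#' labels and true coupling gain.
#'
#' @param study A `synthetic_study`.
#' @param prewhitened Optional [prewhiten_study()] result to reuse.
#' @param cfg A [synchrony_config()].
#' @return A data frame; attribute `prewhitened` carries the residual cache.
#' @export
study_synchrony <- function(study, prewhitened = NULL, cfg = synchrony_config()) {
  if (is.null(prewhitened)) prewhitened <- prewhiten_study(study, cfg)
  blocks <- study$blocks
  res <- prewhitened$residuals
  conv <- prewhitened$fits
  rows <- vector("list", nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    k1 <- signal_key(blocks$dyad[i], blocks$block[i], 1)
    k2 <- signal_key(blocks$dyad[i], blocks$block[i], 2)
    ccf <- cross_correlation(res[[k1]], res[[k2]], max_lag = cfg$max_lag)
    gm <- ccf$lag_group_means %||% list(negative = NA_real_, zero = NA_real_,
                                        positive = NA_real_)
    cv <- conv$converged[conv$dyad == blocks$dyad[i] & conv$block == blocks$block[i]]
    rows[[i]] <- data.frame(
      blocks[i, c("dyad", "block", "block_type", "movement", "leader",
                  "occurrence", "cell", "novelty", "coupling_gain")],
      average_ccf = ccf$average_ccf,
      fisher_z = ccf$fisher_z,
      scaled = ccf$scaled,
      lag_negative = gm$negative,
      lag_zero = gm$zero,
      lag_positive = gm$positive,
      n_samples = ccf$n,
      converged1 = cv[1], converged2 = cv[2]
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "prewhitened") <- prewhitened
  out
}

#' Compare REAL against PSEUDO synchrony
#'
#' Builds the participant-shuffling surrogate distribution (reusing the
#' study's residual cache), then runs Welch's unequal-variances t-tests on
#' the unscaled Fisher-Z synchrony values: REAL task vs PSEUDO task, REAL
#' baseline vs PSEUDO baseline, and REAL task vs REAL baseline. Means are
#' additionally reported on the x100 scale used for model coefficients.
#'
#' @param study A `synthetic_study`.
#' @param synchrony A [study_synchrony()] table (with its residual cache
#'   attribute, or supply `prewhitened`).
#' @param prewhitened Optional [prewhiten_study()] result.
#' @param subsample Optional per-cell cap on surrogate pairings.
#' @param seed Seed for the subsample.
#' @param cfg A [synchrony_config()].
#' @return A list of class `real_pseudo_report`: value vectors, Welch test
#'   results and a summary table.
#' @export
real_vs_pseudo <- function(study, synchrony = NULL, prewhitened = NULL,
                           subsample = NULL, seed = NULL,
                           cfg = synchrony_config()) {
  if (is.null(synchrony)) synchrony <- study_synchrony(study, prewhitened, cfg)
  if (is.null(prewhitened)) prewhitened <- attr(synchrony, "prewhitened")
  if (is.null(prewhitened)) stop("prewhitened residuals required", call. = FALSE)

  pairs <- enumerate_pseudo_pairs(study, subsample = subsample, seed = seed)
  pseudo <- pseudo_synchrony_distribution(pairs, prewhitened$residuals,
                                          max_lag = cfg$max_lag)

  is_base_real <- synchrony$block_type == "baseline"
  is_base_pseudo <- pseudo$cell == "baseline"
  real_task <- synchrony$fisher_z[!is_base_real]
  real_base <- synchrony$fisher_z[is_base_real]
  pseudo_task <- pseudo$fisher_z[!is_base_pseudo]
  pseudo_base <- pseudo$fisher_z[is_base_pseudo]

  report <- list(
    real_task = real_task,
    real_baseline = real_base,
    pseudo_task = pseudo_task,
    pseudo_baseline = pseudo_base,
    pseudo_pairings = pseudo,
    welch_task = welch_test(real_task, pseudo_task),
    welch_baseline = if (length(real_base) >= 2 && length(pseudo_base) >= 2) {
      welch_test(real_base, pseudo_base)
    } else NULL,
    welch_task_vs_baseline = if (length(real_base) >= 2) {
      welch_test(real_task, real_base)
    } else NULL
  )
  report$summary <- data.frame(
    group = c("real_task", "real_baseline", "pseudo_task", "pseudo_baseline"),
    n = c(length(real_task), length(real_base),
          length(pseudo_task), length(pseudo_base)),
    mean_fisher_z = c(mean(real_task),
                      if (length(real_base)) mean(real_base) else NA_real_,
                      mean(pseudo_task),
                      if (length(pseudo_base)) mean(pseudo_base) else NA_real_),
    mean_scaled = 100 * c(mean(real_task),
                          if (length(real_base)) mean(real_base) else NA_real_,
                          mean(pseudo_task),
                          if (length(pseudo_base)) mean(pseudo_base) else NA_real_)
  )
  class(report) <- "real_pseudo_report"
  report
}

#' @export
print.real_pseudo_report <- function(x, ...) {
  cat("<real_pseudo_report>\n")
  print(x$summary, row.names = FALSE)
  w <- x$welch_task
  cat(sprintf("task REAL vs PSEUDO: t = %.3f, df = %.1f, p = %.3g\n",
              w$t, w$df, w$p_value))
  invisible(x)
}

#' Per-subject HRV table for a study
#'
#' Computes rMSSD on the beat-domain IBI series of every subject and block
#' and the change from the subject's resting baseline. Studies stored in the
#' 4 Hz uniform domain are converted back to beats first.
#'
#' @param study A `synthetic_study` including a baseline block.
#' @return Data frame: `dyad`, `subject`, `block`, `rmssd_ms`,
#'   `rmssd_baseline_ms`, `hrv_change_ms`.
#' @export
study_hrv <- function(study) {
  blocks <- study$blocks
  if (!any(blocks$block_type == "baseline")) {
    stop("study has no baseline block; HRV change is undefined", call. = FALSE)
  }
  get_beats <- function(key) {
    sig <- study$signals[[key]]
    if (is.null(sig)) stop("missing signal for ", key, call. = FALSE)
    if (inherits(sig, "uniform_series")) uniform_to_beats(sig) else sig
  }
  rows <- list()
  for (d in unique(blocks$dyad)) {
    db <- blocks[blocks$dyad == d, ]
    base_block <- db$block[db$block_type == "baseline"][1]
    for (s in 1:2) {
      r0 <- rmssd(get_beats(signal_key(d, base_block, s)))
      for (b in db$block) {
        rb <- if (b == base_block) r0 else rmssd(get_beats(signal_key(d, b, s)))
        rows[[length(rows) + 1L]] <- data.frame(
          dyad = d, subject = s, block = b,
          rmssd_ms = rb, rmssd_baseline_ms = r0, hrv_change_ms = rb - r0
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Block-level behavioral synchrony table for a study
#'
#' Convenience wrapper: [trial_differences()] then [block_average()].
#'
#' @param study A `synthetic_study`.
#' @param scope Tukey-filter scope, see [block_average()].
#' @return The [block_average()] table.
#' @export
study_behavior <- function(study, scope = "study") {
  block_average(trial_differences(study$trials), scope = scope)
}
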