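#' Generate a synthetic dyadic joint-action study
#'
#' Builds a complete study with known ground truth: per dyad, one
#' non-interactive baseline block plus task blocks in four conditions (block
#' type free vs. leader-follower crossed with movement same vs. opposite),
#' presented as counterbalanced condition runs of `n_blocks_per_condition`
#' blocks with 20 trials each. Each block carries two coupled IBI series
#' drawn by [generate_dyad_ibi()]; the baseline block always has zero
#' coupling. Behavioral trial times share a dyad-level "sloppiness" factor so
#' grasp-time and start-time differences correlate across dyads, and each
#' subject receives questionnaire scores from truncated normal distributions.
#'
#' The per-block coupling gain is
#' `gain_task + gain_novelty_delta * [block is new] + gain_anxiety_slope *
#' z(anxiety sum)` (clamped at zero), which allows planting recoverable
#' novelty and dyad-sum effects. A block is "new" when its block type x
#' movement x leader combination differs from the immediately preceding
#' block's combination, "old" otherwise.
#'
#' @param n_dyads Number of dyads (at least 2).
#' @param n_blocks_per_condition Blocks per condition run (4 in the emulated
#'   design, giving 16 task blocks).
#' @param trials_per_block Trials per task block (20 in the emulated design).
#' @param block_duration_s,baseline_duration_s Block lengths in seconds.
#' @param include_baseline Generate the resting baseline block.
#' @param gain_task Base coupling gain of task blocks.
#' @param gain_novelty_delta Additional gain in novel blocks.
#' @param gain_anxiety_slope Gain change per population SD of the dyad's
#'   social-anxiety sum (negative values plant the "anxious dyads synchronize
#'   less" effect).
#' @param coupling Template [coupling_config()] providing the individual IBI
#'   dynamics (AR coefficient, trend, respiratory component, driver
#'   bandwidth); baselines, gains, durations and seeds are overridden per
#'   block.
#' @param anxiety_mean,anxiety_sd,anxiety_range Social-anxiety score
#'   distribution (defaults: mean 38.2, SD 20.7, range 0-144).
#' @param pt_mean,pt_sd,pt_range Perspective-taking score distribution
#'   (defaults: mean 27.8, SD 3.8, range 7-35).
#' @param signals Generate physiological signals (set `FALSE` for a fast
#'   metadata-only study, e.g. to enumerate surrogate pairings).
#' @param domain `"uniform"` stores 4 Hz tachograms (fast path);
#'   `"beats"` stores beat-domain [ibi_series()] feeding the full
#'   ECG/cleaning path.
#' @param seed Optional integer seed.
#' @return An object of class `synthetic_study` with elements `subjects`,
#'   `blocks` (including the true per-block `coupling_gain`), `trials`,
#'   `signals` (named list keyed by dyad/block/subject), `domain` and
#'   `params`.
#' @export
generate_study <- function(n_dyads,
                           n_blocks_per_condition = 4,
                           trials_per_block = 20,
                           block_duration_s = 300,
                           baseline_duration_s = 240,
                           include_baseline = TRUE,
                           gain_task = 0.25,
                           gain_novelty_delta = 0.05,
                           gain_anxiety_slope = -0.05,
                           coupling = coupling_config(),
                           anxiety_mean = 38.2, anxiety_sd = 20.7,
                           anxiety_range = c(0, 144),
                           pt_mean = 27.8, pt_sd = 3.8, pt_range = c(7, 35),
                           signals = TRUE,
                           domain = c("uniform", "beats"),
                           seed = NULL) {
  if (n_dyads < 2) stop("need at least 2 dyads", call. = FALSE)
  if (n_blocks_per_condition < 1) stop("need at least 1 block per condition", call. = FALSE)
  domain <- match.arg(domain)
  stopifnot(inherits(coupling, "coupling_config"))

  with_seed(seed, {
    conditions <- data.frame(
      block_type = c("free", "free", "leader_follower", "leader_follower"),
      movement = c("same", "opposite", "same", "opposite"),
      stringsAsFactors = FALSE
    )

    ## Subjects ------------------------------------------------------------
    n_sub <- 2L * n_dyads
    subjects <- data.frame(
      dyad = rep(seq_len(n_dyads), each = 2L),
      subject = rep(1:2, n_dyads),
      social_anxiety = rtruncnorm(n_sub, anxiety_mean, anxiety_sd,
                                  anxiety_range[1], anxiety_range[2]),
      perspective_taking = rtruncnorm(n_sub, pt_mean, pt_sd,
                                      pt_range[1], pt_range[2]),
      baseline_ibi_ms = rtruncnorm(n_sub, 850, 70, 650, 1100)
    )

    anx_sum <- tapply(subjects$social_anxiety, subjects$dyad, sum)
    z_anx <- (anx_sum - 2 * anxiety_mean) / (sqrt(2) * anxiety_sd)

    ## Blocks ---------------------------------------------------------------
    blocks_list <- vector("list", n_dyads)
    for (d in seq_len(n_dyads)) {
      run_order <- ((d - 1L + 0:3) %% 4L) + 1L # cyclic counterbalancing
      rows <- list()
      if (include_baseline) {
        rows[[1]] <- data.frame(
          dyad = d, block = 0L, block_type = "baseline", movement = "none",
          leader = "none", occurrence = 1L, cell = "baseline",
          novelty = NA_character_, stringsAsFactors = FALSE
        )
      }
      b <- 0L
      prev_combo <- "baseline"
      for (r in run_order) {
        for (occ in seq_len(n_blocks_per_condition)) {
          b <- b + 1L
          type <- conditions$block_type[r]
          mov <- conditions$movement[r]
          leader <- if (type == "leader_follower") {
            if (occ <= ceiling(n_blocks_per_condition / 2)) "s1" else "s2"
          } else "none"
          combo <- paste(type, mov, leader)
          rows[[length(rows) + 1L]] <- data.frame(
            dyad = d, block = b, block_type = type, movement = mov,
            leader = leader, occurrence = occ,
            cell = paste(type, mov, occ, sep = "."),
            novelty = if (combo == prev_combo) "old" else "new",
            stringsAsFactors = FALSE
          )
          prev_combo <- combo
        }
      }
      blocks_list[[d]] <- do.call(rbind, rows)
    }
    blocks <- do.call(rbind, blocks_list)
    rownames(blocks) <- NULL

    is_base <- blocks$block_type == "baseline"
    gain <- numeric(nrow(blocks))
    gain[!is_base] <- pmax(
      0,
      gain_task +
        gain_novelty_delta * (blocks$novelty[!is_base] == "new") +
        gain_anxiety_slope * z_anx[blocks$dyad[!is_base]]
    )
    blocks$coupling_gain <- gain

    ## Behavioral trials ----------------------------------------------------
    sloppiness <- exp(stats::rnorm(n_dyads, 0, 0.3))
    task_blocks <- blocks[!is_base, ]
    n_task <- nrow(task_blocks)
    tr <- expand.grid(trial = seq_len(trials_per_block),
                      row = seq_len(n_task))
    tb <- task_blocks[tr$row, ]
    nt <- nrow(tr)
    start_base <- stats::rnorm(nt, 350, 40)
    grasp_base <- stats::rnorm(nt, 1200, 80)
    slop <- sloppiness[tb$dyad]
    mk_subject <- function(s) {
      start <- start_base + stats::rnorm(nt, 0, 140 * slop)
      grasp <- grasp_base + stats::rnorm(nt, 0, 95 * slop)
      distracted <- stats::runif(nt) < 0.02
      delay <- stats::runif(nt, 600, 1500) * distracted
      start <- pmax(start + delay, 50)
      grasp <- pmax(grasp + delay, start + 50)
      data.frame(
        dyad = tb$dyad, block = tb$block, trial = tr$trial, subject = s,
        start_time_ms = start, grasp_time_ms = grasp
      )
    }
    trials <- rbind(mk_subject(1L), mk_subject(2L))
    trials <- trials[order(trials$dyad, trials$block, trials$trial, trials$subject), ]
    rownames(trials) <- NULL

    ## Physiological signals -------------------------------------------------
    sig <- list()
    if (signals) {
      for (i in seq_len(nrow(blocks))) {
        bl <- blocks[i, ]
        base_ibis <- subjects$baseline_ibi_ms[subjects$dyad == bl$dyad]
        cfg <- coupling
        cfg$baseline_ibi_ms <- base_ibis
        cfg$coupling_gain <- bl$coupling_gain
        cfg$block_duration_s <- if (is_base[i]) baseline_duration_s else block_duration_s
        cfg$seed <- NULL
        pair <- generate_dyad_ibi(cfg)
        if (domain == "beats") {
          pair$s1 <- uniform_to_beats(pair$s1)
          pair$s2 <- uniform_to_beats(pair$s2)
        }
        sig[[signal_key(bl$dyad, bl$block, 1)]] <- pair$s1
        sig[[signal_key(bl$dyad, bl$block, 2)]] <- pair$s2
      }
    }

    structure(
      list(
        subjects = subjects,
        blocks = blocks,
        trials = trials,
        signals = sig,
        domain = domain,
        params = list(
          n_dyads = n_dyads,
          n_blocks_per_condition = n_blocks_per_condition,
          trials_per_block = trials_per_block,
          block_duration_s = block_duration_s,
          baseline_duration_s = baseline_duration_s,
          include_baseline = include_baseline,
          gain_task = gain_task,
          gain_novelty_delta = gain_novelty_delta,
          gain_anxiety_slope = gain_anxiety_slope,
          coupling = coupling,
          seed = seed
        )
      ),
      class = "synthetic_study"
    )
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d dyads, %d blocks each (%s baseline), %d trial rows, domain: %s\n",
    x$params$n_dyads,
    sum(x$blocks$dyad == x$blocks$dyad[1]),
    if (x$params$include_baseline) "incl." else "no",
    nrow(x$trials), x$domain
  ))
  invisible(x)
}
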