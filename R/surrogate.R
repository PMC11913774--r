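#' Closed-form pseudo-pair count
#'
#' Number of surrogate pairings produced by exhaustive participant shuffling:
#' `(N_b^2 - N_b) / 2 * N_c`, where `N_b` is the number of blocks in the same
#' condition cell across dyads and `N_c` the number of condition cells per
#' dyad. At the emulated study scale (`N_b = 40`, `N_c = 17`: 16 task cells
#' plus baseline) this gives 13,260.
#'
#' @param n_blocks Blocks per condition cell across dyads (`N_b`).
#' @param n_conditions Condition cells per dyad (`N_c`).
#' @return The pair count.
#' @export
pseudo_pair_count <- function(n_blocks, n_conditions) {
  assert_scalar(n_blocks)
  assert_scalar(n_conditions)
  (n_blocks^2 - n_blocks) / 2 * n_conditions
}

#' Enumerate pseudo-dyad pairings by participant shuffling
#'
#' Within every condition cell (block type x movement x ordinal position
#' within the condition, with the baseline forming its own cell), pairs
#' subject 1 of one dyad with subject 2 of a *different* dyad. Only
#' cross-dyad subject1 x subject2 pairings are generated, preserving the
#' table-side asymmetry of the task; no pairing ever joins two members of
#' the same real dyad. Each unordered dyad pair contributes one pairing per
#' cell (subject 1 taken from the lower-numbered dyad), so the exhaustive
#' count matches [pseudo_pair_count()].
#'
#' @param study A `synthetic_study` or a block table with columns `dyad`,
#'   `block`, `cell`.
#' @param subsample Optional per-cell cap: a seeded subsample (without
#'   replacement) of at most this many pairings per condition cell.
#' @param seed Seed for the subsample.
#' @return An object of class `pseudo_dyad_set`: `pairings` (data frame with
#'   `cell`, `dyad_a`, `block_a`, `dyad_b`, `block_b`), `n_pairs`, `n_b`
#'   (dyads per cell), `n_c` (number of cells).
#' @export
enumerate_pseudo_pairs <- function(study, subsample = NULL, seed = NULL) {
  blocks <- if (inherits(study, "synthetic_study")) study$blocks else study
  stopifnot(all(c("dyad", "block", "cell") %in% names(blocks)))

  cells <- split(blocks, blocks$cell)
  pair_list <- lapply(names(cells), function(cl) {
    cb <- cells[[cl]]
    if (anyDuplicated(cb$dyad)) {
      stop("each dyad must contribute exactly one block per condition cell",
           call. = FALSE)
    }
    dy <- sort(cb$dyad)
    if (length(dy) < 2) {
      stop(sprintf("fewer than 2 dyads in condition cell '%s'", cl), call. = FALSE)
    }
    cmb <- utils::combn(dy, 2)
    blk <- cb$block[match(cmb, cb$dyad)]
    dim(blk) <- dim(cmb)
    data.frame(
      cell = cl,
      dyad_a = cmb[1, ], block_a = blk[1, ],
      dyad_b = cmb[2, ], block_b = blk[2, ],
      stringsAsFactors = FALSE
    )
  })

  if (!is.null(subsample)) {
    pair_list <- with_seed(seed, lapply(pair_list, function(df) {
      if (nrow(df) <= subsample) df else df[sort(sample.int(nrow(df), subsample)), ]
    }))
  }
  pairings <- do.call(rbind, pair_list)
  rownames(pairings) <- NULL

  n_b <- vapply(cells, function(cb) length(unique(cb$dyad)), integer(1))
  structure(
    list(
      pairings = pairings,
      n_pairs = nrow(pairings),
      n_b = unname(n_b),
      n_c = length(cells)
    ),
    class = "pseudo_dyad_set"
  )
}

#' @export
print.pseudo_dyad_set <- function(x, ...) {
  cat(sprintf(
    "<pseudo_dyad_set> %d pairings over %d condition cells (%s dyads per cell)\n",
    x$n_pairs, x$n_c, paste(unique(x$n_b), collapse = "/")
  ))
  invisible(x)
}

#' Synchrony distribution over pseudo-dyad pairings
#'
#' Runs the identical cross-correlation, lag-averaging and Fisher Z path on
#' every surrogate pairing, reusing residual series already computed once per
#' subject and block (see [prewhiten_study()]).
#'
#' @param pairs A [enumerate_pseudo_pairs()] result.
#' @param residuals Named list of residual [uniform_series()] keyed as
#'   produced by [prewhiten_study()].
#' @param max_lag Maximum CCF lag in samples.
#' @return The `pairings` data frame with added columns `average_ccf`,
#'   `fisher_z` and `scaled` (100 x Fisher Z).
#' @export
pseudo_synchrony_distribution <- function(pairs, residuals, max_lag = 12) {
  stopifnot(inherits(pairs, "pseudo_dyad_set"))
  pg <- pairs$pairings
  out <- matrix(NA_real_, nrow(pg), 3)
  for (i in seq_len(nrow(pg))) {
    k1 <- signal_key(pg$dyad_a[i], pg$block_a[i], 1)
    k2 <- signal_key(pg$dyad_b[i], pg$block_b[i], 2)
    r1 <- residuals[[k1]]
    r2 <- residuals[[k2]]
    if (is.null(r1) || is.null(r2)) {
      stop(sprintf("missing residual series for pairing %s x %s", k1, k2),
           call. = FALSE)
    }
    ccf <- cross_correlation(r1, r2, max_lag = max_lag)
    out[i, ] <- c(ccf$average_ccf, ccf$fisher_z, ccf$scaled)
  }
  pg$average_ccf <- out[, 1]
  pg$fisher_z <- out[, 2]
  pg$scaled <- out[, 3]
  pg
}

#' Welch's unequal-variances t-test
#'
#' Two-sample mean comparison with the Welch statistic and Satterthwaite
#' degrees of freedom (no equal-variance or equal-n assumption), as used for
#' the REAL versus PSEUDO synchrony comparisons.
#'
#' @param a,b Numeric vectors with at least 2 finite values each.
#' @return A list with `t`, `df`, `p_value`, `ci95` (95\% CI of
#'   `mean(a) - mean(b)`) and the two group means.
#' @export
welch_test <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 finite values", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("zero variance in both groups", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = unname(tt$p.value),
    ci95 = unname(tt$conf.int),
    mean_a = mean(a),
    mean_b = mean(b)
  )
}
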