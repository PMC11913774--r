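# Package-local session state (one-shot notifications).
.dyadsync_state <- new.env(parent = emptyenv())

# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
# seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

assert_finite <- function(x, name = deparse(substitute(x))) {
  if (!all(is.finite(x))) stop(name, " must contain only finite values", call. = FALSE)
  invisible(x)
}

assert_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(name, " must be a finite numeric scalar", call. = FALSE)
  }
  invisible(x)
}

# Truncated-normal draws via inverse CDF; deterministic under the caller's seed.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

# Zero-phase filtering with odd-reflection end padding: extends the signal
# at both ends by its mirrored continuation before forward-backward
# filtering, which suppresses the edge transients of plain filtfilt.
filtfilt_padded <- function(filt, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1L, max(64L, 12L * length(filt$b)))
  if (pad < 1L) return(signal::filtfilt(filt, x))
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(filt, c(head_pad, x, tail_pad))
  y[(pad + 1):(pad + n)]
}

# Key under which a subject-block signal (or its residual) is stored.
signal_key <- function(dyad, block, subject) {
  sprintf("d%03d.b%02d.s%d", as.integer(dyad), as.integer(block), as.integer(subject))
}
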