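#' Box-Cox power transform
#'
#' @param x Positive numeric vector.
#' @param lambda Exponent; `lambda = 0` gives the natural log.
#' @return Transformed vector `(x^lambda - 1) / lambda` (or `log(x)`).
#' @export
box_cox <- function(x, lambda) {
  if (any(x <= 0)) stop("Box-Cox transform requires strictly positive values", call. = FALSE)
  if (abs(lambda) < 1e-4) log(x) else (x^lambda - 1) / lambda
}

#' Select a Box-Cox lambda by coefficient-of-variation minimization
#'
#' Guerrero-style criterion: the series is split into consecutive subseries of
#' length `window`; for each candidate lambda the ratio `sd_i / mean_i^(1 -
#' lambda)` is computed per subseries, and the lambda minimizing the
#' coefficient of variation of these ratios is returned. The search is a
#' deterministic grid over `[lower, upper]`.
#'
#' @param series A [uniform_series()] or positive numeric vector.
#' @param lower,upper Search bounds for lambda (default `[-1, 2]`).
#' @param window Subseries length (default 8 samples).
#' @param step Grid resolution.
#' @return The selected lambda. A constant series returns 1 by convention.
#' @export
boxcox_lambda <- function(series, lower = -1, upper = 2, window = 8, step = 0.01) {
  x <- if (inherits(series, "uniform_series")) series$values else as.numeric(series)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("boxcox_lambda requires strictly positive finite values", call. = FALSE)
  }
  n_sub <- floor(length(x) / window)
  if (n_sub < 2 || stats::sd(x) == 0) return(1)
  m <- matrix(x[seq_len(n_sub * window)], nrow = window)
  mu <- colMeans(m)
  sig <- apply(m, 2, stats::sd)
  if (any(sig == 0)) return(1)
  lambdas <- seq(lower, upper, by = step)
  cv <- vapply(lambdas, function(l) {
    r <- sig / mu^(1 - l)
    stats::sd(r) / abs(mean(r))
  }, numeric(1))
  lambdas[which.min(cv)]
}

#' ARIMA search settings
#'
#' Settings for the exhaustive (non-stepwise) ARIMA order search used for
#' prewhitening. The non-seasonal differencing order is fixed at `d = 1`;
#' with a seasonal period `m > 1` the seasonal differencing order is fixed at
#' `D = 1` and seasonal orders up to `P_max`/`Q_max` are searched. With the
#' default `m = 1` the seasonal part collapses and only `(p, 1, q)` models are
#' tried. The period of the seasonal component is a required modelling choice:
#' no default period is invented.
#'
#' @param p_max,q_max Maximum non-seasonal AR / MA orders.
#' @param P_max,Q_max Maximum seasonal AR / MA orders (used when `m > 1`).
#' @param m Seasonal period in samples; `m = 1` disables the seasonal part.
#' @param lambda `"auto"` (Guerrero CV criterion), `"none"`, or a numeric
#'   lambda for the Box-Cox pre-transform.
#' @param method Estimation method passed to [stats::arima()]; `"CSS-ML"`
#'   (conditional-sum-of-squares initialized maximum likelihood) by default,
#'   `"ML"` for full maximum likelihood.
#' @return A list of class `arima_search`.
#' @export
arima_search <- function(p_max = 5, q_max = 5, P_max = 2, Q_max = 2, m = 1,
                         lambda = "auto", method = c("CSS-ML", "ML")) {
  method <- match.arg(method)
  stopifnot(p_max >= 0, q_max >= 0, P_max >= 0, Q_max >= 0, m >= 1)
  structure(
    list(p_max = p_max, q_max = q_max, P_max = P_max, Q_max = Q_max,
         m = as.integer(m), lambda = lambda, method = method,
         m_explicit = !missing(m)),
    class = "arima_search"
  )
}

# Information criteria for a stats::arima fit. k counts estimated
# coefficients plus the innovation variance.
arima_ic <- function(fit) {
  k <- length(fit$coef) + 1
  n <- fit$nobs
  aic <- fit$aic
  list(
    aic = aic,
    aicc = if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf,
    bic = aic + k * (log(n) - 2)
  )
}

#' Prewhiten a series by exhaustive ARIMA model selection
#'
#' Fits every candidate `ARIMA(p, 1, q)` (and, for `m > 1`,
#' `(p, 1, q)(P, 1, Q)_m`) model by maximum likelihood on the Box-Cox
#' transformed series and keeps the one minimizing AICc (AIC and BIC are
#' reported alongside). Ties are broken by fewer parameters, then lower MA
#' order. Candidates that fail to converge are skipped; if no candidate
#' converges the differenced series is returned as a flagged fallback. The
#' residuals (innovations) are returned on the transformed scale, since only
#' their cross-correlation is consumed downstream.
#'
#' @param series A [uniform_series()] with at least 60 samples.
#' @param search An [arima_search()] configuration.
#' @return An object of class `arima_prewhiten` with elements `spec` (orders,
#'   period and lambda), `ic` (aicc/aic/bic), `coefficients`, `residuals` (a
#'   [uniform_series()]) and `converged`.
#' @export
fit_auto_arima <- function(series, search = arima_search()) {
  stopifnot(inherits(series, "uniform_series"), inherits(search, "arima_search"))
  x <- series$values
  if (length(x) < 60) stop("series must have at least 60 samples", call. = FALSE)

  lambda <- search$lambda
  if (identical(lambda, "auto")) {
    lambda <- if (all(x > 0)) boxcox_lambda(x) else NA_real_
  } else if (identical(lambda, "none")) {
    lambda <- NA_real_
  }
  xt <- if (is.finite(lambda)) box_cox(x, lambda) else x

  seasonal <- search$m > 1
  if (!seasonal && (search$P_max > 0 || search$Q_max > 0) && !search$m_explicit &&
      !isTRUE(.dyadsync_state$seasonal_notified)) {
    message("seasonal period m not specified; seasonal terms and D = 1 disabled ",
            "(notified once per session)")
    .dyadsync_state$seasonal_notified <- TRUE
  }
  grid <- expand.grid(
    p = 0:search$p_max, q = 0:search$q_max,
    P = if (seasonal) 0:search$P_max else 0L,
    Q = if (seasonal) 0:search$Q_max else 0L
  )

  best <- NULL
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    fit <- tryCatch(
      suppressWarnings(stats::arima(
        xt, order = c(g$p, 1, g$q),
        seasonal = list(
          order = c(g$P, if (seasonal) 1 else 0, g$Q),
          period = search$m
        ),
        method = search$method,
        optim.control = list(maxit = 300)
      )),
      error = function(e) NULL
    )
    if (is.null(fit) || fit$code != 0 || !is.finite(fit$aic)) next
    ic <- arima_ic(fit)
    cand <- list(fit = fit, ic = ic, spec = g, npar = length(fit$coef))
    if (is.null(best) ||
        ic$aicc < best$ic$aicc - 1e-9 ||
        (abs(ic$aicc - best$ic$aicc) <= 1e-9 &&
         (cand$npar < best$npar ||
          (cand$npar == best$npar && g$q < best$spec$q)))) {
      best <- cand
    }
  }

  if (is.null(best)) {
    res <- diff(xt)
    if (seasonal) res <- diff(res, lag = search$m)
    return(structure(
      list(
        spec = list(p = 0L, d = 1L, q = 0L, P = 0L, D = as.integer(seasonal),
                    Q = 0L, m = search$m, lambda = lambda),
        ic = list(aicc = NA_real_, aic = NA_real_, bic = NA_real_),
        coefficients = numeric(0),
        residuals = uniform_series(res - mean(res), series$rate_hz,
                                   series$t0_s + (1 + seasonal * search$m) / series$rate_hz),
        converged = FALSE
      ),
      class = "arima_prewhiten"
    ))
  }

  structure(
    list(
      spec = list(
        p = best$spec$p, d = 1L, q = best$spec$q,
        P = best$spec$P, D = as.integer(seasonal), Q = best$spec$Q,
        m = search$m, lambda = lambda
      ),
      ic = best$ic,
      coefficients = best$fit$coef,
      residuals = uniform_series(as.numeric(best$fit$residuals),
                                 series$rate_hz, series$t0_s),
      converged = TRUE
    ),
    class = "arima_prewhiten"
  )
}

#' @export
print.arima_prewhiten <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<arima_prewhiten> ARIMA(%d,%d,%d)(%d,%d,%d)[%d], lambda %s, AICc %s, converged: %s\n",
    s$p, s$d, s$q, s$P, s$D, s$Q, s$m,
    if (is.finite(s$lambda)) sprintf("%.2f", s$lambda) else "none",
    if (is.finite(x$ic$aicc)) sprintf("%.1f", x$ic$aicc) else "NA",
    x$converged
  ))
  invisible(x)
}

#' Ljung-Box whiteness test
#'
#' Portmanteau test on the first `n_lags` sample autocorrelations, with the
#' p-value taken from a chi-square distribution with `n_lags` degrees of
#' freedom. Used to verify that prewhitening residuals carry no remaining
#' serial structure.
#'
#' @param series A [uniform_series()] or numeric vector longer than
#'   `n_lags + 1`.
#' @param n_lags Number of autocorrelation lags tested (default 20).
#' @return A list with `statistic` and `p_value`.
#' @export
ljung_box <- function(series, n_lags = 20) {
  x <- if (inherits(series, "uniform_series")) series$values else as.numeric(series)
  if (length(x) <= n_lags + 1) {
    stop("series too short for the requested number of lags", call. = FALSE)
  }
  bt <- stats::Box.test(x, lag = n_lags, type = "Ljung-Box")
  list(statistic = unname(bt$statistic), p_value = unname(bt$p.value))
}
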