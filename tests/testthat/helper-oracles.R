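# Independent brute-force oracles used to cross-check the implementation.

# Double-loop lagged cross-correlation with full-series means and population
# SDs (the biased estimator), written as plainly as possible.
naive_ccf <- function(x, y, max_lag) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sx <- sqrt(sum((x - mx)^2) / n)
  sy <- sqrt(sum((y - my)^2) / n)
  out <- numeric(2 * max_lag + 1)
  for (k in -max_lag:max_lag) {
    acc <- 0
    for (t in seq_len(n)) {
      u <- t + k
      if (u >= 1 && u <= n) acc <- acc + (x[t] - mx) * (y[u] - my)
    }
    out[k + max_lag + 1] <- acc / (n * sx * sy)
  }
  out
}

# Step-up Benjamini-Hochberg adjustment written from the definition.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running_min <- 1
  for (i in m:1) {
    running_min <- min(running_min, p[ord[i]] * m / i)
    adj[ord[i]] <- running_min
  }
  adj
}

# Welch t statistic and Satterthwaite df from the textbook formulas.
welch_hand <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  c(t = t, df = df)
}

# rMSSD by explicit loop.
rmssd_loop <- function(x) {
  acc <- 0
  for (i in 2:length(x)) acc <- acc + (x[i] - x[i - 1])^2
  sqrt(acc / (length(x) - 1))
}
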