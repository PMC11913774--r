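# Builds a design table directly (no signals needed) for estimator-level
# simulations: outcome constructed from known coefficients.
make_design <- function(n_dyads, n_blocks, b_sum = 0, b_absdiff = 0,
                        dyad_sd = 0.3, resid_sd = 1) {
  s1 <- rnorm(n_dyads, 0, 1)
  s2 <- rnorm(n_dyads, 0, 1)
  d <- expand.grid(block = seq_len(n_blocks), dyad = seq_len(n_dyads))
  sum_x <- (s1 + s2)[d$dyad]
  absdiff_x <- abs(s1 - s2)[d$dyad]
  d$sum_x <- as.numeric(scale(sum_x))
  d$absdiff_x <- as.numeric(scale(absdiff_x))
  u <- rnorm(n_dyads, 0, dyad_sd)
  d$y <- b_sum * d$sum_x + b_absdiff * d$absdiff_x + u[d$dyad] +
    rnorm(nrow(d), 0, resid_sd)
  d
}

test_that("fdr_adjust equals the step-up rule and its hand example", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(0.04, 5)), rep(0.04, 5))
  set.seed(1)
  for (i in 1:10) {
    p <- runif(sample(3:20, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, bh_bruteforce(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
  }
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("the dyad design carries exact SUM/ABSDIFF and standardized predictors", {
  st <- generate_study(10, block_duration_s = 30, baseline_duration_s = 30,
                       signals = FALSE, seed = 2)
  # synthesize a synchrony table without signals
  task <- st$blocks
  syn <- data.frame(task, average_ccf = 0, fisher_z = 0,
                    scaled = rnorm(nrow(task)), lag_negative = 0, lag_zero = 0,
                    lag_positive = 0, n_samples = 100,
                    converged1 = TRUE, converged2 = TRUE)
  des <- build_dyad_design(st, syn)
  expect_equal(nrow(des), 10 * 16)

  s1 <- st$subjects[st$subjects$subject == 1, ]
  s2 <- st$subjects[st$subjects$subject == 2, ]
  i <- match(des$dyad, s1$dyad)
  expect_equal(des$sum_social_anxiety_raw,
               s1$social_anxiety[i] + s2$social_anxiety[i])
  expect_equal(des$absdiff_social_anxiety_raw,
               abs(s1$social_anxiety[i] - s2$social_anxiety[i]))
  for (v in c("sum_social_anxiety", "absdiff_social_anxiety",
              "sum_perspective_taking")) {
    expect_lt(abs(mean(des[[v]])), 1e-9)
    expect_equal(sd(des[[v]]), 1, tolerance = 1e-9)
  }
  # novelty coding: old = 1, new = 0
  expect_equal(des$novelty_old, as.numeric(des$novelty == "old"))
})

test_that("fit_mixed_model recovers a known coefficient and flags unknowns", {
  set.seed(3)
  d <- make_design(60, 10, b_sum = 2)
  rep_ <- fit_mixed_model(d, "y ~ sum_x + (1 | dyad)", compare_null = TRUE)
  est <- rep_$coefficients$estimate[rep_$coefficients$term == "sum_x"]
  expect_lt(abs(est - 2) / 2, 0.1)
  expect_true(rep_$null_comparison$p_value < 1e-6)
  expect_true(all(rep_$coefficients$p_fdr >= rep_$coefficients$p_value - 1e-12))
  expect_true(all(rep_$coefficients$ci_lower <= rep_$coefficients$estimate &
                  rep_$coefficients$estimate <= rep_$coefficients$ci_upper))
  expect_error(fit_mixed_model(d, "y ~ nope + (1 | dyad)"), "unknown predictor")
})

test_that("fixed-effect p-values are calibrated under the null", {
  set.seed(4)
  rej <- vapply(1:400, function(i) {
    d <- make_design(15, 6)
    r <- fit_mixed_model(d, "y ~ sum_x + (1 | dyad)", compare_null = FALSE)
    r$coefficients$p_value[r$coefficients$term == "sum_x"] < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("random slopes fall back down the ladder instead of failing", {
  set.seed(5)
  d <- make_design(12, 4, b_sum = 1)
  d$z <- rnorm(nrow(d))
  rep_ <- fit_mixed_model(d, "y ~ sum_x + (1 + z | dyad)", compare_null = FALSE)
  expect_s3_class(rep_, "model_report")
  expect_true(any(rep_$coefficients$term == "sum_x"))
})

test_that("saturated model trims when only SUM effects are real", {
  set.seed(6)
  trims <- vapply(1:15, function(i) {
    d <- make_design(30, 8, b_sum = 0.8, b_absdiff = 0)
    d$block_type <- factor(rep(c("free", "leader_follower"), length.out = nrow(d)))
    f <- saturated_then_trim(d, outcome = "y", between = "block_type",
                             within = "x", random = "(1 | dyad)",
                             compare_null = FALSE)
    f$trimmed
  }, logical(1))
  expect_gte(mean(trims), 0.9)
})

test_that("a real ABSDIFF effect keeps the saturated model", {
  set.seed(7)
  kept <- vapply(1:15, function(i) {
    d <- make_design(30, 8, b_sum = 0.5, b_absdiff = 1)
    d$block_type <- factor(rep(c("free", "leader_follower"), length.out = nrow(d)))
    f <- saturated_then_trim(d, outcome = "y", between = "block_type",
                             within = "x", random = "(1 | dyad)",
                             compare_null = FALSE)
    !f$trimmed
  }, logical(1))
  expect_gte(mean(kept), 0.9)
})

test_that("lag_group_contrast reshapes to one row per block and group", {
  st <- quick_study(n_dyads = 4, gain = 2, seed = 8)
  syn <- study_synchrony(st, cfg = fast_cfg())
  lg <- lag_group_contrast(syn)
  expect_equal(nrow(lg), nrow(syn) * 3)
  expect_setequal(levels(lg$lag_group), c("negative", "zero", "positive"))
  # zero-lag planted coupling loads the zero group
  agg <- tapply(lg$mean_ccf, lg$lag_group, mean)
  expect_gt(agg["zero"], agg["negative"])
  expect_gt(agg["zero"], agg["positive"])
})

test_that("planted novelty effects propagate into the fitted design", {
  set.seed(9)
  st <- generate_study(12, n_blocks_per_condition = 4, block_duration_s = 45,
                       include_baseline = FALSE, gain_task = 0.6,
                       gain_novelty_delta = 0.6, gain_anxiety_slope = 0,
                       coupling = coupling_config(block_duration_s = 45),
                       seed = 10)
  syn <- study_synchrony(st, cfg = fast_cfg())
  des <- build_dyad_design(st, syn)
  rep_ <- fit_mixed_model(des,
    "synchrony_scaled ~ novelty_old + block_type + (1 | dyad)",
    compare_null = FALSE)
  est <- rep_$coefficients$estimate[rep_$coefficients$term == "novelty_old"]
  expect_lt(est, 0) # old blocks are less synchronous under the plant
})
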