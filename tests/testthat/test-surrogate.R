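test_that("pseudo-pair closed form reproduces known counts", {
  expect_equal(pseudo_pair_count(40, 17), 13260)
  expect_equal(pseudo_pair_count(2, 1), 1)
  expect_equal(pseudo_pair_count(3, 2), 6)
})

test_that("enumeration matches the closed form and a brute-force oracle", {
  st <- generate_study(3, n_blocks_per_condition = 2, signals = FALSE, seed = 1)
  ps <- enumerate_pseudo_pairs(st)
  n_cells <- length(unique(st$blocks$cell))
  expect_equal(ps$n_pairs, pseudo_pair_count(3, n_cells))

  # brute force: all cross-dyad ordered-by-id pairs per cell
  brute <- 0
  for (cl in unique(st$blocks$cell)) {
    d <- unique(st$blocks$dyad[st$blocks$cell == cl])
    for (i in d) for (j in d) if (i < j) brute <- brute + 1
  }
  expect_equal(ps$n_pairs, brute)
})

test_that("no pairing joins members of the same dyad and cells are matched", {
  st <- generate_study(5, n_blocks_per_condition = 1, signals = FALSE, seed = 2)
  ps <- enumerate_pseudo_pairs(st)
  expect_true(all(ps$pairings$dyad_a != ps$pairings$dyad_b))
  # both blocks of a pairing belong to the pairing's condition cell
  key <- paste(st$blocks$dyad, st$blocks$block)
  cell_of <- st$blocks$cell[match(paste(ps$pairings$dyad_a, ps$pairings$block_a), key)]
  expect_equal(cell_of, ps$pairings$cell)
})

test_that("subsampling never repeats a pairing and respects the cap", {
  st <- generate_study(8, n_blocks_per_condition = 1, signals = FALSE, seed = 3)
  ps <- enumerate_pseudo_pairs(st, subsample = 10, seed = 4)
  expect_equal(ps$n_pairs, 10 * length(unique(st$blocks$cell)))
  id <- with(ps$pairings, paste(cell, dyad_a, dyad_b))
  expect_false(anyDuplicated(id) > 0)
  # deterministic under the seed
  ps2 <- enumerate_pseudo_pairs(st, subsample = 10, seed = 4)
  expect_identical(ps$pairings, ps2$pairings)
})

test_that("enumeration fails with fewer than two dyads in a cell", {
  st <- generate_study(2, n_blocks_per_condition = 1, signals = FALSE, seed = 5)
  blocks <- st$blocks[!(st$blocks$dyad == 2 & st$blocks$cell == st$blocks$cell[2]), ]
  expect_error(enumerate_pseudo_pairs(blocks), "fewer than 2 dyads")
})

test_that("pseudo synchrony runs the identical path as real synchrony", {
  st <- quick_study(n_dyads = 4, gain = 0, seed = 6)
  pw <- prewhiten_study(st, fast_cfg())
  ps <- enumerate_pseudo_pairs(st)
  vals <- pseudo_synchrony_distribution(ps, pw$residuals)
  # recompute one pairing by hand from the cached residuals
  row <- vals[3, ]
  ccf <- cross_correlation(
    pw$residuals[[signal_key(row$dyad_a, row$block_a, 1)]],
    pw$residuals[[signal_key(row$dyad_b, row$block_b, 2)]]
  )
  expect_equal(row$average_ccf, ccf$average_ccf)
  expect_equal(row$scaled, 100 * atanh(row$average_ccf))
  # uncoupled: distribution centred on zero
  se <- sd(vals$fisher_z) / sqrt(nrow(vals))
  expect_lt(abs(mean(vals$fisher_z)), 3 * se)
})

test_that("missing residuals are reported with the offending key", {
  st <- quick_study(n_dyads = 3, seed = 7)
  pw <- prewhiten_study(st, fast_cfg())
  ps <- enumerate_pseudo_pairs(st)
  res <- pw$residuals
  res[[signal_key(1, 1, 1)]] <- NULL
  expect_error(pseudo_synchrony_distribution(ps, res), "missing residual")
})

test_that("welch_test matches the hand-computed Welch formulas", {
  out <- welch_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$t, -3.674, tolerance = 1e-3)
  expect_equal(out$df, 4.0, tolerance = 1e-9)
  oracle <- welch_hand(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$t, unname(oracle["t"]), tolerance = 1e-12)
  expect_equal(out$df, unname(oracle["df"]), tolerance = 1e-12)

  set.seed(8)
  a <- rnorm(20)
  b <- rnorm(35, 0.5, 2)
  out2 <- welch_test(a, b)
  oracle2 <- welch_hand(a, b)
  expect_equal(out2$t, unname(oracle2["t"]), tolerance = 1e-12)
  expect_equal(out2$df, unname(oracle2["df"]), tolerance = 1e-12)
})

test_that("welch_test edge cases behave as expected", {
  same <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  set.seed(9)
  a <- rnorm(50)
  expect_lt(welch_test(a, a + 10)$p_value, 1e-10)
  expect_error(welch_test(1, c(1, 2)), "at least 2")
  expect_error(welch_test(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("the pseudo distribution is invariant to dyad relabelling", {
  st <- quick_study(n_dyads = 4, gain = 0, seed = 10)
  pw <- prewhiten_study(st, fast_cfg())
  vals1 <- sort(pseudo_synchrony_distribution(enumerate_pseudo_pairs(st),
                                              pw$residuals)$fisher_z)
  # relabel dyads by a permutation: same residuals under new names
  perm <- c(3, 1, 4, 2)
  st2 <- st
  st2$blocks$dyad <- perm[st$blocks$dyad]
  res2 <- pw$residuals
  names(res2) <- vapply(names(res2), function(k) {
    d <- as.integer(sub("^d([0-9]+).*", "\\1", k))
    sub("^d[0-9]+", sprintf("d%03d", perm[d]), k)
  }, character(1))
  vals2 <- sort(pseudo_synchrony_distribution(enumerate_pseudo_pairs(st2$blocks),
                                              res2)$fisher_z)
  # relabelling may swap which member plays subject 1 in a pairing, so the
  # concrete values can differ; the distributions must not
  expect_equal(length(vals1), length(vals2))
  ks <- suppressWarnings(stats::ks.test(vals1, vals2))
  expect_gt(ks$p.value, 0.01)
})
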