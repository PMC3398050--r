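test_that("harvest response curves reproduce their printed coefficients", {
  expect_equal(shade_from_gli(0), 3.6802)
  expect_equal(shade_from_gli(100), 2.3602)
  expect_true(all(diff(shade_from_gli(seq(0, 100, 10))) < 0))
  expect_error(shade_from_gli(101), "0, 100")

  expect_equal(substrate_from_pcba(0), 0.1193)
  expect_equal(substrate_from_pcba(1), 0.3009)
  expect_true(all(diff(substrate_from_pcba(seq(0, 1, 0.1))) > 0))

  expect_equal(dwd_from_cut(0), 2.2035)
  expect_equal(dwd_from_cut(1), 0.3699)
  expect_true(all(diff(dwd_from_cut(seq(0, 1, 0.1))) < 0))

  expect_equal(shrub_scenario(0.2, 1.5, "suppressed"), 1.5)
  expect_equal(shrub_scenario(0.8, 1.5, "suppressed"), 0.6)
  expect_equal(shrub_scenario(0.5, 1.5, "suppressed"), 0.7 * 1.5)
  expect_equal(shrub_scenario(0.9, 1.5, "normal"), 1.5)
})

test_that("harvest patterns hit the requested intensity", {
  u <- apply_harvest_pattern(harvest_scenario(0.5, "uniform"))
  expect_true(all(u == 0.5))
  expect_equal(dim(u), c(14, 14))
  z <- apply_harvest_pattern(harvest_scenario(0))
  expect_true(all(z == 0))
  for (pat in c("small_patch", "large_patch")) {
    for (int in c(0.3, 0.9)) {
      pc <- apply_harvest_pattern(harvest_scenario(int, pat, seed = 4))
      expect_true(all(pc >= 0 & pc <= 1))
      expect_gte(mean(pc), int - 0.02)
      expect_lte(mean(pc), int + 0.02)
    }
  }
})

test_that("large patches aggregate the cut more than small patches", {
  vars <- vapply(1:15, function(r) {
    vapply(c("small_patch", "large_patch"), function(pat)
      var(as.vector(apply_harvest_pattern(
        harvest_scenario(0.5, pat, seed = 100 + r)))), numeric(1))
  }, numeric(2))
  expect_gt(mean(vars["large_patch", ]), mean(vars["small_patch", ]))
  # strictly larger on average and in most replicates
  expect_gte(mean(vars["large_patch", ] > vars["small_patch", ]), 0.9)
})

test_that("synthetic gap light tracks the local cut", {
  pc0 <- matrix(0, 14, 14)
  expect_true(all(synthetic_gli(pc0) == 10))
  expect_true(all(synthetic_gli(pc0 + 1) == 95))
  pc <- matrix(0, 14, 14); pc[7, 7] <- 1
  g <- synthetic_gli(pc)
  expect_gt(g[7, 7], g[1, 1])
})

test_that("autocorrelated scatter keeps the marginal and adds spatial structure", {
  base <- matrix(2, 14, 14)
  expect_identical(autocorrelated_lognormal_scatter(base, 0), base)

  out <- autocorrelated_lognormal_scatter(base, cv = 0.5, seed = 6)
  dev <- as.vector(out / base)
  expect_equal(sd(dev) / mean(dev), 0.5, tolerance = 0.1)

  # rank matching must raise Moran's I relative to unarranged noise
  d <- hrscape:::torus_distance_matrix(14, 14) * 15
  w <- 1 / d; diag(w) <- 0
  hits <- 0
  for (r in 1:50) {
    arranged <- hrscape:::as_rowmajor(
      autocorrelated_lognormal_scatter(base, cv = 0.5, seed = 1000 + r))
    shuffled <- hrscape:::with_seed(2000 + r, sample(arranged))
    i_arr <- ape::Moran.I(arranged, w)$observed
    i_shf <- ape::Moran.I(shuffled, w)$observed
    if (i_arr > i_shf) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.9)
})

test_that("scenario runs are reproducible and summarise their replicates", {
  sc <- harvest_scenario(0.5, "small_patch", "suppressed", seed = 3)
  r1 <- run_scenario(sc, replicates = 2, seed = 5)
  r2 <- run_scenario(sc, replicates = 2, seed = 5)
  expect_identical(r1$replicates, r2$replicates)
  expect_equal(r1$summary[["mean_value"]], mean(r1$replicates$mean_value))
  expect_equal(r1$summary[["abundance_hr"]], mean(r1$replicates$abundance_hr))
  expect_true(all(r1$replicates$mean_value >= 0))
})

test_that("habitat value and abundance decline with harvest intensity", {
  res <- lapply(c(0, 0.5, 0.9), function(int)
    run_scenario(harvest_scenario(int, "uniform", "suppressed", seed = 2),
                 replicates = 3, seed = 1))
  v <- vapply(res, function(r) r$summary[["mean_value"]], numeric(1))
  a <- vapply(res, function(r) r$summary[["abundance_hr"]], numeric(1))
  expect_true(all(diff(v) < 0))
  expect_true(all(diff(a) <= 0))
})
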