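test_that("benefit, cost, and net value follow their closed forms", {
  g4 <- uniform_grid(1, 4, 4)
  cells <- rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2))

  # hand-arithmetic oracle: 4 cells of V = 1, each shared with one other
  # range -> S = 4 * 1/2 = 2
  ov <- matrix(1L, 4, 4)
  expect_equal(hr_benefit(cells, g4, ov, params_fitted, form = "hyperbolic"),
               8.108 * 2 / 2.222)
  expect_equal(hr_benefit(cells, g4, ov, params_fitted),
               8.108 * (1 - exp(-0.222 * 2)))

  # zero habitat forces zero benefit; large S approaches the p1 asymptote
  g0 <- uniform_grid(0, 4, 4)
  expect_equal(hr_benefit(cells, g0, NULL, params_fitted), 0)
  ghuge <- uniform_grid(25, 4, 4)
  for (form in c("exponential", "hyperbolic")) {
    b <- hr_benefit(cells, ghuge, NULL, params_fitted, form = form)
    expect_lt(b, 8.108)
    expect_gt(b, 8.108 - 0.05)
  }

  expect_equal(hr_cost(4, params_fitted), 4.150 + 2)
  expect_equal(hr_cost(9, hr_params(1, 1, 1e-12)), 3, tolerance = 1e-9)
  expect_equal(hr_cost(7, params_fitted), 4.150 + sqrt(7))
  expect_error(hr_cost(0, params_fitted), ">= 1")

  # net value: zero habitat with positive fixed costs is never viable
  expect_lt(hr_net_value(cells, g0, NULL, params_fitted), 0)
  # bound from the asymptote for any 4-cell range
  expect_lt(hr_net_value(cells, ghuge, NULL, params_fitted),
            8.108 - 4.150 - 2)
  expect_error(hr_benefit(cells, g4, matrix(-1, 4, 4), params_fitted),
               "non-negative")
})

test_that("benefit is monotone in cell values and overlap counts", {
  set.seed(17)
  cells <- rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
  for (i in 1:20) {
    v <- matrix(runif(16, 0, 3), 4, 4)
    ov <- matrix(sample(0:3, 16, replace = TRUE), 4, 4)
    b0 <- hr_benefit(cells, value_grid(v), ov, params_fitted)
    v2 <- v; v2[1, 1] <- v2[1, 1] + 1
    expect_gte(hr_benefit(cells, value_grid(v2), ov, params_fitted), b0)
    ov2 <- ov; ov2[1, 2] <- ov2[1, 2] + 2
    expect_lte(hr_benefit(cells, value_grid(v), ov2, params_fitted), b0)
    expect_gte(b0, 0)
    expect_lt(b0, params_fitted[["p1"]])
  }
})

test_that("greedy optimization finds the uniform-grid optimal area", {
  # on a uniform grid net value depends only on area; the greedy local
  # optimum must match a 1-D scan over area
  for (v in c(1.3, 1.64, 2.1)) {
    g <- uniform_grid(v, 7, 7)
    hr <- optimize_home_range(rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2)),
                              g, NULL, params_fitted)
    areas <- 4:49
    best_area <- areas[which.max(uniform_nv(areas, v, params_fitted))]
    expect_equal(nrow(hr$cells), best_area)
    expect_equal(hr$net_value, uniform_nv(best_area, v, params_fitted))
  }
})

test_that("greedy optimization contracts to the minimum on barren ground", {
  g <- uniform_grid(0, 5, 5)
  start <- rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2), c(3, 1), c(1, 3))
  hr <- optimize_home_range(start, g, NULL, params_fitted)
  expect_equal(nrow(hr$cells), 4)
  expect_lt(hr$net_value, 0)
})

test_that("establishment recovers an isolated high-value block", {
  m <- matrix(0, 4, 4)
  m[2:3, 2:3] <- 10
  g <- value_grid(m)
  sol <- establish_population(g, params_fitted, seed = 1, max_ranges = 1)
  hr <- sol$home_ranges[[1]]
  expect_equal(hr$cells[order(hr$cells[, 1], hr$cells[, 2]), ],
               rbind(c(2, 2), c(2, 3), c(3, 2), c(3, 3)),
               ignore_attr = TRUE)
  # exhaustive oracle agrees
  bf <- brute_force_best_home_range(g, NULL, params_fitted, max_area = 6)
  expect_equal(sort(bf$cells[, 1] * 10 + bf$cells[, 2]),
               sort(hr$cells[, 1] * 10 + hr$cells[, 2]))
})

test_that("exhaustive enumeration counts connected sets correctly", {
  g <- uniform_grid(1, 3, 3)
  bf <- brute_force_best_home_range(g, NULL, params_fitted, max_area = 4)
  # independent oracle: all 4-subsets of the 9 cells, filtered by an
  # R-side toroidal connectivity check
  combos <- combn(9, 4)
  n_connected <- sum(apply(combos, 2, function(ix) {
    cells <- cbind((ix - 1) %/% 3 + 1, (ix - 1) %% 3 + 1)
    r_connected(cells, 3, 3)
  }))
  expect_equal(attr(bf, "n_sets"), n_connected)
  expect_error(brute_force_best_home_range(uniform_grid(1, 6, 6), NULL,
                                           params_fitted, max_area = 4),
               "combinatorial")
  expect_error(brute_force_best_home_range(g, NULL, params_fitted,
                                           max_area = 9),
               "combinatorial")
})

test_that("population establishment yields valid, viable, tallied solutions", {
  for (seed in 1:5) {
    g <- random_grid(7, 7, vmax = 3, seed = seed)
    sol <- establish_population(g, params_fitted, seed = seed)
    cover <- matrix(0L, 7, 7)
    for (hr in sol$home_ranges) {
      expect_gte(nrow(hr$cells), 4)
      expect_true(r_connected(hr$cells, 7, 7))
      expect_gt(hr$net_value, 0)
      expect_equal(hr$net_value, hr$benefit - hr$cost)
      cover[hr$cells] <- cover[hr$cells] + 1L
    }
    expect_equal(unname(sol$overlap_counts), unname(cover))
    expect_equal(sol$abundance, length(sol$home_ranges))
  }
})

test_that("no population establishes on zero habitat", {
  sol <- establish_population(uniform_grid(0, 7, 7), params_fitted, seed = 1)
  expect_equal(sol$abundance, 0)
  expect_length(sol$home_ranges, 0)
})

test_that("abundance responds monotonically to costs and resources", {
  g <- gen_value_grids(site_generator_config(n_sites = 1, seed = 21))[[1]]
  ab_p3 <- vapply(c(2, 4.15, 6), function(p3)
    establish_population(g, hr_params(8.108, 0.222, p3), seed = 5)$abundance,
    integer(1))
  expect_true(all(diff(ab_p3) <= 0))

  ab_scale <- vapply(c(1, 1.5, 2.5), function(f)
    establish_population(value_grid(g$values * f), params_fitted,
                         seed = 5)$abundance, integer(1))
  expect_true(all(diff(ab_scale) >= 0))
})

test_that("establishment is deterministic given a seed", {
  g <- random_grid(7, 7, vmax = 2.5, seed = 11)
  s1 <- establish_population(g, params_fitted, seed = 99)
  s2 <- establish_population(g, params_fitted, seed = 99)
  expect_identical(s1$overlap_counts, s2$overlap_counts)
  expect_identical(lapply(s1$home_ranges, `[[`, "cells"),
                   lapply(s2$home_ranges, `[[`, "cells"))
})

test_that("a patch supporting one range but not two reports abundance one", {
  # 2 x 3 patch of value 2.0 in a zero background: one range covering the
  # patch is viable, but no pair of ranges can both be viable. Verified by
  # a brute-force two-range oracle: enumerate every connected set of 4-6
  # cells, keep those viable alone (a necessary condition under any extra
  # overlap discount), and check every pair under mutual overlap.
  m <- matrix(0, 4, 4)
  m[2:3, 2:4] <- 2.0
  g <- value_grid(m)

  sets <- list()
  for (size in 4:6) {
    combos <- combn(16, size)
    for (j in seq_len(ncol(combos))) {
      cells <- cbind((combos[, j] - 1) %/% 4 + 1, (combos[, j] - 1) %% 4 + 1)
      if (r_connected(cells, 4, 4)) sets[[length(sets) + 1]] <- cells
    }
  }
  nv_solo <- vapply(sets, function(cl)
    hr_net_value(cl, g, NULL, params_fitted), numeric(1))
  viable <- sets[nv_solo > 0]
  expect_gt(length(viable), 0)

  both_viable <- FALSE
  for (i in seq_along(viable)) {
    ov_i <- matrix(0L, 4, 4)
    ov_i[viable[[i]]] <- 1L
    for (j in seq_along(viable)) {
      if (j == i) next
      ov_j <- matrix(0L, 4, 4)
      ov_j[viable[[j]]] <- 1L
      if (hr_net_value(viable[[i]], g, ov_j, params_fitted) > 0 &&
          hr_net_value(viable[[j]], g, ov_i, params_fitted) > 0) {
        both_viable <- TRUE
        break
      }
    }
    if (both_viable) break
  }
  expect_false(both_viable)

  sol <- establish_population(g, params_fitted, seed = 3)
  expect_equal(sol$abundance, 1)
})

test_that("overlap statistics summarise coverage and sharing", {
  g <- uniform_grid(1.64, 7, 7)
  sol <- establish_population(g, params_fitted, seed = 1)
  os <- overlap_stats(sol)
  expect_equal(sum(os$coverage_fractions), 1)
  expect_equal(os$mean_size_ha, os$mean_size_cells * 225 / 1e4)

  # an isolated patch that supports exactly one home range
  single <- establish_population(value_grid({
    m <- matrix(0, 7, 7); m[3:4, 3:5] <- 2.0; m
  }), params_fitted, seed = 1)
  expect_equal(single$abundance, 1)
  os1 <- overlap_stats(single)
  n1 <- nrow(single$home_ranges[[1]]$cells)
  expect_equal(unname(os1$coverage_fractions["1"]), n1 / 49)
  expect_equal(unname(os1$coverage_fractions["0"]), (49 - n1) / 49)
  expect_equal(os1$mean_shared_fraction, 0)
})
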