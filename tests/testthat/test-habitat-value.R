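test_that("functional responses follow their constant or logistic form", {
  cst <- resource_coef("x", "constant", b0 = 0.5, integration_upper = 10)
  expect_equal(functional_response(cst, 3), 0.5)
  expect_equal(functional_response(cst, c(0, 1, 100)), rep(0.5, 3))

  lgs <- resource_coef("x", "logistic", lower = 0.1, upper = 0.9,
                       midpoint = 2, scale = 0.5, integration_upper = 10)
  # declines from the upper to the lower asymptote
  expect_equal(functional_response(lgs, 1e6), 0.1)
  expect_lt(abs(functional_response(lgs, 0) - 0.9), 0.02)
  # midpoint of the asymptotes at the midpoint availability
  expect_equal(functional_response(lgs, 2), 0.5)

  expect_error(functional_response(cst, -1), "non-negative")
  expect_error(resource_coef("x", "constant", b0 = 1, lower = 0,
                             integration_upper = 1), "logistic")
  expect_error(resource_coef("x", "constant", b0 = 1, integration_upper = 0),
               "integration_upper")
})

test_that("integrated resource value matches quadrature and is exact for constants", {
  cst <- resource_coef("x", "constant", b0 = 0.5, integration_upper = 10)
  expect_equal(integrate_resource_value(cst, 2), 1.0)
  expect_equal(integrate_resource_value(cst, 0), 0)

  lgs <- resource_coef("x", "logistic", lower = 0, upper = 1, midpoint = 1,
                       scale = 0.1, integration_upper = 10)
  # adaptive-quadrature oracle
  oracle <- integrate(function(h) functional_response(lgs, h), 0, 5,
                      rel.tol = 1e-10)$value
  expect_lt(abs(integrate_resource_value(lgs, 5) - oracle), 1e-4)
  # the declining logistic saturates (threshold shape): doubling the amount
  # beyond the midpoint barely changes the integral
  v5 <- integrate_resource_value(lgs, 5)
  v10 <- integrate_resource_value(lgs, 10)
  expect_lt(v10 - v5, 1e-6)

  expect_error(integrate_resource_value(cst, -0.5), "integration_upper")
  expect_error(integrate_resource_value(cst, 11), "integration_upper")
})

test_that("trapezoid integration converges at second order", {
  # midpoint off-centre so the logistic's symmetry cannot cancel the error
  lgs <- resource_coef("x", "logistic", lower = 0, upper = 1, midpoint = 0.6,
                       scale = 0.25, integration_upper = 2)
  oracle <- integrate(function(h) functional_response(lgs, h), 0, 2,
                      rel.tol = 1e-12)$value
  err <- vapply(c(50, 100, 200), function(n)
    abs(integrate_resource_value(lgs, 2, n_steps = n) - oracle), numeric(1))
  # halving the step divides the error by ~4
  expect_gt(err[1] / err[2], 3.5)
  expect_gt(err[2] / err[3], 3.5)
})

test_that("integrated value is nondecreasing for nonnegative effects", {
  set.seed(31)
  for (i in 1:5) {
    lgs <- resource_coef("x", "logistic", lower = 0, upper = runif(1, 0.2, 2),
                         midpoint = runif(1, 0.5, 3), scale = runif(1, 0.05, 1),
                         integration_upper = 6)
    a <- sort(runif(10, 0, 6))
    v <- integrate_resource_value(lgs, a)
    expect_true(all(diff(v) >= -1e-12))
  }
})

test_that("fixed-availability response integrates linearly", {
  lgs <- resource_coef("x", "logistic", lower = 0, upper = 1, midpoint = 1,
                       scale = 0.1, integration_upper = 10)
  b_at_2 <- functional_response(lgs, 2)
  expect_equal(integrate_resource_value(lgs, 3, response = "fixed",
                                        site_availability = 2),
               3 * b_at_2)
})

test_that("habitat-value mapping baselines at the poorest cell", {
  cst <- list(x = resource_coef("x", "constant", b0 = 1, integration_upper = 10))
  g <- list(resource_grid("x", matrix(c(0, 1, 2, 1), 2, 2)))
  v <- map_habitat_value(g, cst)
  expect_equal(min(v$values), 0)
  expect_equal(sort(as.vector(v$values)), c(0, 1, 1, 2))
  expect_equal(v$baseline, 0)

  # doubling a constant coefficient doubles V after re-baselining
  cst2 <- list(x = resource_coef("x", "constant", b0 = 2, integration_upper = 10))
  v2 <- map_habitat_value(g, cst2)
  expect_equal(v2$values, 2 * v$values)

  # multi-resource synthetic site: auto baseline still yields min exactly 0
  cfg <- site_generator_config(n_sites = 1, seed = 3)
  rs <- gen_resource_grids(cfg)
  v3 <- map_habitat_value(rs[[1]], default_habitat_coefs()$coefs)
  expect_equal(min(v3$values), 0)

  bad <- list(resource_grid("x", matrix(1, 3, 3)))
  expect_error(map_habitat_value(c(g, bad), cst), "shape")
})

test_that("pooled baseline across sites is the data-set minimum", {
  cst <- list(x = resource_coef("x", "constant", b0 = 1, integration_upper = 10))
  sites <- list(list(resource_grid("x", matrix(2:5, 2, 2))),
                list(resource_grid("x", matrix(1:4, 2, 2))))
  vg <- map_habitat_value_multi(sites, cst)
  expect_equal(vg[[1]]$baseline, 1)
  expect_equal(min(vg[[2]]$values), 0)
  expect_equal(min(vg[[1]]$values), 1)
})

test_that("local means respect the toroidal window", {
  g <- resource_grid("x", matrix(2, 5, 5))
  expect_equal(local_mean(g, 26)$values, g$values)

  m <- matrix(0, 5, 5); m[3, 3] <- 10
  g1 <- resource_grid("x", m)
  # radius below the cell size: only the focal cell in the window
  expect_equal(local_mean(g1, 10)$values, m)
  # radius spanning the whole torus: every cell the global mean
  expect_equal(local_mean(g1, 1e4)$values, matrix(mean(m), 5, 5))
  # 26 m window on a 15 m grid = the 3 x 3 block (diagonals sit at
  # 15 * sqrt(2) = 21.2 m), i.e. nine cells
  lm <- local_mean(g1, 26)$values
  expect_equal(lm[3, 3], 10 / 9)
  expect_equal(lm[2, 2], 10 / 9)
  expect_equal(lm[1, 3], 0)
  expect_error(local_mean(g1, 0), "positive")
})
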