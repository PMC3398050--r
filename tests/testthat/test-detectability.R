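test_that("removal log-likelihood equals the direct product of binomials", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    p <- runif(1, 0.05, 0.95)
    x1 <- sample(0:min(n, 10), 1)
    x2 <- sample(0:min(n - x1, 8), 1)
    x3 <- sample(0:min(n - x1 - x2, 6), 1)
    direct <- log(dbinom(x1, n, p) * dbinom(x2, n - x1, p) *
                    dbinom(x3, n - x1 - x2, p))
    expect_equal(removal_loglik(c(x1, x2, x3), n, p), direct,
                 tolerance = 1e-12)
  }
  expect_equal(removal_loglik(c(5, 0, 0), 5, 1 - 1e-12), 0, tolerance = 1e-9)
  expect_equal(removal_loglik(c(0, 0, 0), 0, 0.5), 0)
  expect_error(removal_loglik(c(4, 2, 1), 6, 0.4), "infeasible")
})

test_that("cumulative detection follows the removal-design closed form", {
  expect_equal(cumulative_detection(1, 2), 1)
  expect_equal(cumulative_detection(0, 3), 0)
  expect_equal(cumulative_detection(0.5, 3), 1 - 0.5^3)
  expect_error(cumulative_detection(1.2, 3), "p_d")
})

test_that("generated removal histories decline geometrically across days", {
  nt <- data.frame(site = seq_len(1000), year = 2006, n = 20)
  h <- gen_capture_histories(nt, c("2006" = 0.4), seed = 3)
  expect_true(all(h$x1 + h$x2 + h$x3 <= 20))
  # E[x2]/E[x1] = 1 - p_d; E[x1]/n = p_d
  expect_equal(mean(h$x1) / 20, 0.4, tolerance = 0.05)
  expect_equal(mean(h$x2) / mean(h$x1), 0.6, tolerance = 0.05)
  # degenerate detectabilities
  h1 <- gen_capture_histories(nt[1:5, ], c("2006" = 1), seed = 1)
  expect_true(all(h1$x1 == 20 & h1$x2 == 0 & h1$x3 == 0))
  h0 <- gen_capture_histories(nt[1:5, ], c("2006" = 0), seed = 1)
  expect_true(all(h0$x1 == 0 & h0$x2 == 0 & h0$x3 == 0))
})

test_that("a single total-capture history forces p near one", {
  h <- capture_histories(data.frame(site = "a", year = 2006,
                                    x1 = 10, x2 = 0, x3 = 0))
  fit <- fit_detectability(h, "global")
  expect_gt(fit$p_d[["global"]], 0.99)
  expect_equal(fit$n_hat$n_hat, 10)
})

test_that("year-specific detectability is recovered from simulated data", {
  nt <- expand.grid(site = sprintf("s%02d", 1:31), year = c(2006, 2007))
  nt$n <- 10
  est <- vapply(1:10, function(s) {
    h <- gen_capture_histories(nt, c("2006" = 0.63, "2007" = 0.42), seed = s)
    fit_detectability(h, "year")$p_d
  }, numeric(2))
  expect_equal(unname(mean(est["2006", ])), 0.63, tolerance = 0.05 / 0.63)
  expect_equal(unname(mean(est["2007", ])), 0.42, tolerance = 0.05 / 0.42)

  h <- gen_capture_histories(nt, c("2006" = 0.63, "2007" = 0.42), seed = 7)
  fit <- fit_detectability(h, "year")
  expect_true(all(fit$n_hat$n_hat >= h$x1 + h$x2 + h$x3))
  # nesting: the global fit cannot beat the year-specific fit
  fit_g <- fit_detectability(h, "global")
  expect_lte(fit_g$loglik, fit$loglik)
})

test_that("the joint-profile estimator overstates detectability in sparse designs", {
  # one nuisance abundance per history makes the jointly profiled ML
  # inconsistent (incidental parameters); the conditional estimator is not
  nt <- data.frame(site = seq_len(31), year = 1, n = 10)
  h <- gen_capture_histories(nt, c("1" = 0.42), seed = 7)
  p_prof <- fit_detectability(h, "global", method = "profile")$p_d[["global"]]
  p_cond <- fit_detectability(h, "global")$p_d[["global"]]
  expect_gt(p_prof, p_cond + 0.05)
  expect_lt(abs(p_cond - 0.42), 0.1)
})

test_that("maximum-likelihood detectability is consistent as data grow", {
  p_true <- 0.5
  est <- vapply(c(40, 400), function(n_sites) {
    nt <- data.frame(site = seq_len(n_sites), year = 1, n = 12)
    h <- gen_capture_histories(nt, c("1" = p_true), seed = 11)
    fit_detectability(h, "global")$p_d[["global"]]
  }, numeric(1))
  expect_lt(abs(est[2] - p_true), abs(est[1] - p_true) + 0.02)
  expect_lt(abs(est[2] - p_true), 0.03)
})

test_that("all-zero strata are flagged as unidentifiable", {
  h <- data.frame(site = c("a", "b"), year = c(1, 2),
                  x1 = c(0, 3), x2 = 0, x3 = c(0, 1))
  expect_warning(fit <- fit_detectability(h, "year"), "unidentifiable")
  expect_true(is.na(fit$p_d[["1"]]))
  expect_false(is.na(fit$p_d[["2"]]))
})

test_that("corrected abundances follow the capture/detection arithmetic", {
  fit <- structure(list(structure = "year",
                        p_d = c("2006" = 0.63, "2007" = 0.42)),
                   class = "detectability_fit")
  h <- data.frame(site = "s1", year = c(2006, 2007),
                  x1 = c(6, 5), x2 = c(2, 2), x3 = c(1, 1))
  # captures 9 and 8; cumulative detection 0.949 and 0.805
  cum06 <- cumulative_detection(0.63, 3)
  cum07 <- cumulative_detection(0.42, 3)
  expected <- floor((9 / cum06 + 8 / cum07) / 2 + 0.5)
  expect_equal(correct_abundance(h, fit), expected)
  expect_equal(expected, 10)  # round(9.71) = 10

  # perfect detection passes captures through; no captures give zero
  fit1 <- structure(list(structure = "global", p_d = c(global = 1 - 1e-12)),
                    class = "detectability_fit")
  h2 <- data.frame(site = "s1", year = c(1, 2), x1 = c(10, 10), x2 = 0, x3 = 0)
  expect_equal(correct_abundance(h2, fit1), 10)
  h0 <- data.frame(site = "s1", year = c(1, 2), x1 = 0, x2 = 0, x3 = 0)
  expect_equal(correct_abundance(h0, fit1), 0)
})

test_that("structure selection ranks by AICc and refuses degenerate strata", {
  nt <- expand.grid(site = sprintf("s%02d", 1:31), year = c(2006, 2007))
  nt$n <- 10
  h <- gen_capture_histories(nt, c("2006" = 0.63, "2007" = 0.42), seed = 19)
  sel <- select_structure(h)
  expect_setequal(sel$structure, c("global", "year", "site", "year_site"))
  expect_equal(sel$structure[1], "year")
  expect_equal(sel$delta_aicc[1], 0)
  expect_true(all(diff(sel$aicc) >= 0))

  # single history: only the global structure can be fit
  one <- data.frame(site = "a", year = 1, x1 = 4, x2 = 1, x3 = 0)
  sel1 <- select_structure(one)
  expect_equal(sel1$structure, "global")
})
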