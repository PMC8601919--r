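protocol_temps <- c(10, 15, 20, 25, 30, 35, 37, 40)

test_that("noise-free piecewise data is recovered essentially exactly", {
  y <- piecewise_vo2(protocol_temps, 0.96, 17.7, 34.5, -0.11, 0.04)
  fit <- fit_piecewise(protocol_temps, y, 2,
                       bounds = list(c(12, 28), c(28, 38)))
  expect_true(fit$converged)
  expect_equal(fit$psi, c(17.7, 34.5), tolerance = 0.05)
  expect_equal(fit$slopes, c(-0.11, 0, 0.04), tolerance = 1e-6)

  # one breakpoint, slopes (0, 2), psi = 31.85
  y1 <- 100 + 2 * pmax(protocol_temps - 31.85, 0)
  f1 <- fit_piecewise(protocol_temps, y1, 1, bounds = c(28, 38))
  expect_true(f1$converged)
  expect_equal(f1$psi, 31.85, tolerance = 0.05)
})

test_that("grid search attains the brute-force profile optimum", {
  set.seed(101)
  for (r in 1:12) {
    x <- protocol_temps
    psi_true <- runif(1, 29, 36)
    y <- 1 + 0.5 * pmax(x - psi_true, 0) + rnorm(8, 0, 0.05)
    fit <- fit_piecewise(x, y, 1, bounds = c(28, 38))
    oracle <- scan_1bp_oracle(x, y, 28, 38, step = 0.01)
    expect_lte(fit$rss, oracle + 1e-9)
  }
})

test_that("two-breakpoint grid search attains the 2-D oracle optimum", {
  set.seed(202)
  for (r in 1:4) {
    x <- protocol_temps
    y <- piecewise_vo2(x, 1, 17 + runif(1, -1, 1), 34 + runif(1, -1, 1),
                       -0.1, 0.05) * exp(rnorm(8, 0, 0.05))
    fit <- fit_piecewise(x, y, 2, bounds = list(c(14, 20), c(31, 37)))
    oracle <- scan_2bp_oracle(x, y, c(14, 20), c(31, 37), step = 0.02)
    expect_lte(fit$rss, oracle + 1e-9)
  }
})

test_that("fit is invariant to shuffling the observations", {
  set.seed(7)
  y <- piecewise_vo2(protocol_temps, 1, 18, 34, -0.1, 0.05) +
    rnorm(8, 0, 0.03)
  f1 <- fit_piecewise(protocol_temps, y, 2, list(c(12, 28), c(28, 38)))
  perm <- sample(8)
  f2 <- fit_piecewise(protocol_temps[perm], y[perm], 2,
                      list(c(12, 28), c(28, 38)))
  expect_equal(f1$psi, f2$psi, tolerance = 1e-10)
  expect_equal(f1$rss, f2$rss, tolerance = 1e-12)
})

test_that("degenerate inputs are flagged or rejected", {
  y_flat <- rep(1, 8)
  f <- fit_piecewise(protocol_temps, y_flat, 1, bounds = c(28, 38))
  expect_false(f$converged)
  expect_error(fit_piecewise(protocol_temps[1:4], rnorm(4), 1, c(20, 30)),
               "too few")
  expect_error(fit_piecewise(protocol_temps, y_flat, 2,
                             list(c(12, 30), c(28, 38))), "overlap")
  expect_error(fit_piecewise(protocol_temps, y_flat, 1, c(5, 38)),
               "inside")
})

test_that("iterative linearization agrees with the grid on large n", {
  set.seed(33)
  x <- runif(200, 10, 40)
  y <- 2 + 0.8 * pmax(x - 31, 0) + rnorm(200, 0, 0.1)
  g <- fit_piecewise(x, y, 1, bounds = c(15, 39.5), grid_step = 0.05)
  it <- iterative_refit(x, y, psi_init = 25)
  expect_true(it$converged)
  expect_lt(abs(it$psi - g$psi), 0.1)

  # initialized at the truth on noise-free data: one-step convergence
  y0 <- 2 + 0.8 * pmax(x - 31, 0)
  it0 <- iterative_refit(x, y0, psi_init = 31)
  expect_true(it0$converged)
  expect_equal(it0$iterations, 1L)
  expect_equal(it0$psi, 31, tolerance = 1e-6)

  # flat data cannot identify a breakpoint
  itf <- iterative_refit(x, rep(2, 200), psi_init = 25)
  expect_false(itf$converged)
})

test_that("breakpoint estimates tighten as noise vanishes", {
  cvs <- c(0.10, 0.05, 0.01)
  bias <- vapply(cvs, function(cv) {
    errs <- vapply(1:10, function(r) {
      noise <- withr::with_seed(900 + r, exp(rnorm(8, 0, sqrt(log(1 + cv^2)))))
      y <- piecewise_vo2(protocol_temps, 0.96, 17.7, 34.5, -0.11, 0.04) *
        noise
      f <- fit_piecewise(protocol_temps, y, 2, list(c(12, 28), c(28, 38)))
      mean(abs(f$psi - c(17.7, 34.5)))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(bias) < 0))
})

test_that("TNZ arithmetic and BMR rules", {
  y <- piecewise_vo2(protocol_temps, 0.96, 17.7, 34.5, -0.11, 0.04)
  fit <- fit_piecewise(protocol_temps, y, 2, list(c(12, 28), c(28, 38)))
  prof <- data.frame(Ta = protocol_temps, VO2 = y)
  tnz <- tnz_from_fit(fit, prof, id = "b1")
  expect_equal(tnz$breadth, tnz$Tuc - tnz$Tlc)
  expect_equal(tnz$BMR, 0.96, tolerance = 1e-9)

  # breadth identity on the reported critical temperatures
  expect_equal(34.5 - 17.7, 16.8)

  # observed-mean BMR rule: mean of in-zone observations
  prof2 <- data.frame(Ta = c(20, 25, 30), VO2 = c(0.9, 1.0, 1.1))
  fit2 <- fit_piecewise(protocol_temps, y, 2, list(c(12, 28), c(28, 38)))
  fit2$psi <- c(17, 34)
  expect_equal(tnz_from_fit(fit2, prof2)$BMR, 1.0)

  expect_error(tnz_from_fit(fit_piecewise(protocol_temps,
                                          100 + 2 * pmax(protocol_temps -
                                                           31.85, 0),
                                          1, c(28, 38)), prof),
               "two-breakpoint")
})

test_that("EWL inflection propagates convergence", {
  y1 <- 100 + 2 * pmax(protocol_temps - 31.85, 0)
  f1 <- fit_piecewise(protocol_temps, y1, 1, bounds = c(28, 38))
  infl <- ewl_inflection(f1)
  expect_true(infl$converged)
  expect_equal(infl$inflection, 31.85, tolerance = 0.05)

  fflat <- fit_piecewise(protocol_temps, rep(100, 8), 1, c(28, 38))
  expect_false(ewl_inflection(fflat)$converged)
})

test_that("population summary is the arithmetic mean +/- SE", {
  est <- data.frame(id = c("a", "b"), Tlc = c(16, 18), Tuc = c(34, 36),
                    breadth = c(18, 18), BMR = c(1, 1),
                    ewl_infl = c(31, 33), converged = c(TRUE, TRUE))
  s <- population_summary(est)
  expect_equal(s$mean[s$quantity == "Tlc"], 17)
  expect_equal(s$se[s$quantity == "Tlc"], 1)
  expect_equal(s$se[s$quantity == "breadth"], 0)
  expect_error(population_summary(est[1, ]), "fewer than 2")
})
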