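test_that("AICc formula matches hand arithmetic and printed table rows", {
  expect_equal(aicc(16.39, 2, 24), -2 * 16.39 + 4 + 12 / 21)
  expect_equal(aicc(16.39, 2, 24), -28.20, tolerance = 0.02)
  expect_equal(aicc(36.28, 2, 24), -68.00, tolerance = 0.02)
  # the small-sample correction vanishes as n grows
  expect_equal(aicc(10, 3, 1e8), -2 * 10 + 6, tolerance = 1e-5)
  expect_error(aicc(10, 5, 6), "n > k")
})

test_that("marginality-respecting enumeration", {
  ms <- enumerate_models(c("sex", "bill", "tarsi", "bill:sex", "tarsi:sex"))
  expect_length(ms, 13)
  for (m in ms) {
    if ("bill:sex" %in% m) expect_true(all(c("bill", "sex") %in% m))
    if ("tarsi:sex" %in% m) expect_true(all(c("tarsi", "sex") %in% m))
  }
  expect_length(enumerate_models("sex"), 2)
  expect_true(any(vapply(ms, length, integer(1)) == 0))  # null included
})

test_that("Gaussian ML log-likelihood and k match the table convention", {
  # intercept-only fit on {1, 2, 3}: coefficient 2, RSS 2
  f <- tnztools:::fit_one_model(character(0), "y",
                                data.frame(y = c(1, 2, 3)))
  expect_equal(unname(coef(f$fit)), 2)
  expect_equal(f$rss, 2)
  expect_equal(f$k, 2)  # intercept + residual variance
  n <- 3
  expect_equal(f$logLik, -n / 2 * (log(2 * pi * f$rss / n) + 1),
               tolerance = 1e-10)
  # the null model carries df = 2 in a ranked table
  set.seed(41)
  tab <- model_selection(data.frame(y = rnorm(24)), "y", character(0))
  expect_equal(tab$df, 2)
})

test_that("bivariate fit matches the normal-equations oracle", {
  set.seed(42)
  d <- data.frame(x1 = c(0, 1, 2, 3, 4, 5, 6, 7),
                  x2 = c(1, 0, 1, 0, 1, 0, 1, 0))
  d$y <- 0.5 + 1.1 * d$x1 - 0.7 * d$x2 + rnorm(8, 0, 0.3)
  tab <- model_selection(d, "y", c("x1", "x2"))
  full <- attr(tab, "fits")[[which(tab$model == "x1 + x2")]]
  o <- ols_oracle(cbind(1, d$x1, d$x2), d$y)
  expect_equal(unname(coef(full$fit)), o$beta, tolerance = 1e-10)
  expect_equal(full$rss, o$rss, tolerance = 1e-12)
})

test_that("Akaike weights: normalization, symmetry, direct evaluation", {
  d <- c(0, 2, 4)
  w <- exp(-d / 2) / sum(exp(-d / 2))
  expect_equal(w, c(0.6652410, 0.2447285, 0.0900306), tolerance = 1e-6)
  expect_equal(sum(w), 1, tolerance = 1e-12)

  # two models with equal AICc split the weight evenly
  expect_equal(exp(0) / sum(exp(c(0, 0))), 0.5)

  # a perfectly saturated model is dropped with a warning
  dsat <- data.frame(x = 1:6, y = 2 * (1:6))
  expect_warning(tabsat <- model_selection(dsat, "y", "x"), "saturated")
  expect_equal(tabsat$model, "Null")

  set.seed(4)
  dd <- data.frame(y = rnorm(24), a = rnorm(24), b = rnorm(24))
  tab <- model_selection(dd, "y", c("a", "b"))
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_equal(tab$dAICc[1], 0)
  expect_true(all(diff(tab$AICc) >= 0))
  # weights depend only on AICc differences
  w2 <- exp(-(tab$AICc + 7 - min(tab$AICc + 7)) / 2)
  expect_equal(tab$weight, w2 / sum(w2), tolerance = 1e-12)
})

test_that("relative importance weights sum the right models", {
  set.seed(5)
  dd <- data.frame(y = rnorm(30), a = rnorm(30), b = rnorm(30))
  tab <- model_selection(dd, "y", c("a", "b"))
  fits <- attr(tab, "fits")
  manual <- sum(tab$weight[vapply(fits, function(f) "a" %in% f$terms,
                                  logical(1))])
  expect_equal(riw("a", tab), manual, tolerance = 1e-12)
  # a term in every model / no model
  one <- model_selection(dd, "y", character(0))
  expect_equal(riw("a", one), 0)
})

test_that("conditional model averaging follows Burnham-Anderson", {
  set.seed(12)
  n <- 24
  dd <- data.frame(a = rnorm(n), b = rnorm(n))
  dd$y <- 0.4 * dd$a + rnorm(n, 0, 1)
  tab <- model_selection(dd, "y", c("a", "b"))
  avg <- model_average(tab, delta_max = 2)

  if (!attr(avg, "single_model")) {
    keep <- tab$dAICc < 2
    w <- tab$weight[keep] / sum(tab$weight[keep])
    fits <- attr(tab, "fits")[keep]
    # oracle for the coefficient of 'a': renormalized over models with 'a'
    has_a <- vapply(fits, function(f) "a" %in% f$terms, logical(1))
    if (any(has_a)) {
      wa <- w[has_a] / sum(w[has_a])
      est <- vapply(fits[has_a],
                    function(f) summary(f$fit)$coefficients["a", 1],
                    numeric(1))
      se <- vapply(fits[has_a],
                   function(f) summary(f$fit)$coefficients["a", 2],
                   numeric(1))
      bbar <- sum(wa * est)
      expect_equal(avg$estimate[avg$term == "a"], bbar, tolerance = 1e-10)
      expect_equal(avg$se[avg$term == "a"],
                   sqrt(sum(wa * (se^2 + (est - bbar)^2))),
                   tolerance = 1e-10)
      # averaged estimate lies in the convex hull of contributors
      expect_gte(avg$estimate[avg$term == "a"], min(est) - 1e-12)
      expect_lte(avg$estimate[avg$term == "a"], max(est) + 1e-12)
    }
  }
  expect_equal(avg$ci_lo, avg$estimate - 1.96 * avg$se, tolerance = 1e-3)
  expect_identical(avg$significant, avg$ci_lo > 0 | avg$ci_hi < 0)
})

test_that("two-model equal-weight averaging oracle", {
  # estimates 1 and 3 with zero SE and equal weights: mean 2, SE 1
  est <- c(1, 3); w <- c(0.5, 0.5)
  bbar <- sum(w * est)
  se <- sqrt(sum(w * (0^2 + (est - bbar)^2)))
  expect_equal(bbar, 2)
  expect_equal(se, 1)
})

test_that("VIF matches 1/(1 - R2) and the car implementation", {
  # orthogonal predictors -> all VIF 1
  d <- data.frame(a = rep(c(-1, 1), 8), b = rep(c(-1, -1, 1, 1), 4))
  expect_equal(unname(vif(d, c("a", "b"))), c(1, 1), tolerance = 1e-12)

  set.seed(6)
  d3 <- data.frame(a = rnorm(40), b = rnorm(40))
  d3$c <- 0.7 * d3$a + 0.3 * rnorm(40)
  v <- vif(d3, c("a", "b", "c"))
  r2a <- summary(lm(a ~ b + c, d3))$r.squared
  expect_equal(unname(v["a"]), 1 / (1 - r2a), tolerance = 1e-10)
  d3$y <- rnorm(40)
  v_car <- car::vif(lm(y ~ a + b + c, d3))
  expect_equal(unname(v), unname(v_car[names(v)]), tolerance = 1e-8)

  d3$dup <- d3$a
  expect_true(is.infinite(vif(d3, c("a", "dup", "b"))["a"]))
})

test_that("t tests: guards and textbook agreement", {
  expect_equal(t_test2(c(1, 2, 3), c(1, 2, 3), paired = TRUE),
               list(t = 0, df = 2, p = 1))
  r <- t_test2(c(2, 3, 4), c(1, 2, 3), paired = TRUE)
  expect_equal(r$p, 0)
  expect_true(is.infinite(r$t))

  a <- c(1, 2, 3, 4, 5); b <- c(3, 4, 5, 6, 7)
  got <- t_test2(a, b)
  want <- pooled_t_oracle(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-10)
  expect_equal(got$df, want$df)
  expect_equal(got$p, want$p, tolerance = 1e-10)
})
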