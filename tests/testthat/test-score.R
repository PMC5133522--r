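test_that("score components reduce to the textbook forms", {
  d <- toy_logistic(100, seed = 21)
  g <- rbinom(100, 2, 0.1)
  # constant genotype carries no score
  sc0 <- score_components(d$y, d$X, rep(1, 100))
  expect_equal(sc0$U, 0, tolerance = 1e-10)
  expect_lt(sc0$V, 1e-10)
  # intercept-only null: U = sum g_i (y_i - ybar)
  sc1 <- score_components(d$y, matrix(1, 100), g)
  expect_equal(sc1$U, sum(g * (d$y - mean(d$y))), tolerance = 1e-8)
})

test_that("score variance matches the inverse-information block oracle", {
  set.seed(50)
  n <- 50
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, 0.4)
  g <- rbinom(n, 2, 0.2)
  sc <- score_components(y, X, g)
  # full-matrix oracle: V = 1 / [I^{-1}]_gg at the null fit
  pi0 <- fit_mle(y, X)$fitted_probs
  w <- pi0 * (1 - pi0)
  Xfull <- cbind(X, g)
  Ifull <- crossprod(Xfull * w, Xfull)
  V_oracle <- 1 / solve(Ifull)[4, 4]
  expect_equal(sc$V, V_oracle, tolerance = 1e-8)
})

test_that("standard score test is chi-square referred and affine invariant", {
  d <- toy_logistic(200, seed = 4)
  g <- rbinom(200, 2, 0.15)
  sc <- score_components(d$y, d$X, g)
  st <- standard_score_test(sc)
  expect_equal(st$p_value, pchisq(st$statistic, 1, lower.tail = FALSE))
  # affine rescale of g leaves the statistic unchanged (intercept present)
  sc2 <- score_components(d$y, d$X, 3.7 * g + 0.9)
  expect_equal(standard_score_test(sc2)$statistic, st$statistic,
               tolerance = 1e-8)
  # degenerate variance falls back to p = 1
  expect_equal(standard_score_test(score_components(d$y, d$X,
                                                    rep(0, 200)))$p_value, 1)
})

test_that("score and LR tests agree asymptotically for a common variant", {
  set.seed(61)
  n <- 5000
  X <- cbind(1, rnorm(n, 50, 10))
  g <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-1 + 0.005 * X[, 2]))
  p_score <- standard_score_test(score_components(y, X, g))$p_value
  full <- fit_mle(y, cbind(X, g))
  p_lr <- lr_test(full, fit_mle(y, X))$p_value
  expect_lt(abs(p_score - p_lr), 0.005)
})

test_that("kurtosis-based degrees of freedom follow 12/gamma with guards", {
  d <- toy_logistic(400, seed = 8)
  g <- rbinom(400, 2, 0.02)
  sc <- score_components(d$y, d$X, g)
  ad <- adjusted_score_test(sc, B = 2000, seed = 5)
  pars <- attr(ad, "df_or_params")
  expect_equal(pars$df, min(max(12 / pars$gamma_hat, 0.5), 1e5))
  expect_error(adjusted_score_test(sc, B = 500), "B >= 1000")
  # gamma <= 0 caps df at the normal limit with fallback status
  ad2 <- adjusted_score_test(sc, Qstar = rep(c(1, 2), 500))
  expect_equal(attr(ad2, "df_or_params")$df, 1e5)
})

test_that("adjusted tests meet the standard score test in the normal limit", {
  set.seed(13)
  n <- 2000
  X <- cbind(1, rnorm(n))
  y <- rbinom(n, 1, 0.5)
  g <- rbinom(n, 2, 0.4)   # MAC~ near n/2: ample information
  sc <- score_components(y, X, g)
  p0 <- standard_score_test(sc)$p_value
  expect_lt(abs(adjusted_score_test(sc, adjust = "variance")$p_value - p0),
            0.01)
  # kurtosis mode: with the exact normal-limit resampling law (V chi2_1)
  # the moment recipe reproduces the standard test; with a finite
  # bootstrap the df estimate carries sampling noise of a few percent
  set.seed(2)
  Qstar_exact <- sc$V * rchisq(5e5, 1)
  expect_lt(abs(adjusted_score_test(sc, Qstar = Qstar_exact)$p_value - p0),
            0.02)
  expect_lt(abs(adjusted_score_test(sc, B = 10000, seed = 2)$p_value - p0),
            0.05)
})

test_that("analytic kurtosis equals the bootstrap's large-B limit", {
  set.seed(5)
  n <- 800
  X <- cbind(1, rnorm(n))
  y <- rbinom(n, 1, 0.25)
  for (maf in c(0.03, 0.3)) {
    g <- rbinom(n, 2, maf)
    sc <- score_components(y, X, g)
    ga <- rarelogit:::analytic_Q_kurtosis(sc$g_adj, sc$null_probs)
    Qb <- boot_Qstar_vec(sc$g_adj, sc$null_probs, 2e5, seed = 9)
    # the sample kurtosis of a chi-square-1-type variable needs eighth
    # moments: even at 2e5 draws its own spread is several tenths
    expect_lt(abs(ga - rarelogit:::excess_kurtosis(Qb)), 2.5)
    # the two kurtosis modes give close p-values
    pa <- adjusted_score_test(sc, kurtosis = "analytic")$p_value
    pb <- adjusted_score_test(sc, B = 20000, seed = 4)$p_value
    expect_lt(abs(pa - pb), 0.05)
  }
  # normal limit: a common variant's Q is chi-square-1 (excess kurtosis 12)
  g2 <- rbinom(5000, 2, 0.4)
  sc2 <- score_components(rbinom(5000, 1, 0.5), cbind(1, rnorm(5000)), g2)
  expect_lt(abs(rarelogit:::analytic_Q_kurtosis(sc2$g_adj,
                                                sc2$null_probs) - 12), 0.2)
})

test_that("bootstrap moments are reproducible under a fixed seed", {
  d <- toy_logistic(300, seed = 14)
  g <- rbinom(300, 2, 0.03)
  sc <- score_components(d$y, d$X, g)
  a1 <- adjusted_score_test(sc, B = 2000, seed = 77)
  a2 <- adjusted_score_test(sc, B = 2000, seed = 77)
  expect_identical(a1$p_value, a2$p_value)
  expect_identical(attr(a1, "df_or_params")$gamma_hat,
                   attr(a2, "df_or_params")$gamma_hat)
})

test_that("adjusted p for a sparse variant tracks its resampling law", {
  set.seed(31)
  n <- 500
  X <- cbind(1, rnorm(n, 50, 10))
  y <- rbinom(n, 1, plogis(-1.4 + 0.005 * X[, 2]))
  g <- integer(n)
  g[sample(n, 3)] <- 1L   # MAC~ = 3
  sc <- score_components(y, X, g)
  ad <- adjusted_score_test(sc, B = 10000, seed = 3)
  p_boot <- boot_tail(sc$g_adj, sc$null_probs, sc$U^2, B = 1e5, seed = 4)
  # with 3 carriers the exact resampling law has large atoms; a smooth
  # chi-square moment fit can only track it to the size of those atoms
  expect_lt(abs(ad$p_value - p_boot), 0.08)
  # at moderate sparseness, tail p-values track the resampling law closely
  set.seed(37)
  g2 <- integer(500)
  g2[sample(500, 25)] <- 1L
  sc2 <- score_components(y, X, g2)
  expect_lt(standard_score_test(sc2)$p_value, 0.05)  # a tail observation
  ad2 <- adjusted_score_test(sc2, B = 10000, seed = 5)
  p_boot2 <- boot_tail(sc2$g_adj, sc2$null_probs, sc2$U^2, B = 1e5, seed = 6)
  expect_lt(abs(ad2$p_value - p_boot2), 0.005)
})
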