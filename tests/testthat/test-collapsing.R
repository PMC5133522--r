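test_that("variant weights follow the Beta density and Madsen-Browning forms", {
  expect_equal(variant_weights(1e-6, "beta"), 25 * (1 - 1e-6)^24,
               tolerance = 1e-9)
  expect_equal(variant_weights(0.5, "beta"), 25 * 0.5^24)
  expect_equal(variant_weights(0.1, "madsen-browning", n = 100), 1 / 3)
  expect_error(variant_weights(0, "beta"), "filter")
  expect_error(variant_weights(0.1, "madsen-browning"), "sample size")
  # rare variants get the largest Beta(1,25) weights
  w <- variant_weights(c(0.001, 0.01, 0.1), "beta")
  expect_true(all(diff(w) < 0))
})

test_that("single-variant regions reduce burden and SKAT to the score test", {
  tr <- toy_region()
  cfg <- collapsing_config(adjust = "off")
  g <- tr$G[, 2, drop = FALSE]
  p_score <- standard_score_test(score_components(tr$y, tr$X, g[, 1]))$p_value
  expect_equal(burden_test(tr$y, tr$X, g, cfg)$p_value, p_score,
               tolerance = 1e-10)
  expect_equal(skat_test(tr$y, tr$X, g, cfg)$p_value, p_score,
               tolerance = 1e-8)
})

test_that("SKAT statistic is a nonnegative quadratic form, invariant to column order", {
  tr <- toy_region()
  cfg <- collapsing_config(adjust = "off")
  s1 <- skat_test(tr$y, tr$X, tr$G, cfg)
  expect_gte(s1$statistic, 0)
  s2 <- skat_test(tr$y, tr$X, tr$G[, c(4, 1, 5, 2, 3)], cfg)
  expect_equal(s2$statistic, s1$statistic, tolerance = 1e-9)
  expect_equal(s2$p_value, s1$p_value, tolerance = 1e-9)
})

test_that("burden p-value is invariant to rescaling all weights", {
  tr <- toy_region()
  cfg <- collapsing_config(adjust = "off")
  p1 <- burden_test(tr$y, tr$X, tr$G, cfg)$p_value
  cfg2 <- collapsing_config(adjust = "off", a1 = 1, a2 = 25)
  # rescaling the collapsed variable is an affine map; p is unchanged
  p2 <- standard_score_test(score_components(
    tr$y, tr$X,
    7.3 * as.numeric(tr$G %*% variant_weights(apply(tr$G, 2, compute_maf),
                                              "beta"))))$p_value
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("all-zero regions fall back to p = 1", {
  tr <- toy_region()
  G0 <- matrix(0, nrow(tr$G), 2)
  expect_equal(burden_test(tr$y, tr$X, G0)$p_value, 1)
  expect_equal(burden_test(tr$y, tr$X, G0)$status, "fallback")
  expect_equal(skat_test(tr$y, tr$X, G0)$p_value, 1)
})

test_that("SKAT-O endpoint grids reduce to SKAT and burden exactly", {
  tr <- toy_region()
  cfg0 <- collapsing_config(adjust = "off")
  p_skat <- skat_test(tr$y, tr$X, tr$G, cfg0)$p_value
  p_burd <- burden_test(tr$y, tr$X, tr$G, cfg0)$p_value
  g_skat <- collapsing_config(adjust = "off", rho_grid = 0)
  g_burd <- collapsing_config(adjust = "off", rho_grid = 1)
  expect_equal(skato_test(tr$y, tr$X, tr$G, g_skat)$p_value, p_skat,
               tolerance = 1e-10)
  expect_equal(skato_test(tr$y, tr$X, tr$G, g_burd)$p_value, p_burd,
               tolerance = 1e-10)
})

test_that("SKAT-O respects the Bonferroni bound over its grid", {
  set.seed(77)
  for (i in 1:5) {
    tr <- toy_region(n = 250, seed = 100 + i)
    cfg <- collapsing_config(adjust = "off")
    so <- skato_test(tr$y, tr$X, tr$G, cfg)
    pars <- attr(so, "df_or_params")
    expect_lte(so$p_value,
               length(cfg$rho_grid) * min(pars$p_rho) + 1e-12)
    expect_gte(so$p_value, 0)
    expect_lte(so$p_value, 1)
  }
})

test_that("SKAT-O min-p null distribution is consistent with resampling", {
  # moment-matched per-rho p-values on both the observed statistic and the
  # resamples keep the comparison apples-to-apples
  set.seed(5)
  n <- 200
  X <- matrix(1, n)
  y <- rbinom(n, 1, 0.3)
  G <- sapply(c(0.05, 0.1, 0.08, 0.12), function(p) rbinom(n, 2, p))
  cfg <- collapsing_config(adjust = "off", rho_grid = c(0, 0.5, 1),
                           skato_method = "liu")
  so <- skato_test(y, X, G, cfg)
  # resampling oracle for the minimum-p statistic
  nf <- fit_mle(y, X)
  prep <- rarelogit:::region_prep(y, X, G, cfg, nf)
  U <- as.numeric(crossprod(prep$Bm, prep$r))
  lam_rho <- list()
  for (i in seq_along(cfg$rho_grid)) {
    rho <- min(cfg$rho_grid[i], 0.999)
    m <- prep$m
    Z <- prep$Bm * sqrt(prep$w)
    s1 <- sqrt(1 - rho); s2 <- sqrt(1 - rho + m * rho)
    Zr <- s1 * Z + ((s2 - s1) / m) * (Z %*% matrix(1, m, m))
    lam <- eigen(crossprod(Zr), symmetric = TRUE, only.values = TRUE)$values
    lam_rho[[i]] <- lam[lam > 1e-10 * max(lam)]
  }
  p_of <- function(Uv) {
    min(vapply(seq_along(cfg$rho_grid), function(i) {
      rho <- min(cfg$rho_grid[i], 0.999)
      q <- (1 - rho) * sum(Uv^2) + rho * sum(Uv)^2
      liu_pvalue(q, lam_rho[[i]])
    }, numeric(1)))
  }
  T_obs <- p_of(U)
  set.seed(6)
  B <- 4000
  Tstar <- numeric(B)
  for (b in seq_len(B)) {
    r <- rbinom(n, 1, prep$pi0) - prep$pi0
    Tstar[b] <- p_of(as.numeric(crossprod(prep$Bm, r)))
  }
  p_resamp <- mean(Tstar <= T_obs)
  se <- sqrt(max(p_resamp * (1 - p_resamp), 1e-4) / B)
  expect_lt(abs(so$p_value - p_resamp), max(3 * se, 0.03))
})

test_that("class selection matches Table-1 style boundaries and cardinality", {
  set.seed(60)
  n <- 400
  mafs <- c(0.004, 0.008, 0.002, 0.03, 0.05, 0.2)
  G <- sapply(mafs, function(p) rbinom(n, 2, p))
  colnames(G) <- paste0("v", 1:6)
  gm <- genotype_matrix(G, variants = data.frame(
    id = paste0("v", 1:6), chrom = "3", pos = 1:6 * 100))
  # force the spec'd MAFs for classification by injecting them
  gm$variants$maf <- mafs
  part <- structure(list(assignments = c(1, 1, 1, 2, 2, 2), K = 2L),
                    class = "subregion_partition")
  y <- rbinom(n, 1, 0.3)
  X <- matrix(1, n)
  cfg <- collapsing_config(adjust = "off")
  res <- suppressMessages(
    test_region_by_class(y, X, gm, part, methods = c("burden", "skat"),
                         cfg = cfg))
  # subregion 1 is all rare: its three class selections coincide
  s1 <- res[res$target == "1" & res$method == "skat", ]
  expect_equal(length(unique(s1$p_value)), 1L)
  # subregion 2 has no rare variant: the rare selector is skipped
  expect_false(any(res$target == "2" & res$class == "rare"))
  # cardinality: (3 classes x 1 region + 2 classes x 1 region) x 2 methods
  expect_equal(nrow(res), 10L)
  # MAF 0.01 is low-frequency, 0.05 is common (left-closed boundaries)
  expect_equal(as.character(variant_class(c(0.01, 0.05))),
               c("low-frequency", "common"))
})

test_that("opposed equal effects cancel in the burden sum but not in SKAT", {
  # protective and deleterious variants of equal magnitude: the weighted
  # sum carries almost no mean signal, while the variance-component
  # statistic keeps both
  set.seed(88)
  n <- 1500
  g1 <- rbinom(n, 2, 0.1)
  g2 <- rbinom(n, 2, 0.1)
  X <- matrix(1, n)
  cfg <- collapsing_config(adjust = "off")
  rej_b <- rej_s <- 0
  for (i in 1:30) {
    yy <- rbinom(n, 1, plogis(-1.2 + 0.5 * g1 - 0.5 * g2))
    rej_b <- rej_b + (burden_test(yy, X, cbind(g1, g2), cfg)$p_value < 0.05)
    rej_s <- rej_s + (skat_test(yy, X, cbind(g1, g2), cfg)$p_value < 0.05)
  }
  expect_gte(rej_s - rej_b, 10)  # SKAT retains far more of the signal
  expect_lte(rej_b, 15)          # burden power collapses toward size
})

test_that("sparse regions reveal the conservatism the adjustments target", {
  # at n = 300 with MAFs of 1.5-5% the asymptotic SKAT mixture sits a few
  # relative percent above the exact resampling law in the tail; the
  # adjusted variant moves toward it.  This is the small-sample effect
  # that motivates moment adjustment in the first place.
  tr <- toy_region(seed = 31)
  nf <- fit_mle(tr$y, tr$X)
  cfg0 <- collapsing_config(adjust = "off")
  sk <- skat_test(tr$y, tr$X, tr$G, cfg0, null_fit = nf)
  prep <- rarelogit:::region_prep(tr$y, tr$X, tr$G, cfg0, nf)
  p_boot <- boot_tail(prep$Bm, prep$pi0, sk$statistic, B = 1e5, seed = 3)
  # close in absolute terms, with the gap on the conservative side
  expect_lt(abs(sk$p_value - p_boot), 0.01)
  expect_gte(sk$p_value, p_boot - 3 * sqrt(p_boot * (1 - p_boot) / 1e5))
})

test_that("burden and SKAT track a large parametric-bootstrap oracle", {
  tr <- toy_oracle_region()
  nf <- fit_mle(tr$y, tr$X)
  cfg0 <- collapsing_config(adjust = "off")
  wj <- variant_weights(apply(tr$G, 2, compute_maf), "beta")
  sc <- score_components(tr$y, tr$X, as.numeric(tr$G %*% wj), null_fit = nf)
  bt <- burden_test(tr$y, tr$X, tr$G, cfg0, null_fit = nf)
  p_boot <- boot_tail(sc$g_adj, sc$null_probs, sc$U^2, B = 1e5, seed = 2)
  se <- sqrt(p_boot * (1 - p_boot) / 1e5)
  expect_lt(abs(bt$p_value - p_boot), 3 * se)
  sk <- skat_test(tr$y, tr$X, tr$G, cfg0, null_fit = nf)
  prep <- rarelogit:::region_prep(tr$y, tr$X, tr$G, cfg0, nf)
  p_boot2 <- boot_tail(prep$Bm, prep$pi0, sk$statistic, B = 1e5, seed = 3)
  se2 <- sqrt(p_boot2 * (1 - p_boot2) / 1e5)
  expect_lt(abs(sk$p_value - p_boot2), 3 * se2)
})
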