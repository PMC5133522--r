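#' Configuration for variant-collapsing tests
#'
#' @param weight_scheme `"beta"` (Beta-density MAF weights, the SKAT
#'   convention) or `"madsen-browning"` (inverse-binomial-SD weights).
#' @param a1,a2 Beta-density parameters; the default `Beta(1, 25)`
#'   up-weights rare variants steeply.
#' @param rho_grid SKAT-O correlation grid in \[0, 1\]; must contain 0
#'   (pure SKAT) and 1 (pure burden).
#' @param class_cutoffs MAF boundaries: rare `< cutoff[1]`,
#'   low-frequency `< cutoff[2]`, common otherwise.
#' @param adjust small-sample moment adjustment for burden/SKAT:
#'   `"auto"` applies it when `n < 2000` or the case fraction is below
#'   0.2; `"on"`/`"off"` force it.
#' @param B bootstrap replicates for the kurtosis estimate when the
#'   adjustment is active.
#' @param skato_method mixture-tail method inside the SKAT-O min-p
#'   integration: `"davies"` (default) or `"liu"` (faster, used by the
#'   replicate driver).
#' @return list of class `collapsing_config`.
#' @export
collapsing_config <- function(weight_scheme = c("beta", "madsen-browning"),
                              a1 = 1, a2 = 25,
                              rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1),
                              class_cutoffs = c(0.01, 0.05),
                              adjust = c("auto", "on", "off"),
                              B = 10000L,
                              skato_method = c("davies", "liu")) {
  weight_scheme <- match.arg(weight_scheme)
  adjust <- match.arg(adjust)
  skato_method <- match.arg(skato_method)
  if (any(rho_grid < 0 | rho_grid > 1))
    stop("rho_grid values must lie in [0, 1]")
  if (length(rho_grid) > 1 && (!(0 %in% rho_grid) || !(1 %in% rho_grid)))
    stop("a multi-point rho_grid must contain both endpoints 0 and 1")
  structure(list(weight_scheme = weight_scheme, a1 = a1, a2 = a2,
                 rho_grid = sort(unique(rho_grid)),
                 class_cutoffs = class_cutoffs, adjust = adjust,
                 B = as.integer(B), skato_method = skato_method),
            class = "collapsing_config")
}

#' MAF-based variant weights
#'
#' Beta scheme: \eqn{w_j = f_{Beta}(maf_j; a_1, a_2)}, so `Beta(1, 25)`
#' gives \eqn{25 (1 - maf)^{24}}. Madsen-Browning scheme:
#' \eqn{w_j = 1 / \sqrt{n p_j (1 - p_j)}}.
#'
#' @param mafs minor allele frequencies in `(0, 0.5]`; zero MAF is an
#'   error (filter monomorphic variants first).
#' @param scheme `"beta"` or `"madsen-browning"`.
#' @param a1,a2 Beta parameters.
#' @param n sample size (Madsen-Browning only).
#' @return positive weights.
#' @export
variant_weights <- function(mafs, scheme = c("beta", "madsen-browning"),
                            a1 = 1, a2 = 25, n = NULL) {
  scheme <- match.arg(scheme)
  if (any(mafs <= 0)) stop("MAF = 0: filter monomorphic variants first")
  if (any(mafs > 0.5)) stop("MAF must not exceed 0.5")
  if (scheme == "beta") {
    dbeta(mafs, a1, a2)
  } else {
    if (is.null(n)) stop("Madsen-Browning weights need the sample size n")
    1 / sqrt(n * mafs * (1 - mafs))
  }
}

# Shared per-region preparation: null fit pieces, covariate-residualized
# weighted genotypes, and the analytic moment ingredients.
region_prep <- function(y, X_null, G, cfg, null_fit = NULL) {
  X_null <- as.matrix(X_null)
  G <- as.matrix(G)
  y <- as.numeric(y)
  if (is.null(null_fit)) null_fit <- fit_mle(y, X_null)
  pi0 <- null_fit$fitted_probs
  w <- pi0 * (1 - pi0)
  mafs <- apply(G, 2L, compute_maf)
  keep <- mafs > 0
  G <- G[, keep, drop = FALSE]
  mafs <- mafs[keep]
  m <- ncol(G)
  if (m == 0L) return(NULL)
  wj <- variant_weights(mafs, scheme = cfg$weight_scheme, a1 = cfg$a1,
                        a2 = cfg$a2, n = nrow(G))
  XtWX <- crossprod(X_null * w, X_null)
  Gt <- G - X_null %*% solve(XtWX, crossprod(X_null * w, G))
  Bm <- Gt * rep(wj, each = nrow(Gt))       # residualized, weighted
  r <- y - pi0
  list(null_fit = null_fit, pi0 = pi0, w = w, r = r, mafs = mafs,
       wj = wj, G = G, Bm = Bm, m = m, kappa4 = w * (1 - 6 * w))
}

adjust_active <- function(cfg, y) {
  switch(cfg$adjust,
         on = TRUE, off = FALSE,
         auto = length(y) < 2000 || mean(y) < 0.2 || mean(y) > 0.8)
}

# parametric-bootstrap residual block: B columns of y* - pi0 with
# y*_i ~ Bernoulli(pi0_i).  Shared across the tests of one null fit so
# that identical variant sets yield identical adjusted p-values.
boot_resid <- function(pi0, B) {
  matrix(rbinom(length(pi0) * B, 1L, pi0), nrow = length(pi0)) - pi0
}

# bootstrap statistics Q* = column sums of squares of Bm'(y* - pi0)
boot_Qstar <- function(Bm, pi0, B, resid_boot = NULL) {
  if (!is.null(resid_boot)) {
    return(colSums(crossprod(Bm, resid_boot)^2))
  }
  n <- length(pi0)
  Q <- numeric(B)
  done <- 0L
  while (done < B) {
    nb <- min(500L, B - done)
    U <- crossprod(Bm, boot_resid(pi0, nb))         # m x nb
    Q[(done + 1L):(done + nb)] <- colSums(U^2)
    done <- done + nb
  }
  Q
}

#' MAF-weighted burden test
#'
#' Collapses the region into one score per individual,
#' \eqn{c_i = \sum_j w_j G_{ij}}, and applies the covariate-adjusted
#' score test to the collapsed variable; when the small-sample adjustment
#' is active the kurtosis-adjusted score test is used.  Powerful when
#' effects share a direction; protective and deleterious effects cancel
#' in the sum.
#'
#' @param y binary outcome.
#' @param X_null covariate design (with intercept).
#' @param G_region n x m dosage matrix of the region's variants.
#' @param cfg a [collapsing_config].
#' @param null_fit optional precomputed null [fit_mle].
#' @param seed optional seed for the adjustment bootstrap.
#' @param resid_boot optional precomputed bootstrap residual block
#'   (internal; lets several tests share one set of resamples).
#' @return one-row `test_result` (method `"burden"`).
#' @export
burden_test <- function(y, X_null, G_region, cfg = collapsing_config(),
                        null_fit = NULL, seed = NULL, resid_boot = NULL) {
  prep <- region_prep(y, X_null, G_region, cfg, null_fit)
  if (is.null(prep))
    return(test_result(method = "burden", statistic = 0, p_value = 1,
                       status = "fallback"))
  collapsed <- prep$G %*% prep$wj
  if (all(abs(collapsed - collapsed[1]) < 1e-12))
    return(test_result(method = "burden", statistic = 0, p_value = 1,
                       status = "fallback"))
  sc <- score_components(y, X_null, as.numeric(collapsed),
                         null_fit = prep$null_fit)
  res <- if (adjust_active(cfg, y)) {
    if (!is.null(seed)) set.seed(seed)
    Qstar <- if (is.null(resid_boot)) NULL
             else as.numeric(crossprod(sc$g_adj, resid_boot))^2
    adjusted_score_test(sc, adjust = "variance+kurtosis", B = cfg$B,
                        Qstar = Qstar)
  } else {
    standard_score_test(sc)
  }
  res$method <- "burden"
  res
}

#' Sequence kernel association test (SKAT)
#'
#' Variance-component score test with statistic
#' \eqn{Q = (y - \hat\pi_0)' G W^2 G' (y - \hat\pi_0)},
#' \eqn{W = diag(w_j)}; its null distribution is the chi-square mixture
#' whose weights are the eigenvalues of the covariate-projected weighted
#' kernel.  Robust to mixed effect directions.  When the small-sample
#' adjustment is active, the reference distribution is moment-matched
#' with analytic mean/variance and bootstrap kurtosis instead of the
#' asymptotic mixture.
#'
#' @inheritParams burden_test
#' @return one-row `test_result` (method `"skat"`); `df_or_params` holds
#'   the eigenvalues and the p-value path (`davies`/`liu`/`moment`).
#' @inheritParams burden_test
#' @export
skat_test <- function(y, X_null, G_region, cfg = collapsing_config(),
                      null_fit = NULL, seed = NULL, resid_boot = NULL) {
  prep <- region_prep(y, X_null, G_region, cfg, null_fit)
  if (is.null(prep))
    return(test_result(method = "skat", statistic = 0, p_value = 1,
                       status = "fallback"))
  U <- as.numeric(crossprod(prep$Bm, prep$r))
  Q <- sum(U^2)
  K <- crossprod(prep$Bm * sqrt(prep$w))          # m x m
  lambda <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > 1e-10 * max(lambda)]
  if (length(lambda) == 0L)
    return(test_result(method = "skat", statistic = Q, p_value = 1,
                       status = "fallback"))
  if (adjust_active(cfg, y)) {
    if (!is.null(seed)) set.seed(seed)
    mu_Q <- sum(lambda)
    a_ii <- rowSums(prep$Bm^2)
    sigma_Q <- sqrt(2 * sum(lambda^2) + sum(a_ii^2 * prep$kappa4))
    Qstar <- boot_Qstar(prep$Bm, prep$pi0, cfg$B, resid_boot)
    gamma_hat <- excess_kurtosis(Qstar)
    status <- "converged"
    if (!is.finite(gamma_hat) || gamma_hat <= 0) {
      df <- 1e5; status <- "fallback"
    } else df <- min(max(12 / gamma_hat, 0.5), 1e5)
    stat <- (Q - mu_Q) / sigma_Q * sqrt(2 * df) + df
    return(test_result(method = "skat", statistic = Q,
                       p_value = pchisq(stat, df = df, lower.tail = FALSE),
                       df_or_params = list(lambda = lambda, path = "moment",
                                           mu_Q = mu_Q, sigma_Q = sigma_Q,
                                           gamma_hat = gamma_hat, df = df),
                       status = status))
  }
  pv <- chisqmix_pvalue(Q, lambda)
  test_result(method = "skat", statistic = Q, p_value = pv$p,
              df_or_params = list(lambda = lambda, path = pv$path))
}

#' Optimal unified burden/SKAT test (SKAT-O)
#'
#' Evaluates \eqn{Q_\rho = (1-\rho) Q_{SKAT} + \rho Q_{burden}} over the
#' configured \eqn{\rho} grid, takes the minimum p-value over the grid,
#' and computes the final p-value by one-dimensional numerical
#' integration of the null distribution of the minimum-p statistic
#' (decomposition into a common one-df component plus an independent
#' chi-square mixture).  The final p-value is capped at
#' `length(rho_grid)` times the minimum per-rho p (the Bonferroni
#' bound).
#'
#' @inheritParams burden_test
#' @return one-row `test_result` (method `"skato"`); `df_or_params`
#'   holds the per-rho p-values.
#' @export
skato_test <- function(y, X_null, G_region, cfg = collapsing_config(),
                       null_fit = NULL, seed = NULL) {
  prep <- region_prep(y, X_null, G_region, cfg, null_fit)
  if (is.null(prep))
    return(test_result(method = "skato", statistic = 0, p_value = 1,
                       status = "fallback"))
  grid <- cfg$rho_grid
  # endpoint-only grids reduce exactly
  if (length(grid) == 1L || prep$m == 1L) {
    use_burden <- length(grid) == 1L && grid[1] >= 0.999
    res <- if (use_burden) {
      burden_test(y, X_null, G_region, cfg, null_fit = prep$null_fit,
                  seed = seed)
    } else {
      skat_test(y, X_null, G_region, cfg, null_fit = prep$null_fit,
                seed = seed)
    }
    res$method <- "skato"
    return(res)
  }
  pfun <- function(q, lambda, accuracy = 1e-9) {
    if (cfg$skato_method == "davies")
      chisqmix_pvalue(q, lambda, accuracy = accuracy)$p
    else liu_pvalue(q, lambda)
  }
  m <- prep$m
  U <- as.numeric(crossprod(prep$Bm, prep$r))
  Q_skat <- sum(U^2)
  Q_burden <- sum(U)^2
  grid_eff <- pmin(grid, 0.999)   # rho = 1 is singular in the mixture algebra
  Z <- prep$Bm * sqrt(prep$w)     # n x m; U ~ Z' u with u std normal
  p_rho <- numeric(length(grid))
  liu_par <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    rho <- grid_eff[i]
    Q_rho <- (1 - rho) * Q_skat + rho * Q_burden
    # symmetric sqrt of R_rho = (1-rho) I + rho J
    s1 <- sqrt(1 - rho)
    s2 <- sqrt(1 - rho + m * rho)
    Zr <- s1 * Z + ((s2 - s1) / m) * (Z %*% matrix(1, m, m))
    Kr <- crossprod(Zr)
    lam <- eigen(Kr, symmetric = TRUE, only.values = TRUE)$values
    lam <- lam[lam > 1e-10 * max(lam)]
    p_rho[i] <- pfun(Q_rho, lam)
    liu_par[[i]] <- list(lambda = lam, Q = Q_rho)
  }
  Tmin <- min(p_rho)
  # Null decomposition: Z u = common component along rowMeans(Z) + remainder
  z_mean <- rowMeans(Z)
  zm2 <- sum(z_mean^2)
  if (zm2 <= 0) {
    res <- skat_test(y, X_null, G_region, cfg, null_fit = prep$null_fit)
    res$method <- "skato"
    return(res)
  }
  cof1 <- as.numeric(crossprod(z_mean, Z)) / zm2
  Z1 <- outer(z_mean, cof1)
  Z2 <- Z - Z1
  K22 <- crossprod(Z2)
  lambda2 <- eigen(K22, symmetric = TRUE, only.values = TRUE)$values
  lambda2 <- lambda2[lambda2 > 1e-10 * max(abs(lambda2))]
  var_remain <- 4 * sum(crossprod(Z1) * K22)
  mu_Q <- sum(lambda2)
  var_Q <- 2 * sum(lambda2^2) + var_remain
  tau <- (m^2 * grid_eff + (1 - grid_eff) * sum(cof1^2)) * zm2
  # per-rho quantiles of Q_rho at tail prob Tmin (Liu inverse)
  q_min <- vapply(seq_along(grid), function(i) {
    lam <- liu_par[[i]]$lambda
    c1 <- sum(lam); c2 <- sum(lam^2); c3 <- sum(lam^3); c4 <- sum(lam^4)
    s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
    if (s1^2 > s2) {
      a <- 1 / (s1 - sqrt(s1^2 - s2)); d <- s1 * a^3 - a^2; l <- a^2 - 2 * d
    } else { l <- 1 / s2; a <- sqrt(l); d <- 0 }
    q_org <- qchisq(Tmin, df = l, ncp = d, lower.tail = FALSE)
    (q_org - (l + d)) / (sqrt(2) * a) * sqrt(2 * c2) + c1
  }, numeric(1))
  sd_ratio <- sqrt(max(var_Q - var_remain, 0)) / sqrt(var_Q)
  integrand <- function(x) {
    vapply(x, function(xi) {
      min1 <- min((q_min - tau * xi) / (1 - grid_eff))
      surv <- if (min1 > sum(lambda2) * 1e4) {
        0
      } else {
        min1_st <- (min1 - mu_Q) * sd_ratio + mu_Q
        if (min1_st <= 0) {
          1
        } else {
          # tail quantiles make the CF inversion oscillate over hundreds of
          # periods while contributing (1 - o(1)) * dchisq to the integral;
          # the moment match serves there (local error < 1e-3, weighted by
          # little chi-square mass), the inversion where it matters
          pl <- liu_pvalue(min1_st, lambda2)
          if (pl < 1e-2) pl else pfun(min1_st, lambda2, accuracy = 1e-6)
        }
      }
      (1 - surv) * dchisq(xi, df = 1)
    }, numeric(1))
  }
  int <- tryCatch(
    integrate(integrand, lower = 0, upper = 40, subdivisions = 2000L,
              abs.tol = 1e-25, stop.on.error = FALSE)$value,
    error = function(e) NA_real_)
  p_final <- 1 - int
  path <- cfg$skato_method
  if (!is.finite(p_final) || p_final <= 0) {
    p_final <- Tmin * length(grid)
    path <- "bonferroni"
  }
  p_final <- min(p_final, Tmin * length(grid), 1)
  test_result(method = "skato", statistic = Tmin, p_value = p_final,
              df_or_params = list(rho_grid = grid, p_rho = p_rho,
                                  path = path))
}

#' Region tests by variant frequency class
#'
#' For each subregion of a partition, restricts the genotype columns to
#' the selected MAF class(es) and runs the requested collapsing tests,
#' emitting one result row per (subregion, class, method).  Subregions
#' with no variant in a class are skipped with a notice.
#'
#' @param y binary outcome (complete cases).
#' @param X_null covariate design matrix.
#' @param gm [genotype_matrix] already subset to the analyzed samples.
#' @param partition a [partition_by_position] result.
#' @param classes subset of `c("rare", "rare+low-frequency", "all")`.
#' @param methods subset of `c("burden", "skat", "skato")`.
#' @param cfg a [collapsing_config].
#' @param null_fit optional precomputed null fit.
#' @param seed optional seed for adjustment bootstraps.
#' @return data frame with columns `target` (subregion), `class`,
#'   `method`, `statistic`, `p_value`, `status`.
#' @export
test_region_by_class <- function(y, X_null, gm, partition,
                                 classes = c("rare", "rare+low-frequency", "all"),
                                 methods = c("burden", "skat", "skato"),
                                 cfg = collapsing_config(), null_fit = NULL,
                                 seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  classes <- match.arg(classes, several.ok = TRUE)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(null_fit)) null_fit <- fit_mle(y, X_null)
  vclass <- variant_class(gm$variants$maf, cfg$class_cutoffs)
  # one bootstrap residual block for the whole battery: tests over the
  # same variant set (e.g. identical class selections) get identical
  # adjusted p-values, and the resampling cost is paid once
  resid_boot <- if (adjust_active(cfg, y) &&
                    any(c("burden", "skat") %in% methods)) {
    if (!is.null(seed)) set.seed(seed)
    boot_resid(null_fit$fitted_probs, cfg$B)
  } else NULL
  out <- list()
  for (k in seq_len(partition$K)) {
    in_region <- partition$assignments == k
    for (cl in classes) {
      sel <- switch(cl,
        "rare" = in_region & vclass == "rare",
        "rare+low-frequency" = in_region & vclass %in% c("rare", "low-frequency"),
        "all" = in_region)
      if (!any(sel)) {
        message(sprintf("subregion %d: no variants in class '%s'; skipped", k, cl))
        next
      }
      G <- gm$dosages[, sel, drop = FALSE]
      for (mth in methods) {
        res <- switch(mth,
          burden = burden_test(y, X_null, G, cfg, null_fit,
                               resid_boot = resid_boot),
          skat = skat_test(y, X_null, G, cfg, null_fit,
                           resid_boot = resid_boot),
          skato = skato_test(y, X_null, G, cfg, null_fit, seed = seed))
        res$target <- as.character(k)
        res$class <- cl
        out[[length(out) + 1L]] <- res
      }
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, lapply(out, function(d) {
    d[, c("target", "class", "method", "statistic", "p_value", "status")]
  }))
}
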