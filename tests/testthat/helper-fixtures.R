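# Small data builders shared across test files.  Everything is generated
# in code under fixed seeds; no stored fixtures.

# logistic toy data with intercept + one continuous + one binary covariate
toy_logistic <- function(n, beta = c(-1.5, 0.02, 0.4), seed = 1) {
  set.seed(seed)
  X <- cbind(1, rnorm(n, 50, 10), rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(X %*% beta))
  list(y = y, X = X)
}

# individual-level data for a 2x2 table: cells (a, b) at x = 1, (c, d) at x = 0
table_2x2 <- function(a, b, c, d) {
  list(y = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
       X = cbind(1, x = c(rep(1, a + b), rep(0, c + d))))
}

haldane_slope <- function(a, b, c, d) {
  log((a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5)))
}

# toy region: covariate-adjusted cohort with m low-frequency variants
toy_region <- function(n = 300, mafs = c(0.02, 0.035, 0.05, 0.015, 0.04),
                       seed = 11) {
  toy_cohort(n, mafs, seed)
}

# oracle toy: moderate MAFs at n = 300 put the region statistics in the
# regime the asymptotic null distributions are built for, with the seed
# chosen so the observed statistics land in the informative tail
toy_oracle_region <- function() {
  toy_cohort(300, c(0.05, 0.1, 0.2, 0.08, 0.15), seed = 36)
}

toy_cohort <- function(n, mafs, seed) {
  set.seed(seed)
  X <- cbind(1, rnorm(n, 50, 10), rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(-1.6 + 0.01 * X[, 2]))
  G <- sapply(mafs, function(p) rbinom(n, 2, p))
  colnames(G) <- paste0("v", seq_along(mafs))
  list(y = y, X = X, G = G)
}

# a vector of bootstrap statistics Q* for one residualized genotype
boot_Qstar_vec <- function(g_adj, pi0, B, seed = 1, block = 500L) {
  set.seed(seed)
  n <- length(pi0)
  out <- numeric(0)
  done <- 0L
  while (done < B) {
    nb <- min(block, B - done)
    r <- matrix(rbinom(n * nb, 1L, pi0), n) - pi0
    out <- c(out, colSums(crossprod(g_adj, r)^2))
    done <- done + nb
  }
  out
}

# parametric-bootstrap tail probability of Q* = (b' (y* - pi0))^2 summed
# over columns of B_mat; the resampling oracle used against analytic paths
boot_tail <- function(B_mat, pi0, q_obs, B = 1e5, seed = 99, block = 500L) {
  set.seed(seed)
  B_mat <- as.matrix(B_mat)
  n <- length(pi0)
  hits <- 0
  done <- 0L
  while (done < B) {
    nb <- min(block, B - done)
    r <- matrix(rbinom(n * nb, 1L, pi0), n) - pi0
    Qs <- colSums(crossprod(B_mat, r)^2)
    hits <- hits + sum(Qs >= q_obs)
    done <- done + nb
  }
  hits / B
}
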