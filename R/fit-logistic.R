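#' Logistic regression by maximum likelihood
#'
#' Iteratively reweighted least squares for the logistic model
#' \eqn{logit P(y=1|x) = x'\beta}.  Under complete or quasi-complete
#' separation the MLE is infinite; the fit is then flagged
#' (`converged = FALSE`, `separated = TRUE`) rather than silently
#' returned, mirroring the known failure mode of standard logistic
#' regression on sparse genotype data.
#'
#' @param y binary 0/1 response vector.
#' @param X design matrix including an intercept column; `n >= ncol(X)`.
#' @param maxit iteration cap (25, the conventional IRLS cap).
#' @return An object of class `model_fit`: list with `coefficients`,
#'   `loglik`, `penalized_loglik` (`NA` for a plain MLE), `fitted_probs`,
#'   `information` (Fisher information at the estimate), `converged`,
#'   `separated`, `n_iter`.
#' @export
fit_mle <- function(y, X, maxit = 25L) {
  xy <- check_design(y, X)
  f <- .cpp_logistic_mle(xy$X, xy$y, maxit = maxit, tol = 1e-10)
  if (!f$ok) stop("logistic MLE failed numerically (singular information)")
  new_model_fit(f, xy$X, penalized = FALSE)
}

#' Firth-penalized logistic regression
#'
#' Maximizes the Jeffreys-penalized log-likelihood
#' \eqn{l_p(\beta) = l(\beta) + \frac12 \log|i(\beta)|}, the
#' generalization of Haldane's add-half correction for sparse 2x2
#' tables; estimates are finite for any full-rank design, including
#' separated data.  Solves the modified score equations in which each
#' observation's working residual is
#' \eqn{y_i - \pi_i + h_i(\frac12 - \pi_i)} with \eqn{h_i} the leverage
#' of the weighted design.
#'
#' With `constrained`, the listed coefficients are held fixed while the
#' remaining ones maximize the penalized likelihood of the FULL design
#' (profile convention: the penalty keeps the full information matrix).
#'
#' @inheritParams fit_mle
#' @param constrained optional named list `list(index =, value =)` of
#'   coefficient positions to hold fixed and their values.
#' @param maxit iteration cap (default 500) with step-halving on
#'   penalized-likelihood decrease.
#' @return A `model_fit` (see [fit_mle]); `penalized_loglik` is
#'   \eqn{l_p} at the optimum.
#' @export
fit_firth <- function(y, X, constrained = NULL, maxit = 500L) {
  xy <- check_design(y, X)
  p <- ncol(xy$X)
  init <- numeric(p)
  ybar <- mean(xy$y)
  if (all(xy$X[, 1] == 1)) init[1] <- qlogis((ybar * length(xy$y) + 0.5) /
                                               (length(xy$y) + 1))
  free <- seq_len(p)
  if (!is.null(constrained)) {
    idx <- as.integer(constrained$index)
    if (any(idx < 1L | idx > p)) stop("constrained index out of range")
    init[idx] <- as.numeric(constrained$value)
    free <- setdiff(free, idx)
    if (length(free) == 0L) stop("no free coefficients left")
  }
  f <- .cpp_logistic_firth(xy$X, xy$y, free_idx = free - 1L,
                           beta_init = init, maxit = maxit)
  if (!f$ok) stop("Firth fit failed numerically (singular information)")
  new_model_fit(f, xy$X, penalized = TRUE)
}

# shared design validation; errors name the collinear column
check_design <- function(y, X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X; subset first")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (nrow(X) < ncol(X)) stop("more coefficients than observations")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- qx$pivot[(qx$rank + 1L):ncol(X)]
    nms <- colnames(X) %||% paste0("column ", seq_len(ncol(X)))
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(nms[bad], collapse = ", "))
  }
  list(y = y, X = X)
}

new_model_fit <- function(f, X, penalized) {
  pi_hat <- as.numeric(f$fitted)
  w <- pi_hat * (1 - pi_hat)
  info <- crossprod(X * w, X)
  beta <- as.numeric(f$beta)
  names(beta) <- colnames(X)
  structure(list(
    coefficients = beta,
    loglik = f$loglik,
    penalized_loglik = if (penalized) f$penloglik else NA_real_,
    information = info,
    fitted_probs = pi_hat,
    converged = f$converged,
    separated = f$separated,
    n_iter = f$iter,
    penalized = penalized
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  kind <- if (x$penalized) "Firth-penalized logistic fit" else "logistic MLE"
  cat(sprintf("<model_fit> %s, %d coefficients\n", kind,
              length(x$coefficients)))
  print(round(x$coefficients, 6))
  cat(sprintf("  loglik %.6f%s  converged: %s%s\n", x$loglik,
              if (x$penalized) sprintf("  penalized %.6f", x$penalized_loglik) else "",
              x$converged, if (x$separated) "  [separation detected]" else ""))
  invisible(x)
}

#' Likelihood-ratio test of nested logistic fits
#'
#' @param full,null `model_fit` objects for the full and nested null model
#'   (both plain MLE fits).
#' @param df degrees of freedom (number of constrained coefficients).
#' @return A one-row `test_result` data frame with `statistic`
#'   (\eqn{2(l_{full} - l_{null})}) and the chi-square p-value.
#' @export
lr_test <- function(full, null, df = 1L) {
  stat <- 2 * (full$loglik - null$loglik)
  if (stat < -1e-6)
    stop("negative LR statistic: models not nested or fits not converged")
  stat <- max(stat, 0)
  status <- if (isTRUE(full$converged) && isTRUE(null$converged))
    "converged" else "fallback"
  test_result(method = "lrt", statistic = stat,
              p_value = pchisq(stat, df = df, lower.tail = FALSE),
              df_or_params = list(df = df), status = status)
}

#' Penalized likelihood-ratio test for one genotype coefficient
#'
#' Firth-type penalized LR test: twice the difference between the
#' penalized log-likelihood at the unconstrained Firth optimum and at the
#' optimum with the genotype coefficient fixed at zero, referred to
#' chi-square with 1 df.  By default both evaluations keep the full
#' design's information matrix in the penalty (profile convention);
#' `penalty = "reduced"` instead refits the reduced design with its own
#' (smaller) information matrix.
#'
#' @inheritParams fit_mle
#' @param test_index column of `X` holding the genotype coefficient under
#'   test (default: last column).
#' @param penalty `"profile"` (default) or `"reduced"`.
#' @return A one-row `test_result` data frame.
#' @export
penalized_lr_test <- function(y, X, test_index = ncol(as.matrix(X)),
                              penalty = c("profile", "reduced")) {
  penalty <- match.arg(penalty)
  X <- as.matrix(X)
  full <- fit_firth(y, X)
  if (penalty == "profile") {
    null <- fit_firth(y, X, constrained = list(index = test_index, value = 0))
    lp0 <- null$penalized_loglik
  } else {
    null <- fit_firth(y, X[, -test_index, drop = FALSE])
    lp0 <- null$penalized_loglik
  }
  stat <- 2 * (full$penalized_loglik - lp0)
  if (stat < -1e-6)
    stop("negative penalized LR statistic: constrained fit not converged")
  stat <- max(stat, 0)
  status <- if (isTRUE(full$converged) && isTRUE(null$converged))
    "converged" else "fallback"
  test_result(method = "plrt", statistic = stat,
              p_value = pchisq(stat, df = 1, lower.tail = FALSE),
              df_or_params = list(df = 1, penalty = penalty), status = status)
}

# uniform one-row result container shared by every test in the package
test_result <- function(method, statistic, p_value, df_or_params = list(),
                        status = "converged", target = NA_character_) {
  out <- data.frame(target = target, method = method,
                    statistic = statistic, p_value = p_value,
                    status = status, stringsAsFactors = FALSE)
  attr(out, "df_or_params") <- df_or_params
  class(out) <- c("test_result", class(out))
  out
}
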