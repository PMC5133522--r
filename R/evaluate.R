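SV_METHODS <- c("lrt", "plrt", "score", "score_var_adj", "score_kurt_adj")
REGION_METHODS <- c("burden", "skat", "skato")

# Fast per-replicate single-variant battery.  One null fit is shared by all
# variants; the likelihood tests run through the compiled battery; the score
# family is fully vectorized across variants; the kurtosis adjustment reuses
# one parametric-bootstrap residual block for every variant.
sv_battery <- function(y, Xc, G, methods = SV_METHODS, B = 1000L) {
  y <- as.numeric(y)
  Xc <- as.matrix(Xc)
  G <- as.matrix(G)
  m <- ncol(G)
  out <- list()
  need_lik <- any(c("lrt", "plrt") %in% methods)
  need_score <- any(c("score", "score_var_adj", "score_kurt_adj") %in% methods)
  null_mle <- fit_mle(y, Xc)
  if (need_lik) {
    null_firth <- fit_firth(y, Xc)
    bt <- .cpp_sv_battery(Xc, y, G, null_firth$coefficients,
                          null_mle$coefficients)
    if ("lrt" %in% methods) {
      stat <- pmax(2 * (bt[, 1] - null_mle$loglik), 0)
      out$lrt <- data.frame(
        method = "lrt", variant = seq_len(m), statistic = stat,
        p_value = pchisq(stat, 1, lower.tail = FALSE),
        status = ifelse(is.na(bt[, 1]), "failed",
                 ifelse(bt[, 2] == 1, "converged", "fallback")),
        stringsAsFactors = FALSE)
    }
    if ("plrt" %in% methods) {
      stat <- pmax(2 * (bt[, 4] - bt[, 5]), 0)
      out$plrt <- data.frame(
        method = "plrt", variant = seq_len(m), statistic = stat,
        p_value = pchisq(stat, 1, lower.tail = FALSE),
        status = ifelse(is.na(bt[, 4]) | is.na(bt[, 5]), "failed",
                 ifelse(bt[, 6] == 1, "converged", "fallback")),
        stringsAsFactors = FALSE)
    }
  }
  if (need_score) {
    pi0 <- null_mle$fitted_probs
    w <- pi0 * (1 - pi0)
    XtWX <- crossprod(Xc * w, Xc)
    Gt <- G - Xc %*% solve(XtWX, crossprod(Xc * w, G))
    r <- y - pi0
    U <- as.numeric(crossprod(Gt, r))
    V <- colSums(w * Gt^2)
    ok <- V > .Machine$double.eps * length(y)
    if ("score" %in% methods) {
      stat <- ifelse(ok, U^2 / pmax(V, 1e-300), 0)
      out$score <- data.frame(
        method = "score", variant = seq_len(m), statistic = stat,
        p_value = ifelse(ok, pchisq(stat, 1, lower.tail = FALSE), 1),
        status = ifelse(ok, "converged", "fallback"),
        stringsAsFactors = FALSE)
    }
    if (any(c("score_var_adj", "score_kurt_adj") %in% methods)) {
      kap4 <- w * (1 - 6 * w)
      Q <- U^2
      mu_Q <- V
      sigma_Q <- sqrt(pmax(2 * V^2 + colSums(Gt^4 * kap4), 1e-300))
      if ("score_var_adj" %in% methods) {
        stat <- (Q - mu_Q) / sigma_Q * sqrt(2) + 1
        out$score_var_adj <- data.frame(
          method = "score_var_adj", variant = seq_len(m), statistic = Q,
          p_value = ifelse(ok, pchisq(stat, 1, lower.tail = FALSE), 1),
          status = ifelse(ok, "converged", "fallback"),
          stringsAsFactors = FALSE)
      }
      if ("score_kurt_adj" %in% methods) {
        # exact kurtosis of each variant's Q under the resampling law:
        # the closed-form limit of the parametric bootstrap, noise-free
        gam <- analytic_Q_kurtosis(Gt, pi0)
        df <- ifelse(is.finite(gam) & gam > 0,
                     pmin(pmax(12 / gam, 0.5), 1e5), 1e5)
        stat <- (Q - mu_Q) / sigma_Q * sqrt(2 * df) + df
        out$score_kurt_adj <- data.frame(
          method = "score_kurt_adj", variant = seq_len(m), statistic = Q,
          p_value = ifelse(ok, pchisq(stat, df = df, lower.tail = FALSE), 1),
          status = ifelse(!ok, "fallback",
                   ifelse(is.finite(gam) & gam > 0, "converged", "fallback")),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out[methods[methods %in% names(out)]])
}

#' Run phenotype replicates of the simulation design
#'
#' Generates the cohort's genotypes and covariates once from the spec,
#' then regenerates phenotypes `R` times (null Gaussian-dichotomized
#' trait, or the alternative logistic model) with per-replicate seeds
#' `base_seed + r`, running the requested single-variant and/or
#' region-level tests on the complete-case subsample each time.
#'
#' @param spec a [simulation_spec].
#' @param methods character vector from `lrt`, `plrt`, `score`,
#'   `score_var_adj`, `score_kurt_adj` (single-variant) and `burden`,
#'   `skat`, `skato` (region-level).
#' @param R number of phenotype replicates.
#' @param scenario `"null"` or `"alternative"`.
#' @param base_seed integer; replicate `r` uses seed `base_seed + r`.
#' @param B bootstrap size for the kurtosis adjustments inside the loop.
#' @param classes variant-class selectors for the region tests.
#' @param cfg a [collapsing_config] for the region tests; its
#'   `skato_method` defaults to `"liu"` here for throughput.
#' @param regions optional integer vector restricting which subregions
#'   are tested (default: all).
#' @param verbose print progress every 100 replicates.
#' @return A `replicate_results` object: data frame with columns
#'   `replicate`, `target`, `class`, `method`, `p_value`, `status`, and
#'   attributes `variants` (metadata incl. complete-case MAC~),
#'   `scenario`, `base_seed`, `R`, `manifest`.
#' @export
run_replicates <- function(spec, methods = SV_METHODS, R = 200L,
                           scenario = c("null", "alternative"),
                           base_seed = 2016L, B = 1000L,
                           classes = c("rare", "rare+low-frequency", "all"),
                           cfg = NULL, regions = NULL, verbose = FALSE) {
  scenario <- match.arg(scenario)
  stopifnot(R >= 1)
  sv_methods <- intersect(methods, SV_METHODS)
  rg_methods <- intersect(methods, REGION_METHODS)
  if (is.null(cfg))
    cfg <- collapsing_config(B = B, skato_method = "liu")
  gm <- gen_genotypes(spec, spec$seed)
  gm <- filter_polymorphic(gm)
  partition <- spec_partition(spec)
  keep_var <- match(gm$variants$id, spec$variants$id)
  part_poly <- structure(list(assignments = partition$assignments[keep_var],
                              K = partition$K), class = "subregion_partition")
  # covariates (and hence the complete-case mask) are deterministic per spec
  cov <- gen_covariates(spec)
  mask <- !is.na(cov$age_obs)
  gm_cc <- subset_samples(gm, mask)
  Xc <- cbind(`(Intercept)` = 1, age = cov$age[mask], sex = cov$sex[mask])
  G <- gm_cc$dosages
  res <- vector("list", R)
  for (r in seq_len(R)) {
    seed_r <- base_seed + r
    pt <- if (scenario == "null") gen_null_phenotypes(spec, gm, seed_r)
          else gen_alt_phenotypes(spec, gm, seed_r)
    y <- pt$outcome[mask]
    pieces <- list()
    if (length(sv_methods)) {
      sv <- sv_battery(y, Xc, G, methods = sv_methods, B = B)
      pieces$sv <- data.frame(replicate = r,
                              target = gm_cc$variants$id[sv$variant],
                              class = NA_character_, method = sv$method,
                              p_value = sv$p_value, status = sv$status,
                              stringsAsFactors = FALSE)
    }
    if (length(rg_methods)) {
      part_use <- part_poly
      gm_use <- gm_cc
      if (!is.null(regions)) {
        sel <- part_poly$assignments %in% regions
        gm_use <- genotype_matrix(gm_cc$dosages[, sel, drop = FALSE],
                                  sample_ids = gm_cc$sample_ids,
                                  variants = gm_cc$variants[sel,
                                    c("id", "chrom", "pos", "functional")])
        part_use <- structure(list(assignments = part_poly$assignments[sel],
                                   K = part_poly$K),
                              class = "subregion_partition")
      }
      rg <- suppressMessages(
        test_region_by_class(y, Xc, gm_use, part_use, classes = classes,
                             methods = rg_methods, cfg = cfg))
      if (!is.null(rg)) {
        pieces$rg <- data.frame(replicate = r, target = rg$target,
                                class = rg$class, method = rg$method,
                                p_value = rg$p_value, status = rg$status,
                                stringsAsFactors = FALSE)
      }
    }
    res[[r]] <- do.call(rbind, pieces)
    if (verbose && r %% 100 == 0)
      message(sprintf("replicate %d / %d", r, R))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  vinfo <- gm_cc$variants
  vinfo$subregion <- part_poly$assignments
  structure(out, class = c("replicate_results", class(out)),
            variants = vinfo, scenario = scenario, base_seed = base_seed,
            R = R, n_complete = sum(mask),
            manifest = list(base_seed = base_seed,
                            replicate_seeds = base_seed + seq_len(R),
                            spec_seed = spec$seed, n = spec$n, R = R,
                            scenario = scenario, B = B,
                            version = as.character(packageVersion("rarelogit"))))
}

#' Re-run a single replicate from its manifest seed
#'
#' Reproduces one replicate of [run_replicates] in isolation: replicate
#' `r` depends only on the spec and `base_seed + r`, so its p-values are
#' regenerated bit-for-bit.
#'
#' @inheritParams run_replicates
#' @param replicate replicate index `r`.
#' @return the replicate's rows, as from [run_replicates].
#' @export
regenerate_replicate <- function(spec, replicate, methods = SV_METHODS,
                                 scenario = c("null", "alternative"),
                                 base_seed = 2016L, B = 1000L,
                                 classes = c("rare", "rare+low-frequency", "all"),
                                 cfg = NULL, regions = NULL) {
  rr <- run_replicates(spec, methods = methods, R = 1L,
                       scenario = match.arg(scenario),
                       base_seed = base_seed + replicate - 1L, B = B,
                       classes = classes, cfg = cfg, regions = regions)
  rr$replicate <- replicate
  rr
}

#' Pool null rejection rates by carrier count
#'
#' Groups the null-scenario single-variant results by the variants'
#' carrier count \eqn{\tilde{MAC}} (computed on the analyzed
#' complete-case sample) and reports, per method and group, the
#' proportion of p-values below `alpha` together with the binomial
#' simulation error half-width \eqn{2\sqrt{\alpha(1-\alpha)/N}} where
#' `N = R x` (variants in the group).
#'
#' @param rr a `replicate_results` object (null scenario).
#' @param alpha significance level (default 0.01).
#' @param breaks optional numeric cut points for binned (rather than
#'   exact-integer) MAC~ grouping.
#' @return data frame with `method`, `mac_tilde` (or bin label), `rate`,
#'   `N`, `half_width`.
#' @export
pool_type1_by_mac <- function(rr, alpha = 0.01, breaks = NULL) {
  v <- attr(rr, "variants")
  sv <- rr[is.na(rr$class) & rr$status != "failed", ]
  mac <- v$mac_tilde[match(sv$target, v$id)]
  grp <- if (is.null(breaks)) as.character(mac)
         else as.character(cut(mac, breaks = breaks, include.lowest = TRUE))
  agg <- aggregate(sv$p_value < alpha,
                   by = list(method = sv$method, group = grp),
                   FUN = function(z) c(rate = mean(z), N = length(z)))
  out <- data.frame(method = agg$method, mac_tilde = agg$group,
                    rate = agg$x[, "rate"], N = agg$x[, "N"],
                    stringsAsFactors = FALSE)
  out$half_width <- 2 * sqrt(alpha * (1 - alpha) / out$N)
  if (is.null(breaks)) {
    out <- out[order(out$method, as.numeric(out$mac_tilde)), ]
    out$mac_tilde <- as.numeric(out$mac_tilde)
  }
  rownames(out) <- NULL
  out
}

#' Empirical power (rejection rate) per target
#'
#' For each target (variant, or subregion x class), method and
#' significance level, the proportion of replicates with `p < alpha`.
#' On null-scenario input this is the empirical size.
#'
#' @param rr a `replicate_results` object.
#' @param alphas significance levels (defaults: the conventional 0.01 and
#'   0.05 plus the exome-wide 1e-6 and genome-wide 5e-8).
#' @return data frame with `target`, `class`, `method`, `alpha`, `power`,
#'   `R` (replicates contributing).
#' @export
power_by_target <- function(rr, alphas = c(0.01, 0.05, 1e-6, 5e-8)) {
  ok <- rr[rr$status != "failed", ]
  cls <- ifelse(is.na(ok$class), "", ok$class)
  out <- list()
  for (a in alphas) {
    agg <- aggregate(ok$p_value < a,
                     by = list(target = ok$target, class = cls,
                               method = ok$method),
                     FUN = function(z) c(power = mean(z), R = length(z)))
    out[[length(out) + 1L]] <- data.frame(
      target = agg$target,
      class = ifelse(agg$class == "", NA_character_, agg$class),
      method = agg$method,
      alpha = a, power = agg$x[, "power"], R = agg$x[, "R"],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Quantile-quantile coordinates for p-values
#'
#' Sorted observed p-values against expected uniform quantiles
#' `(i - 0.5) / n`, both on the `-log10` scale (plot-ready).  Zero
#' p-values are clamped to `1 / (10 n)` with a warning.
#'
#' @param pvals vector of p-values.
#' @return data frame with columns `expected` and `observed`
#'   (`-log10` scale).
#' @export
qq_points <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) == 0L) stop("no p-values supplied")
  n <- length(pvals)
  if (any(pvals == 0)) {
    warning("p-values of 0 clamped to 1/(10n) for the -log10 scale")
    pvals[pvals == 0] <- 1 / (10 * n)
  }
  data.frame(expected = -log10((seq_len(n) - 0.5) / n),
             observed = -log10(sort(pvals)))
}

#' Bonferroni multiple-testing adjustment
#'
#' `min(1, m * p)` within the declared test family (all polymorphic
#' variants for the single-variant family; the K subregions for the
#' region family).
#'
#' @param pvals raw p-values.
#' @param m family size (defaults to `length(pvals)`).
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(pvals, m = length(pvals)) {
  pmin(1, m * pvals)
}
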