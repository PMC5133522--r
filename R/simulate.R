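#' Simulation specification
#'
#' Describes a synthetic cohort: sample size, a per-variant table (MAF,
#' subregion, functional flag, log-odds effect size), an optional
#' tight-LD block simulated on shared haplotypes, Gaussian AGE / binary
#' SEX covariates, the Gaussian null quantitative trait they feed, and
#' the target disease prevalence used for dichotomization.
#'
#' @param n sample count.
#' @param variants data frame with columns `id`, `chrom`, `pos`, `maf`,
#'   `subregion`, `functional`, `beta` (log-odds ratio; 0 for
#'   non-functional variants).
#' @param ld_block optional `list(indices =, r2 =)`: variant indices
#'   drawn from a shared haplotype model with the given target pairwise
#'   \eqn{r^2}.
#' @param covariates list of covariate-model parameters (see
#'   [default_map4_like_spec] for the defaults).
#' @param prevalence_target disease prevalence in (0, 1).
#' @param n_incomplete number of samples with a missing covariate (AGE),
#'   excluded from complete-case analysis.
#' @param dosage_noise_sd truncated-Gaussian blur applied to integer
#'   genotypes to mimic imputation uncertainty (0 = hard calls).
#' @param seed base seed governing genotype/covariate generation.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(n, variants, ld_block = NULL,
                            covariates = list(), prevalence_target = 0.178,
                            n_incomplete = 0L, dosage_noise_sd = 0,
                            seed = 1L) {
  variants <- as.data.frame(variants)
  stopifnot(all(c("id", "pos", "maf", "subregion", "functional", "beta") %in%
                  names(variants)))
  if (any(variants$maf <= 0 | variants$maf > 0.5))
    stop("variant MAFs must lie in (0, 0.5]")
  if (prevalence_target <= 0 || prevalence_target >= 1)
    stop("prevalence_target must be in (0, 1)")
  if (any(variants$functional & variants$beta == 0))
    stop("functional variants must have nonzero effect")
  if (any(!variants$functional & variants$beta != 0))
    stop("non-functional variants must have zero effect")
  if (is.null(variants$chrom)) variants$chrom <- "3"
  cov_defaults <- list(age_mean = 45, age_sd = 12, age_range = c(18, 90),
                      sex_prob = 0.5,
                      q1_intercept = 40, q1_age = 0.025, q1_sex = 0.29,
                      q1_resid_sd = 1,
                      logit_age = 0.025, logit_sex = 0.3)
  covariates <- modifyList(cov_defaults, covariates)
  structure(list(n = as.integer(n), variants = variants,
                 ld_block = ld_block, covariates = covariates,
                 prevalence_target = prevalence_target,
                 n_incomplete = as.integer(n_incomplete),
                 dosage_noise_sd = dosage_noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf("<simulation_spec> n = %d, %d variants (%d functional), %d subregions\n",
              x$n, nrow(x$variants), sum(x$variants$functional),
              max(x$variants$subregion)))
  cat(sprintf("  prevalence target %.3f, %d incomplete covariates, seed %d\n",
              x$prevalence_target, x$n_incomplete, x$seed))
  invisible(x)
}

#' Default single-gene exonic variant panel
#'
#' Builds the package's reference simulation design: 90 polymorphic
#' exonic variants in 6 position-contiguous subregions of sizes
#' 16/22/15/24/9/4, with 81 rare (MAF < 1\%), 5 low-frequency
#' (1\% <= MAF < 5\%) and 4 common (MAF >= 5\%) variants and 26
#' functional variants (22 rare, 2 low-frequency, 2 common) distributed
#' 4/7/0/13/0/2 across the subregions.  MAFs are drawn log-uniformly
#' within class ranges, clamped to `[max(1/(2n), 0.00027), 0.34]`.  The
#' two common variants of subregion 1 form a tight LD block (adjacent
#' positions, shared-haplotype model, target \eqn{r^2 = 0.8}).
#' Functional effects are \eqn{\beta_j = c\,|\log_{10} maf_j|} with
#' alternating signs within each subregion (both protective and
#' deleterious variants per region).  The cohort has 1943 samples of
#' which 81 lack a covariate, leaving 1862 complete cases, and the null
#' trait is dichotomized at 17.8\% prevalence.
#'
#' @param n sample count.
#' @param effect_scale the constant `c` of the effect-size rule.
#' @param seed seed used both to draw the MAFs here and as the spec's
#'   base genotype seed.
#' @param dosage_noise_sd see [simulation_spec].
#' @return a [simulation_spec].
#' @export
default_map4_like_spec <- function(n = 1943L, effect_scale = 0.7,
                                   seed = 1129L, dosage_noise_sd = 0) {
  sizes <- c(16L, 22L, 15L, 24L, 9L, 4L)
  rare_n <- c(14L, 20L, 15L, 20L, 9L, 3L)
  low_n  <- c(0L, 2L, 0L, 2L, 0L, 1L)
  com_n  <- c(2L, 0L, 0L, 2L, 0L, 0L)
  fun_rare <- c(4L, 7L, 0L, 10L, 0L, 1L)
  fun_low  <- c(0L, 0L, 0L, 1L, 0L, 1L)
  fun_com  <- c(0L, 0L, 0L, 2L, 0L, 0L)
  stopifnot(all(rare_n + low_n + com_n == sizes))
  maf_lo <- max(1 / (2 * n), 0.00027)
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  runif_log <- function(k, lo, hi) exp(runif(k, log(lo), log(hi)))
  rows <- list()
  pos <- 47500000L
  for (k in 1:6) {
    cls <- c(rep("rare", rare_n[k]), rep("low-frequency", low_n[k]),
             rep("common", com_n[k]))
    maf <- c(runif_log(rare_n[k], maf_lo, 0.0099),
             runif_log(low_n[k], 0.01, 0.0499),
             runif_log(com_n[k], 0.05, 0.34))
    fun <- c(rep(c(TRUE, FALSE), c(fun_rare[k], rare_n[k] - fun_rare[k])),
             rep(c(TRUE, FALSE), c(fun_low[k], low_n[k] - fun_low[k])),
             rep(c(TRUE, FALSE), c(fun_com[k], com_n[k] - fun_com[k])))
    ord <- sample.int(sizes[k])   # interleave classes along the subregion
    cls <- cls[ord]; maf <- maf[ord]; fun <- fun[ord]
    step <- sample(500:3000, sizes[k], replace = TRUE)
    pos_k <- pos + cumsum(step)
    pos <- pos_k[sizes[k]] + 20000L
    rows[[k]] <- data.frame(subregion = k, pos = pos_k, maf = maf,
                            functional = fun, class = cls,
                            stringsAsFactors = FALSE)
  }
  v <- do.call(rbind, rows)
  # tight LD block: the two common variants of subregion 1, 30 bases apart
  blk <- which(v$subregion == 1 & v$class == "common")
  if (length(blk) >= 2) {
    blk <- blk[1:2]
    v$pos[blk[2]] <- v$pos[blk[1]] + 30L
    # tightly linked variants have near-identical allele frequencies
    # (pairwise r2 is bounded by the frequency ratio); share one MAF
    v$maf[blk[2]] <- v$maf[blk[1]]
    v <- v[order(v$pos), ]
    blk <- which(v$subregion == 1 & v$class == "common")[1:2]
  }
  rownames(v) <- NULL
  # alternating effect signs within each subregion's functional variants
  v$beta <- 0
  for (k in 1:6) {
    idx <- which(v$subregion == k & v$functional)
    if (length(idx)) {
      sgn <- rep_len(c(1, -1), length(idx))
      v$beta[idx] <- sgn * effect_scale * abs(log10(v$maf[idx]))
    }
  }
  v$id <- sprintf("var_3_%d", v$pos)
  v$chrom <- "3"
  simulation_spec(
    n = n,
    variants = v[, c("id", "chrom", "pos", "maf", "subregion",
                     "functional", "beta", "class")],
    ld_block = if (length(blk) >= 2) list(indices = blk, r2 = 0.8) else NULL,
    prevalence_target = 0.178,
    n_incomplete = round(n * 81 / 1943),
    dosage_noise_sd = dosage_noise_sd,
    seed = seed
  )
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' Generate genotype dosages
#'
#' Non-block variants are drawn independently per sample as
#' `Binomial(2, MAF)` hard calls.  LD-block variants are drawn from a
#' shared two-haplotype model: a latent haplotype allele at the block's
#' maximum MAF is thinned per variant to its own MAF and perturbed by
#' per-variant mutation noise calibrated so the pairwise \eqn{r^2}
#' reaches the block's target; an infeasible target (the correlation
#' attainable between two variants is constrained by their allele
#' frequencies) is an error.  Optional truncated-Gaussian dosage blur
#' mimics imputation.
#'
#' @param spec a [simulation_spec].
#' @param seed integer seed (defaults to the spec's own).
#' @return a [genotype_matrix] with the spec's variant metadata.
#' @export
gen_genotypes <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(seed)
  n <- spec$n
  v <- spec$variants
  m <- nrow(v)
  dos <- matrix(0, n, m)
  blk <- if (!is.null(spec$ld_block)) spec$ld_block$indices else integer(0)
  for (j in setdiff(seq_len(m), blk)) {
    # condition on the variant being polymorphic in-sample: the panel
    # stands in for variants *observed* in the cohort, so an all-zero
    # draw (likely when MAF ~ 1/(2n)) is redrawn
    for (try in 1:1000) {
      x <- rbinom(n, 2L, v$maf[j])
      if (any(x > 0)) break
    }
    dos[, j] <- x
  }
  if (length(blk) >= 2) {
    p <- v$maf[blk]
    p0 <- max(p)
    # feasible r2 between variants i,j under the nested-haplotype model
    r2_pair <- outer(p, p, function(a, b) {
      lo <- pmin(a, b); hi <- pmax(a, b)
      lo * (1 - hi) / ((1 - lo) * hi)
    })
    r2_min <- min(r2_pair[upper.tri(r2_pair)])
    if (spec$ld_block$r2 > r2_min + 1e-12)
      stop(sprintf(paste0("LD-block target r2 = %.3f infeasible: allele ",
                          "frequencies constrain the attainable pairwise ",
                          "r2 to at most %.3f"), spec$ld_block$r2, r2_min))
    mu <- 1 - (spec$ld_block$r2 / r2_min)^(1 / 4)
    for (hap in 1:2) {
      latent <- rbinom(n, 1L, p0)
      for (k in seq_along(blk)) {
        allele <- latent * rbinom(n, 1L, p[k] / p0)
        mut <- rbinom(n, 1L, mu) == 1L
        allele[mut] <- rbinom(sum(mut), 1L, p[k])
        dos[, blk[k]] <- dos[, blk[k]] + allele
      }
    }
  }
  if (spec$dosage_noise_sd > 0) {
    dos <- pmin(pmax(dos + rnorm(length(dos), 0, spec$dosage_noise_sd), 0), 2)
  }
  genotype_matrix(dos, sample_ids = paste0("S", seq_len(n)),
                  variants = v[, c("id", "chrom", "pos", "functional")])
}

# Covariates are deterministic given the spec (seed + 1): fixed across
# phenotype replicates like the genotypes.  AGE is truncated Gaussian via
# the inverse CDF; `n_incomplete` samples have observed AGE masked.
gen_covariates <- function(spec) {
  set.seed(spec$seed + 1L)
  n <- spec$n
  cv <- spec$covariates
  lo <- pnorm((cv$age_range[1] - cv$age_mean) / cv$age_sd)
  hi <- pnorm((cv$age_range[2] - cv$age_mean) / cv$age_sd)
  age <- cv$age_mean + cv$age_sd * qnorm(runif(n, lo, hi))
  sex <- rbinom(n, 1L, cv$sex_prob)
  age_obs <- age
  if (spec$n_incomplete > 0)
    age_obs[sample.int(n, spec$n_incomplete)] <- NA_real_
  list(age = age, age_obs = age_obs, sex = sex)
}

#' Generate a null phenotype replicate
#'
#' Draws the Gaussian quantitative trait
#' \eqn{Q_1 = \alpha_0 + \alpha_a AGE + \alpha_s SEX + \epsilon} with no
#' genetic terms, then dichotomizes at the empirical
#' `1 - prevalence_target` quantile, so the binary outcome `Q2` has
#' exactly `round(prevalence_target * n)` cases and correlates with AGE
#' and SEX only through `Q1`.
#'
#' @param spec a [simulation_spec].
#' @param gm the cohort's [genotype_matrix] (sample bookkeeping only;
#'   the null trait has no genetic component).
#' @param replicate_seed seed for this phenotype replicate.
#' @return a [phenotype_table] with `outcome`, `age` (NA for incomplete
#'   samples), `sex` and `q1`.
#' @export
gen_null_phenotypes <- function(spec, gm, replicate_seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  cov <- gen_covariates(spec)
  set.seed(replicate_seed)
  cv <- spec$covariates
  q1 <- cv$q1_intercept + cv$q1_age * cov$age + cv$q1_sex * cov$sex +
    rnorm(spec$n, 0, cv$q1_resid_sd)
  n_case <- round(spec$prevalence_target * spec$n)
  q2 <- integer(spec$n)
  q2[order(q1, decreasing = TRUE)[seq_len(n_case)]] <- 1L
  phenotype_table(sample_ids = gm$sample_ids, outcome = q2,
                  age = cov$age_obs, sex = cov$sex, q1 = q1)
}

#' Generate an alternative (genetic-effect) phenotype replicate
#'
#' Binary outcome from the logistic model
#' \eqn{logit P(y=1) = \beta_0 + \beta_a AGE + \beta_s SEX + G'\beta_g}
#' with \eqn{\beta_g} nonzero only for functional variants (the spec's
#' per-variant effects, by default log-MAF-scaled with mixed signs
#' within subregions).  The intercept is solved numerically so the
#' marginal prevalence over the cohort equals `prevalence_target`.
#'
#' @inheritParams gen_null_phenotypes
#' @return a [phenotype_table].
#' @export
gen_alt_phenotypes <- function(spec, gm, replicate_seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  cov <- gen_covariates(spec)
  cv <- spec$covariates
  lin <- cv$logit_age * (cov$age - cv$age_mean) + cv$logit_sex * cov$sex +
    as.numeric(gm$dosages %*% spec$variants$beta)
  f <- function(b0) mean(plogis(b0 + lin)) - spec$prevalence_target
  if (f(-30) > 0 || f(30) < 0)
    stop("prevalence target unattainable for the given effect sizes")
  b0 <- uniroot(f, c(-30, 30), tol = 1e-10)$root
  set.seed(replicate_seed)
  y <- rbinom(spec$n, 1L, plogis(b0 + lin))
  phenotype_table(sample_ids = gm$sample_ids, outcome = y,
                  age = cov$age_obs, sex = cov$sex)
}

#' Subregion partition recorded in a simulation spec
#'
#' @param spec a [simulation_spec].
#' @return a `subregion_partition` matching the spec's variant table.
#' @export
spec_partition <- function(spec) {
  structure(list(assignments = as.integer(spec$variants$subregion),
                 K = max(as.integer(spec$variants$subregion))),
            class = "subregion_partition")
}
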