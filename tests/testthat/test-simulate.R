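spec <- default_map4_like_spec()

test_that("default panel reproduces the reference design counts", {
  v <- spec$variants
  expect_equal(nrow(v), 90)
  expect_equal(as.integer(table(v$subregion)), c(16, 22, 15, 24, 9, 4))
  expect_equal(as.integer(table(v$class)[c("rare", "low-frequency", "common")]),
               c(81, 5, 4))
  expect_equal(as.integer(tapply(v$functional, v$subregion, sum)),
               c(4, 7, 0, 13, 0, 2))
  expect_equal(sum(v$functional), 26)
  expect_equal(as.integer(table(v$class[v$functional])[
    c("rare", "low-frequency", "common")]), c(22, 2, 2))
  expect_true(all(v$maf >= 0.00027 - 1e-12 & v$maf <= 0.34))
  expect_equal(spec$prevalence_target, 0.178)
  expect_equal(spec$n_incomplete, 81)
  # functional variants carry effects of both signs within subregion 4
  b4 <- v$beta[v$subregion == 4 & v$functional]
  expect_true(any(b4 > 0) && any(b4 < 0))
  # positions within subregions are increasing (contiguity)
  expect_true(all(diff(v$pos) > 0))
})

test_that("spec validation enforces its invariants", {
  v <- spec$variants
  v$maf[1] <- 0
  expect_error(simulation_spec(100, v), "MAF")
  v <- spec$variants
  v$beta[which(v$functional)[1]] <- 0
  expect_error(simulation_spec(100, v), "nonzero")
  expect_error(simulation_spec(100, spec$variants, prevalence_target = 1.2),
               "prevalence")
})

test_that("genotype generation is reproducible and matches target MAFs", {
  g1 <- gen_genotypes(spec, seed = 5)
  g2 <- gen_genotypes(spec, seed = 5)
  expect_identical(g1$dosages, g2$dosages)
  # empirical MAF of a single common variant at large n
  one <- simulation_spec(
    n = 20000,
    variants = data.frame(id = "v1", chrom = "1", pos = 1, maf = 0.25,
                          subregion = 1, functional = FALSE, beta = 0),
    seed = 3)
  gm <- gen_genotypes(one)
  se <- sqrt(0.25 * 0.75 / (2 * 20000))
  expect_lt(abs(compute_maf(gm$dosages[, 1]) - 0.25), 3 * se)
  # every panel variant is polymorphic in-sample by construction
  expect_true(all(g1$variants$mac_tilde >= 1))
})

test_that("LD block reaches its target r2 and rejects infeasible targets", {
  blk_spec <- simulation_spec(
    n = 10000,
    variants = data.frame(id = paste0("v", 1:3), chrom = "1", pos = 1:3,
                          maf = c(0.2, 0.2, 0.2), subregion = 1,
                          functional = FALSE, beta = 0),
    ld_block = list(indices = 1:3, r2 = 0.9), seed = 8)
  gm <- gen_genotypes(blk_spec)
  cors <- cor(gm$dosages)^2
  expect_true(all(cors[upper.tri(cors)] >= 0.8))
  bad <- simulation_spec(
    n = 1000,
    variants = data.frame(id = paste0("v", 1:2), chrom = "1", pos = 1:2,
                          maf = c(0.3, 0.01), subregion = 1,
                          functional = FALSE, beta = 0),
    ld_block = list(indices = 1:2, r2 = 0.9), seed = 8)
  expect_error(gen_genotypes(bad), "allele")
})

test_that("null phenotypes dichotomize to the exact target prevalence", {
  sp <- default_map4_like_spec(n = 1000)
  gm <- gen_genotypes(sp)
  pt <- gen_null_phenotypes(sp, gm, replicate_seed = 4)
  expect_equal(sum(pt$outcome), round(0.178 * 1000))
  # prevalence 1/2 with symmetric noise puts the cut near the median
  sp5 <- sp; sp5$prevalence_target <- 0.5
  pt5 <- gen_null_phenotypes(sp5, gm, replicate_seed = 4)
  thr <- min(pt5$q1[pt5$outcome == 1])
  expect_lt(abs(thr - median(pt5$q1)), 0.05)
  # covariates identical across replicates; q1 varies
  pt2 <- gen_null_phenotypes(sp, gm, replicate_seed = 5)
  expect_identical(pt$age, pt2$age)
  expect_identical(pt$sex, pt2$sex)
  expect_false(identical(pt$q1, pt2$q1))
  expect_equal(sum(!complete_case_mask(pt)), sp$n_incomplete)
})

test_that("null phenotypes carry no genetic signal", {
  sp <- default_map4_like_spec()
  gm <- gen_genotypes(sp)
  j <- which.max(gm$variants$maf)
  rej <- 0
  for (r in 1:60) {
    pt <- gen_null_phenotypes(sp, gm, replicate_seed = 100 + r)
    mask <- complete_case_mask(pt)
    sc <- score_components(pt$outcome[mask],
                           cbind(1, pt$age[mask], pt$sex[mask]),
                           gm$dosages[mask, j])
    rej <- rej + (standard_score_test(sc)$p_value < 0.05)
  }
  # binomial(60, 0.05): 3 expected, 9 is ~3 SD
  expect_lte(rej, 9)
})

test_that("alternative model hits the target prevalence and recovers effects", {
  sp <- default_map4_like_spec()
  gm <- gen_genotypes(sp)
  pa <- gen_alt_phenotypes(sp, gm, replicate_seed = 11)
  se <- sqrt(0.178 * 0.822 / sp$n)
  expect_lt(abs(mean(pa$outcome) - 0.178), 3 * se)
  # single common variant at large n: logistic refit recovers beta
  one <- simulation_spec(
    n = 100000,
    variants = data.frame(id = "v1", chrom = "1", pos = 1, maf = 0.2,
                          subregion = 1, functional = TRUE, beta = 1),
    prevalence_target = 0.178, seed = 21)
  gm1 <- gen_genotypes(one)
  p1 <- gen_alt_phenotypes(one, gm1, replicate_seed = 2)
  X <- cbind(1, p1$age, p1$sex, g = gm1$dosages[, 1])
  fit <- fit_mle(p1$outcome, X)
  se_b <- sqrt(solve(fit$information)[4, 4])
  expect_lt(abs(fit$coefficients[4] - 1), 3 * se_b)
  # zero-effect spec behaves like the null: target prevalence, no signal
  zero <- one
  zero$variants$functional <- FALSE
  zero$variants$beta <- 0
  p0 <- gen_alt_phenotypes(zero, gm1, replicate_seed = 2)
  expect_lt(abs(mean(p0$outcome) - 0.178), 3 * sqrt(0.178 * 0.822 / 1e5))
})

test_that("power rises with effect size and with MAF", {
  base <- function(maf, beta) simulation_spec(
    n = 1500,
    variants = data.frame(id = "v1", chrom = "1", pos = 1, maf = maf,
                          subregion = 1, functional = TRUE, beta = beta),
    prevalence_target = 0.178, seed = 31)
  pw <- function(sp, R = 40) {
    gm <- gen_genotypes(sp)
    hits <- 0
    for (r in seq_len(R)) {
      pt <- gen_alt_phenotypes(sp, gm, replicate_seed = 500 + r)
      mask <- complete_case_mask(pt)
      sc <- score_components(pt$outcome[mask],
                             cbind(1, pt$age[mask], pt$sex[mask]),
                             gm$dosages[mask, 1])
      hits <- hits + (standard_score_test(sc)$p_value < 0.05)
    }
    hits / R
  }
  p_small <- pw(base(0.05, 0.3))
  p_big <- pw(base(0.05, 1.2))
  expect_gte(p_big, p_small)
  p_rare <- pw(base(0.01, 0.8))
  p_common <- pw(base(0.2, 0.8))
  expect_gte(p_common, p_rare)
})
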