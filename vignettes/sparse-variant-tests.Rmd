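---
title: "Sparse-data association tests for rare variants: models, adjustments, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-data association tests for rare variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Single-variant association tests for a binary trait are built on the
logistic regression model

$$
\mathrm{logit}\,P(Y_i = 1 \mid \cdot) \;=\;
\beta_0 + \mathrm{AGE}_i\,\beta_a + \mathrm{SEX}_i\,\beta_s + G_i\,\beta_g ,
$$

where $G_i \in [0,2]$ is the (possibly imputed, hence non-integer) dosage
of the nonreference allele.  For rare variants the effective sample size
behind $\hat\beta_g$ is the number of carriers, not $n$; with a handful of
carriers the usual large-sample chi-square references fail, the standard
score test can be sharply anticonservative at stringent levels, and the
maximum-likelihood estimate is infinite whenever the carriers separate
cases from controls.  `rarelogit` implements the sparse-data repair kit —
Firth-penalized likelihood-ratio tests and moment-adjusted score tests for
single variants; weighted burden, SKAT and SKAT-O for variant sets — plus
the simulation machinery needed to measure how well each test controls
type-1 error as a function of carrier count.

Because dosages are analyzed as-is, carrier counts are summarized by
$\widetilde{\mathrm{MAC}}$, the number of individuals with dosage strictly
greater than zero, which approaches the minor allele count at low MAF.

# Single-variant tests

**Standard LR and score tests.** The likelihood-ratio statistic
$2\{\ell(\hat\beta) - \ell(\hat\beta_0)\}$ and the score statistic
$U^2/V$, with $U = \sum_i g_i (y_i - \hat\pi_{0i})$ and
$V = g'Wg - g'WX(X'WX)^{-1}X'Wg$, both referred to $\chi^2_1$.  The MLE
fitter flags separation (any $|\hat\beta| > 15$, or fitted probabilities
pinned to 0/1) instead of silently returning a boundary estimate.

**Firth-penalized LR test.** The Jeffreys-prior penalty
$\ell_p(\beta) = \ell(\beta) + \tfrac12 \log |i(\beta)|$ generalizes the
Haldane add-half correction for sparse 2×2 tables (for a binary covariate
the Firth slope equals the add-half log odds ratio exactly) and keeps all
estimates finite under separation.  The test statistic is
$2\{\ell_p(\hat\beta) - \ell_p(\tilde\beta)\}$, where the constrained
optimum $\tilde\beta$ fixes $\beta_g = 0$ while the penalty retains the
full design's information matrix.  This *profile* convention matches the
common Firth-test software lineage; a *reduced* convention that refits the
smaller design with its own penalty is exposed behind
`penalized_lr_test(..., penalty = "reduced")`, but it compares penalties
of different dimension and carries a log-determinant offset, so profile is
the default and the recommendation.

**Moment-adjusted score tests.** Writing $Q = U^2$, the null mean
$\mu_Q = V$ is exact, and so is the variance
$\sigma_Q^2 = 2V^2 + \sum_i \tilde g_i^4\,\kappa_{4i}$ under the
parametric resampling scheme $y_i^* \sim \mathrm{Bernoulli}(\hat\pi_{0i})$
with the covariate-residualized genotype
$\tilde g = g - X(X'WX)^{-1}X'Wg$ ($\kappa_{4i} = w_i(1-6w_i)$ is the
fourth cumulant of a centered Bernoulli).  The *variance* mode refers
$(Q-\mu_Q)/\sigma_Q\sqrt2 + 1$ to $\chi^2_1$; the *variance+kurtosis*
mode estimates the excess kurtosis $\hat\gamma$ of $Q$ from $B$
parametric-bootstrap replicates (default $B = 10{,}000$) and refers
$(Q-\mu_Q)/\sigma_Q\sqrt{2\,df} + df$ to $\chi^2_{df}$ with
$df = 12/\hat\gamma$ (floored at 0.5, capped at $10^5$ — the normal
limit — when $\hat\gamma \le 0$).  Because $U$ is a sum of independent
centered Bernoulli terms, every cumulant of $Q$ under the resampling law
is also available in closed form; `kurtosis = "analytic"` computes
$\hat\gamma$ as that exact large-$B$ limit, noise-free (it approaches 12,
the $\chi^2_1$ value, for common variants).

Two properties of this recipe are worth knowing.  First, holding
$\hat\pi_0$ fixed in the bootstrap (no per-replicate covariate refit)
makes the analytic moments exact for the resampling law; it is an
approximation to the refitted law, adopted for tractability.  Second, the
sample kurtosis of a $\chi^2_1$-type variable involves eighth moments and
is noisy even at $B = 10^4$ (standard error near 1.5), so the
kurtosis-mode p-value fluctuates by a few hundredths in the mid-range; the
adjustment earns its keep in the tail, which is where testing decisions
live.  For very sparse variants (a few carriers) the exact null is
discrete with atoms of several hundredths, and *no* smooth reference
distribution tracks it more closely than the atom size.

# Variant-collapsing tests

For a subregion with dosage matrix $G$ ($n \times m_k$) and MAF-based
weights $W = \mathrm{diag}(w_j)$:

* **Weighted burden**: score test of the collapsed variable
  $c_i = \sum_j w_j G_{ij}$ — powerful when effects share a direction,
  degraded by sign cancellation.
* **SKAT**: $Q = (y-\hat\pi_0)'\,G W^2 G'\,(y-\hat\pi_0)$, with null
  distribution $\sum_j \lambda_j \chi^2_1$ where $\lambda_j$ are the
  eigenvalues of the covariate-projected weighted kernel — robust to
  mixed effect directions.
* **SKAT-O**: $Q_\rho = (1-\rho)Q_{\mathrm{SKAT}} + \rho\,Q_{\mathrm{burden}}$
  minimized in p over a $\rho$ grid (default
  $\{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1\}$); the final p-value
  integrates the minimum-p statistic's null distribution
  one-dimensionally after decomposing the kernel into a shared
  one-degree-of-freedom component plus an independent mixture, and is
  additionally capped at the Bonferroni bound (grid size times the
  minimum per-$\rho$ p).  $\rho = 1$ is replaced by $0.999$ inside the
  mixture algebra, where the exchangeable correlation matrix becomes
  singular.

Weights default to the Beta(1, 25) density of the MAF (the convention of
the SKAT software family); Madsen–Browning weights
$1/\sqrt{n p_j (1-p_j)}$ are available via
`collapsing_config(weight_scheme = "madsen-browning")`.  Variant classes
use the conventional cut-offs: rare MAF < 1%, low-frequency 1–5%, common
≥ 5%, with left-closed boundaries.

Mixture tail probabilities come from characteristic-function inversion of
the Imhof/Davies integral by adaptive quadrature (absolute accuracy
$10^{-9}$; equal-weight mixtures short-circuit to the exact scaled
chi-square), with the Liu four-moment match as fallback whenever the
inversion faults or underflows; result tables record which path produced
each p-value.  Eigenvalues below $10^{-10}\lambda_{\max}$ are pruned.

The small-sample moment adjustment (analytic mean and variance, bootstrap
kurtosis) is applied to burden and SKAT whenever $n < 2000$ or the case
fraction is below 0.2 (`adjust = "auto"`), and can be forced either way.
Within one region battery all adjusted tests share a single block of
bootstrap resamples, so identical variant selections yield identical
p-values and the resampling cost is paid once per null fit.  SKAT-O's
min-p integration is used unadjusted: a fully moment-adjusted SKAT-O null
requires the joint small-sample law across the $\rho$ grid, which is out
of proportion to its role here; this is a known limitation.

# The synthetic cohort

No individual-level cohort ships with the package, so the generator
builds one with the statistical structure the analyses assume — a
single-gene exonic panel observed in roughly two thousand unrelated
individuals:

* 90 polymorphic variants in 6 position-contiguous subregions of sizes
  16/22/15/24/9/4; 81 rare, 5 low-frequency, 4 common; 26 functional
  (22 rare, 2 low-frequency, 2 common) distributed 4/7/0/13/0/2 across
  subregions.
* MAFs drawn log-uniformly within class ranges and clamped to
  $[\max\{1/(2n), 0.00027\},\, 0.34]$.  Every variant is drawn
  conditional on being polymorphic in-sample, because the panel stands
  in for variants *observed* in a cohort; at MAF near $1/(2n)$ this
  yields the heavy singleton load typical of exome panels.
* One tight LD block: the two common variants of subregion 1, thirty
  bases apart, share a MAF and a latent haplotype with per-variant
  thinning and mutation noise calibrated to a target pairwise
  $r^2 = 0.8$ (tightly linked variants must have near-equal frequencies;
  an infeasible target given the frequencies is an error).
* Covariates: AGE $\sim N(45, 12^2)$ truncated to [18, 90], SEX
  $\sim$ Bernoulli(0.5) — defaults, not estimates from any cohort.  With
  $n = 1943$, exactly 81 samples lack AGE, leaving 1862 complete cases.
* Null trait: $Q_1 = \alpha_0 + \alpha_a\mathrm{AGE} + \alpha_s\mathrm{SEX}
  + \varepsilon$ with coefficients chosen so the covariates explain about
  10% of the variance; the binary outcome $Q_2$ flags the top
  $\mathrm{round}(0.178\,n)$ values of $Q_1$, so the prevalence is 17.8%
  exactly and the outcome correlates with the covariates only through
  $Q_1$.  Dichotomizing at the empirical quantile rather than a fixed
  cut-point keeps the invariant property (the prevalence) independent of
  the trait's arbitrary scale.
* Alternative model: logistic, with
  $\beta_j = c\,|\log_{10}\mathrm{MAF}_j|$ for functional variants
  ($c = 0.7$ by default, each effect individually overridable),
  alternating signs within each subregion so regions contain both
  protective and deleterious variants, and the intercept solved
  numerically so the marginal prevalence equals the target.

What the generator does *not* emulate: population structure or admixture,
relatedness, genotyping/imputation error beyond an optional Gaussian
dosage blur, linkage beyond the single block, and genome-scale polygenic
background.  Passing tests therefore demonstrate the statistical behavior
of the tests under a clean cohort of this shape, not robustness to those
real-data complications.

# Replicate evaluation design

Genotypes and covariates are fixed per spec (they play the role of the
observed cohort); phenotypes are regenerated per replicate with seeds
`base_seed + r`, so any replicate can be reproduced bit-for-bit in
isolation from the run manifest.  Null type-1 error is pooled across
variants sharing a $\widetilde{\mathrm{MAC}}$ value — computed on the
complete-case sample actually analyzed — with ±2 binomial-SE error bars
on $N = R \times (\text{group size})$ tests; power is reported per
functional variant and per subregion × variant class.

Problem sizes used by the packaged checks: the null surface uses
$R = 2000$ replicates of the full five-test battery ($n = 1943$, 1862
complete cases), with the analytic kurtosis mode for the adjusted score
test (the bootstrap mode's estimator noise at replicate-loop budgets
visibly deforms the p-value distribution — see the limitations below);
the power comparison uses $R = 1000$ replicates of the collapsing
battery on the mixed-effect-direction subregion with $B = 1000$ shared
bootstrap resamples per replicate for the region adjustments.  The
replicate driver evaluates SKAT-O's outer integrand with the Liu form
(the Davies form is the default for one-shot analysis); one-off
`adjusted_score_test` calls keep $B = 10{,}000$.

# Numerical choices

* IRLS convergence: penalized-score norm below $10^{-9}$
  ($10^{-7}$ in the batch path) or step below $10^{-10}$, with
  step-halving on any penalized-likelihood decrease; cap 200 iterations.
  The tight score tolerance is what makes the Firth slope match closed
  forms to $10^{-6}$.
* MLE separation flags: $|\hat\beta| > 15$ or fitted probabilities within
  $10^{-10}$ of 0/1; flagged fits report `converged = FALSE` and are
  marked `fallback` in result tables rather than dropped.
* Working weights floored at $10^{-12}$; rank deficiency is detected
  up-front by pivoted QR and reported with the offending column's name.
* Ties in the null-trait dichotomization are broken by order statistics
  (the top $k$ values are cases), which is immaterial for a continuous
  trait.
* Bonferroni is the default multiple-testing correction, applied within
  the declared family (all polymorphic variants, or the $K$ regions).

# Known limitations

* The kurtosis-mode score adjustment inherits bootstrap noise in its
  effective df (see above) unless the analytic mode is used; for common
  variants it adds nothing over the standard test and is reported for
  completeness.  Its reference distribution also has an upper-range
  artifact: whenever $\hat\gamma > 12$ (so $df < 1$), every statistic
  below the shifted chi-square's support start maps to $p = 1$ exactly.
  At a common variant this puts a few percent of null replicates in an
  atom at 1 — harmless for testing decisions, but the p-value
  distribution is visibly non-uniform near 1 and fails a
  Kolmogorov–Smirnov uniformity check that the other four tests pass.
* The moment-adjusted SKAT reference corrects the tail but can sit a few
  thousandths from the exact resampling law in the mid-range, where the
  chi-square family cannot match skewness and kurtosis simultaneously.
* At a handful of carriers, *every* smooth reference distribution — and
  equally the asymptotic mixture — deviates from the atom-sized steps of
  the exact null; this is the regime the carrier-count-pooled error
  surfaces are designed to expose, not one any single-variant p-value
  should be trusted in.
* SKAT-O is not moment-adjusted (see above).
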