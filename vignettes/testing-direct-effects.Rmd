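---
title: "Testing direct effects of genetic instruments in MR and TWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing direct effects of genetic instruments in MR and TWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tede)
```

## The problem

Mendelian randomization (MR) and transcriptome-wide association studies
(TWAS) infer the causal effect of an exposure $X$ (a trait, or a gene's
expression) on an outcome $Y$ using genetic variants as instrumental
variables. The inference is only valid when each instrument affects the
outcome exclusively through the exposure. Horizontal pleiotropy — a SNP
acting on $Y$ directly, or through a confounder — violates this and biases
every downstream estimate. MR typically uses independent genome-wide SNPs;
TWAS uses correlated cis-SNPs, so any usable check must handle linkage
disequilibrium (LD).

This package implements a goodness-of-fit test for the presence of such
*direct effects*, operating purely on GWAS summary statistics plus an LD
reference. Write $G$ for the $n \times p$ centered genotype matrix,
$\hat\omega$ for the SNP-to-exposure weights (joint TWAS weights, or
marginal effects when instruments are independent), and
$\hat X = G\hat\omega$ for the imputed exposure. The working model is

$$ Y_i = \sum_{j=1}^p \alpha_j G_{ij} + \beta \hat X_i + \varepsilon_i,
   \qquad \varepsilon_i \sim N(0, \sigma^2_Y), $$

and the null hypothesis of no direct effects is
$H_0: \alpha_1 = \dots = \alpha_p = 0$. Rejection indicates the
two-stage model is mis-specified — invalid instruments, population
structure, or inaccurate first-stage weights.

## The tests

**Score system.** Under $H_0$ the MLE is $\hat\beta = X'Y / X'X$ with
$X = G\hat\omega$, and $\hat\sigma^2_Y$ is the residual variance of
$Y - \hat\beta X$. The score vector at the null MLE has components
$U_j = G_j'(Y - \hat\beta X)/\hat\sigma^2$ for the direct effects and
exactly zero for the $\beta$ coordinate; the expected information is
$I = \sigma^{-2} \left[\begin{smallmatrix} G'G & G'X \\ X'G & X'X
\end{smallmatrix}\right]$. Every entry is a function of $G'G$, $G'Y$,
$Y'Y$ — quantities reconstructible from marginal summary statistics and an
LD reference (see below), which is what makes the whole construction
summary-statistics-only.

**TEDE-Sc** is the score test $U'I^{+}U$, referred to a chi-squared
distribution with degrees of freedom equal to the numerical rank of $I$.
The information is structurally rank-deficient ($X$ lies in the span of
$G$), hence the pseudo-inverse; singular values below $10^{-10}$ of the
largest are treated as zero so the degrees of freedom are deterministic.
Because estimating $\beta$ removes one dimension from the score's true
null distribution while the reference distribution uses the rank of $I$
($= p$), the test is mildly conservative — by design, matching its
original formulation.

**TEDE-aSPU** standardizes the scores, $Z = C^{-1/2}U$ with $C =
\mathrm{diag}(I)$, and combines the sum-of-powered-scores statistics
$\mathrm{SPU}(\gamma) = \sum_j z_j^\gamma$ (and $\max_j |z_j|$ for
$\gamma=\infty$) over $\Gamma = \{1,\dots,8,\infty\}$. Low powers are
sensitive to dense weak direct effects; high powers to sparse strong ones.
Each SPU statistic gets a two-sided Monte-Carlo p-value from $B$ draws of
the score vector under the null, and the adaptive statistic is the minimum
p-value, itself calibrated against the same draws by a leave-one-out rank
computation (one sort per power — identical output to the naive double
loop at $B\log B$ cost). The attainable p-value floor is $1/B$, or
$1/(B+1)$ with the optional add-one correction.

A numerical point matters here. The exact null covariance of the score at
the null MLE is the Schur complement
$S = (G'G - G'X(X'X)^{-1}X'G)/\sigma^2$ — the projection orthogonal to the
imputed-exposure direction — with the $\beta$ coordinate identically zero.
`tede_aspu()` samples its Monte-Carlo null from this projected covariance
(the default `null_cov = "score"`). Sampling instead from the standardized
information matrix is asymptotically equivalent for independent
instruments, but under LD the projected direction is close to the leading
eigenvector of the LD matrix, and unprojected draws then overstate the
spread of the smooth SPU directions, making the test markedly
conservative. The unprojected variant is retained as
`null_cov = "information"`.

**TEDE-Sc2 / TEDE-aSPU2.** The score system treats $\hat\omega$ as fixed.
When the first-stage sample is small and $\beta \ne 0$, weight-estimation
error inflates type I error; the corrected variants replace the
direct-effect block of $I$ by
$G'G/\sigma^2 + \hat\beta^2 (G'G)\,\mathrm{Cov}(\hat\omega)\,(G'G)/\sigma^4$.
They require first-stage standard errors; without them the package raises
a typed condition (`tede_no_stage1_se`) rather than guessing.

**Comparators.** `cochran_q()` (heterogeneity of Wald ratios,
$\chi^2_{p-1}$), `mr_egger()` (weighted Egger regression with the standard
multiplicative overdispersion of its random-effects formulation; the
intercept tests directional pleiotropy), and `lda_mr_egger()` (the
generalized least-squares Egger regression on joint effects with
$\Sigma = \mathrm{Cov}(\hat\gamma)$ and coefficient covariance $M^{-1}$,
for correlated instruments).

Cochran's Q exposes two weightings: the default first-order weights
$w_j = (\hat\omega^*_j / se(\hat\gamma^*_j))^2$, and a `"paper"` mode with
$w_j = (\hat\gamma^*_j / se(\hat\gamma^*_j))^2$ as printed in part of the
model-checking literature. The latter weights SNPs by their *outcome*
association, so pleiotropic outliers dominate the IVW mean they are
compared against and the test retains almost no power; first-order is
therefore the default. A consequence worth knowing: a correctly
calibrated first-order Q sits within about two percentage points of
TEDE-Sc's power in the independent-instrument scenarios below, so which
of the two "wins" a given cell is at the level of simulation noise.

## Moment reconstruction

With centered genotypes, Hardy–Weinberg variance $v_j = 2f_j(1-f_j)$, and
an LD correlation matrix $R$,

* $(G'G)_{jk} = R_{jk}\sqrt{v_j v_k}\,(n-1)$;
* $G_j'Y = \hat\gamma^*_j (G'G)_{jj}$ (the marginal normal equation);
* $Y'Y$ is recovered per SNP by inverting the marginal OLS variance
  formula, $s_j = se_j^2 (n-2)(G'G)_{jj} + \hat\gamma^{*2}_j (G'G)_{jj}$,
  and aggregated by the median across SNPs — robust to a few mis-scaled
  standard errors.

Joint effects and their covariance follow as
$\hat\gamma = (G'G)^{-1}G'Y$,
$\mathrm{Cov}(\hat\gamma) = \hat\sigma^2 (G'G)^{-1}$ with $\hat\sigma^2 =
(Y'Y - \hat\gamma'G'Y)/(n-p-1)$, floored at a small positive value. The
same reconstruction applied to the exposure sample yields joint weights
and $\mathrm{Cov}(\hat\omega)$. When the LD reference is the analysis
sample itself, every reconstructed moment equals its individual-level
counterpart to numerical precision, and therefore so does every test —
this closure property anchors the unit tests.

$G'G$ is used as-is; if its condition number exceeds $10^{10}$ the
reconstruction stops with advice to prune ($r^2 < 0.9$ is the usual
working rule) rather than silently regularize, since ridge shrinkage would
bias the score test. Degrees-of-freedom conventions are $n-1$ for
variances and $n-2$ for the marginal residual; the differences are
$O(1/n)$ at GWAS sample sizes.

## A worked example

```{r example}
cfg <- scenario_config(p = 30, n1 = 10000, n2 = 10000, scenario = "S1",
                       prop_invalid = 0.1, h2_xy = 0, seed = 7)
set.seed(7)
effects <- draw_effects(cfg)
dat <- simulate_two_sample(cfg, effects)
ld <- ld_diag_from_freq(dat$outcome$freq, dat$outcome$snp)
results <- tede_test(dat$exposure, dat$outcome, ld,
                     methods = c("cochran_q", "mr_egger",
                                 "tede_sc", "tede_aspu"),
                     B = 1000, seed = 1)
results_table(results)
```

With three of thirty instruments invalid, the heterogeneity and score
tests reject decisively while the MR-Egger intercept — which only sees the
*average* direct effect, here balanced around zero — does not.

## The simulation engine

`scenario_config()` fixes one cell of the rejection-rate study;
`run_rejection_experiment()` runs it. The generative model, in each of two
independent samples (sizes $n_1$ for the exposure GWAS, $n_2$ for the
outcome GWAS), is

$$ U = G\delta + \epsilon,\quad X = G\omega + U + e,\quad
   Y = \beta X + G\upsilon + U + \varepsilon, $$

with standard-normal noise. Defaults are the reference study conditions:
MAF $f = 0.3$ for every SNP; $\omega_j$ drawn from $N(0, 0.15^2)$
truncated to $(0.08, \infty)$ — one-sided, so all true instrument effects
are positive and instrument strength is guaranteed — then rescaled so the
SNPs explain 20% of $\mathrm{Var}(X)$; a uniformly random fraction
`prop_invalid` of SNPs made invalid with direct effects per scenario
(S1 balanced $\upsilon_j \sim N(0, 0.075)$; S2 directional
$\upsilon_j \sim N(0.1\,\mathrm{sign}(\omega_j), 0.025)$; S3 adds
confounder effects $\delta_j \sim \mathrm{Unif}(0, 0.1)$, violating the
InSIDE assumption). The scenario dispersions are read as variances by
default (`dispersion = "sd"` selects the other reading; after rescaling
the choice is nearly immaterial for S1 and mild for S2/S3).

Three scaling conventions deserve explicit statement, because the
qualitative behaviour of the study depends on them:

* $\upsilon$ is rescaled so $G\upsilon$ explains `h2_direct` (0.3%) of the
  *non-causal* outcome variance, i.e. $\mathrm{Var}(Y)$ evaluated at
  $\beta = 0$. Scaling against the full variance would make every power
  ~invariant to $\beta$ (signal and noise would grow together); under
  this convention power declines as the causal effect grows, which is the
  behaviour the reference rejection rates exhibit.
* $\delta$ is *not* rescaled, so in S3 the confounder channel grows with
  the number of invalid instruments — power rises steeply with
  `prop_invalid` there, unlike S1/S2 where $\upsilon$ is renormalized. The
  default bound `delta_max = 0.1` keeps the per-SNP confounder signal on
  the same scale as the pleiotropy signal at 10% invalid instruments.
* All scaling constants are solved analytically from the generative
  variance identities (including every cross-covariance channel), so the
  effect sizes are deterministic given the raw draws; scaling empirically
  per replicate would couple effect sizes to noise.

Correlated genotypes use a Gaussian-copula construction: two latent
haplotype vectors with an AR-structured correlation matrix are thresholded
at the $f$-quantile and summed, giving allele counts with
$\mathrm{Binomial}(2, f)$ margins. The latent correlation for each lag is
solved by root-finding on the bivariate-normal orthant probability so the
*allele-count* correlation equals $\rho^{|j-k|}$ at every lag, not only at
lag one (thresholding attenuates correlations nonlinearly, so calibrating
lag 1 alone and relying on the AR recursion would miss longer lags by up
to a few hundredths).

For correlated instruments the experiment harness supplies the
model-implied AR correlation to the tests by default
(`ld_source = "analytic"`). A finite reference panel is fully supported
(`ld_source = "panel"`, default size 503, the size of a familiar European
reference panel), but noise in a small panel's $(G'G)^{-1}$ visibly
inflates the score test's size — an effect worth knowing about when
applying the LDA tests with small panels in practice. The calibration
checks in the test suite use the analytic-LD setting.

What the generator does *not* emulate: real LD is not AR-structured,
allele frequencies vary across SNPs, effect sizes correlate with
frequency, traits are often binary, and samples can overlap. Passing the
calibration study therefore shows the machinery is correct under the
stated model, not that type I error is guaranteed on any real dataset.

## Problem sizes and reproducibility

The packaged checks use $p = 30$–$100$ SNPs, GWAS sample sizes
2,000–50,000, $B = 1000$ Monte-Carlo draws and 400–1000 replicates per
cell; `scripts/acceptance.R` re-runs the headline cells from a single
seed. Every experiment is reproducible bit-for-bit from `cfg$seed`: the
harness draws one child seed per replicate, so results do not depend on
which methods are requested together.

## Known limitations

* Linear models only; binary outcomes are approximated by linear
  regression at small effect sizes, as is standard with GWAS summary data.
* The aSPU p-value floor of $1/B$ makes genome-wide thresholds expensive;
  asymptotic or importance-sampling variants are out of scope.
* No identification of *which* instruments are invalid — the test is
  global by construction (the full model with per-SNP direct effects is
  unidentified).
* Strand-ambiguous (A/T, C/G) SNPs whose reported orientations conflict
  are dropped, never guessed.
* LDA MR-Egger's intercept test has limited and configuration-sensitive
  power under InSIDE violation; in the packaged S3 study its power
  saturates around a quarter while the score-based tests exceed 0.9, and
  reported values for comparable designs vary with the exact
  confounder-effect conventions.
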