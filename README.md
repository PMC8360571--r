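# tede: testing direct effects of genetic instruments

Mendelian randomization (MR) and TWAS draw causal conclusions from genetic
instruments, and those conclusions stand or fall with the assumption that
no instrument affects the outcome except through the exposure. Horizontal
pleiotropy — direct SNP-to-outcome effects, or effects routed through a
confounder — breaks that assumption silently. `tede` provides a
goodness-of-fit test for the presence of direct effects that works from
GWAS summary statistics alone, for both independent instruments (MR) and
LD-correlated instruments (TWAS), together with the classical comparators.

For centered genotypes `G`, first-stage weights `ω̂` and imputed exposure
`X̂ = Gω̂`, the expanded second-stage model is

    Y = Σⱼ αⱼ Gⱼ + β X̂ + ε,        H₀: α₁ = … = α_p = 0.

The package tests H₀ with a score test (**TEDE-Sc**: `U′I⁺U ~ χ²` with
df = rank of the information) and an adaptive sum-of-powered-scores test
(**TEDE-aSPU**: `SPU(γ) = Σⱼ zⱼ^γ` over `γ ∈ {1,…,8,∞}` combined by
minimum Monte-Carlo p-value), plus variance-corrected variants
(**TEDE-Sc2/aSPU2**) that propagate the uncertainty of estimated weights.
All inputs — `G′G`, `G′Y`, `Y′Y` and their first-stage analogues — are
reconstructed from marginal effect estimates, standard errors and an LD
reference, so no individual-level data are needed. Comparators: Cochran's
Q, MR-Egger (intercept test), and LDA MR-Egger for correlated SNPs.

## Worked example

Simulate a two-sample MR study with 30 independent SNPs (MAF 0.3, both
GWAS n = 10,000) in which 10% of instruments carry balanced pleiotropic
effects, then test for direct effects from the summary statistics:

```r
library(tede)

cfg <- scenario_config(p = 30, n1 = 10000, n2 = 10000, scenario = "S1",
                       prop_invalid = 0.1, h2_xy = 0, seed = 3)
set.seed(3)
effects <- draw_effects(cfg)
dat <- simulate_two_sample(cfg, effects)
ld  <- ld_diag_from_freq(dat$outcome$freq, dat$outcome$snp)

results <- tede_test(dat$exposure, dat$outcome, ld,
                     methods = c("cochran_q", "mr_egger",
                                 "tede_sc", "tede_aspu"),
                     B = 1000, seed = 1)
results_table(results)
#>        method statistic df      p_value
#> 1 Cochran's Q 64.826905 29 0.0001494151
#> 2    MR-Egger  1.802427  1 0.1794193451
#> 3     TEDE-Sc 64.635321 30 0.0002441792
#> 4   TEDE-aSPU  0.000000 NA 0.0000000000
```

Three of the thirty instruments are invalid: Cochran's Q and TEDE-Sc
reject at p ≈ 2 × 10⁻⁴, and TEDE-aSPU's Monte-Carlo p-value hits its
floor (< 1/B = 0.001). MR-Egger's intercept test does not reject (p =
0.18) — the direct effects are balanced around zero, and the intercept
only measures their mean. That contrast is the method's point: heterogeneity- and score-based
tests detect pleiotropy that intercept-based tests structurally miss.

For TWAS-style correlated instruments, supply a reference panel
(`ld_from_panel(genotype_matrix)`) or a correlation matrix
(`ld_reference()`), and optionally TWAS weights (`read_joint_weights()`);
`tede_test()` then reconstructs joint effects behind the scenes. A thin
command-line front end for both testing and simulation lives at
`inst/cli/tede.R` (subcommands `test` and `simulate`).

Real-data use follows the same path: `read_marginal_summary()` for the two
GWAS files (tab/comma/whitespace-delimited with a header; column names
remappable), `harmonize()` to align alleles — swapped-allele effects are
sign-flipped, unresolvable and conflicting palindromic SNPs are dropped
with a warning — and the tests above.

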