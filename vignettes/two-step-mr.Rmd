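---
title: "Two-sample and two-step Mendelian randomization with mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample and two-step Mendelian randomization with mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The design

Mendelian randomization (MR) treats genetic variants as instrumental
variables for a modifiable exposure. A variant is a valid instrument when
it (i) associates with the exposure, (ii) is independent of
exposure–outcome confounders, and (iii) affects the outcome only through
the exposure (exclusion restriction). In the *two-sample* design the
SNP–exposure and SNP–outcome associations come from different,
non-overlapping GWAS, so the whole analysis runs on published summary
statistics: one row per SNP with effect allele, other allele, effect-allele
frequency (EAF), beta, SE, p and sample size.

`mrmediate` implements the full workflow — instrument selection, allele
harmonization, estimation, sensitivity analysis, multivariable MR,
two-step mediation, and power — plus a generator of synthetic summary
statistics with known causal structure, used throughout the test suite.

## Instrument selection

Instruments are SNPs reaching genome-wide significance (p < 5·10⁻⁸,
strict), thinned by greedy LD clumping (keep the smallest-p SNP, discard
neighbours with r² ≥ 0.001 and, when positions are available, within
10,000 kb; ties in p broken lexicographically by SNP id so the output does
not depend on row order), and strength-filtered at F = β²/SE² > 10.
Pairwise LD is an *input* (square or long-format matrix file): the package
never touches genotype panels, which keeps it fully testable offline. The
instrument set's explanatory power is summarized as
R²ₓᵤ = Σⱼ 2·EAFⱼ(1−EAFⱼ)βⱼ², the standard per-allele approximation for a
standardized trait.

## Harmonization

Exposure and outcome records are joined on SNP id and placed on a common
effect-allele orientation: identical allele pairs pass through, swapped
pairs have the outcome beta negated and EAF complemented, and pairs that
match only under strand complement are complemented first (cross-consortium
files differ in strand convention). Palindromic SNPs (A/T, C/G) are
ambiguous between strands and are excluded by default; an optional
frequency-inference mode keeps them when both EAFs are on the same side of
0.5 and farther than 0.08 from it (threshold 0.42), but it is off by
default because unconditional exclusion is the more conservative and more
reproducible choice. Instruments whose exposure beta is exactly zero after
harmonization are excluded (undefined Wald ratio). The harmonization
report accounts for every joined SNP: harmonized + palindromic +
mismatched + zero-beta = input.

## Estimators

Each harmonized instrument carries a Wald ratio rⱼ = βⱼ(out)/βⱼ(exp) with
first-order SE = SEⱼ(out)/|βⱼ(exp)| — the exposure-side uncertainty is
deliberately ignored in the ratio SE (the convention under which IVW is
exactly a weighted regression); it re-enters through the weighted-median
bootstrap and the MR-PRESSO simulations.

**IVW.** β̂ = Σwⱼrⱼ/Σwⱼ with wⱼ = βⱼ(exp)²/SEⱼ(out)², algebraically
weighted least squares of outcome betas on exposure betas through the
origin with weights SE(out)⁻². Fixed-effects SE = (Σwⱼ)^−1/2; the
multiplicative random-effects SE inflates it by max(1, √(Q/(J−1))),
clipping underdispersion at 1. The model is chosen by Cochran's Q: fixed
when the heterogeneity p exceeds 0.05 (strictly), random otherwise.
P-values are normal.

**MR-Egger.** Instruments are oriented so every exposure beta is positive
(both betas negated as needed), then outcome betas are regressed on
exposure betas *with* an intercept, weights SE(out)⁻². The slope is the
pleiotropy-adjusted causal estimate; the intercept estimates the average
directional pleiotropic effect. SEs carry the same multiplicative
overdispersion factor with J−2 degrees of freedom, and p-values use
t(J−2) — the heavier tail reflecting the method's lower precision.
Pleiotropy is judged ignorable when |intercept| < 0.1 *and* its p > 0.05.

**Weighted median.** Wald ratios are sorted; the estimate sits where the
normalized cumulative weight, evaluated at the midpoint convention
sⱼ = (Σₖ≤ⱼwₖ − wⱼ/2)/Σwₖ, crosses one half, interpolating linearly
between the bracketing ratios. Weights are inverse first-order ratio
variances. The SE comes from a parametric bootstrap (default 1000
replicates, mandatory seed): exposure and outcome betas are resampled from
normals with their reported SEs and the estimate recomputed.

**MR-PRESSO.** For each instrument the leave-one-out IVW estimate b₋ⱼ
(computed in closed form from the full-set weighted sums) predicts the
outcome beta; the observed weighted residual sum of squares is compared
with its parametric-simulation distribution (default 1000 draws). The
global p uses the add-one Monte-Carlo convention (1+#{RSS* ≥ RSS})/(n+1);
per-SNP outlier p-values come from each instrument's own simulated
residual distribution, Bonferroni-adjusted across instruments and flagged
below 0.05; the corrected estimate is IVW on the unflagged set, and a
distortion p compares the corrected-vs-original shift with random removals
of equally many instruments. The reference method's bootstrap scheme is
followed in structure, not byte-for-byte.

For binary outcomes all betas are log-odds and estimates are reported as
OR = exp(β) with exponentiated CI endpoints.

## Multivariable MR and mediation

The mediator→outcome coefficient conditional on the exposure (β₂) comes
from multivariable MR: weighted least squares of outcome betas on the
exposure *and* mediator beta columns jointly, no intercept, weights
SE(out)⁻², overdispersion clipped at 1, p from t(J−K). The instrument set
is the union of each trait's genome-wide-significant clumped SNPs, jointly
clumped, harmonized to the first exposure's orientation, and restricted to
SNPs observed in every trait. With K = 1 the fit reduces exactly to
multiplicative random-effects IVW. Conditional F-statistics per column are
reported as a weak-instrument diagnostic. An all-zero or collinear
exposure column is a hard error rather than a silent drop.

Two-step mediation combines β₀ (total effect, IVW), β₁
(exposure→mediator, IVW) and β₂ (MVMR) through the significance decision
table at α = 0.05: all three significant → *partial* mediation; β₀ not
significant but both paths significant → *full*; β₀ significant with a
broken path → *none*; neither → *no causal path*. The proportion mediated
is β₁β₂/β₀ (dimensionless when β₀ is on the log-odds scale), reported
only for partial/full classifications. Proportions outside [0, 1]
(inconsistent mediation, e.g. opposing direct and indirect paths) are
returned as computed with a warning rather than clipped. The delta-method
SE of the indirect effect, √(β₂²se₁² + β₁²se₂²), assumes the two steps are
estimated from non-overlapping samples.

## Power

For a binary outcome the IVW z-statistic has approximate non-centrality
√(N·R²ₓᵤ·K(1−K))·|ln OR|, where N is the outcome sample size and K the
case fraction (the K(1−K) factor is the variance of the case indicator),
giving power Φ(ncp − z₁₋α/₂). The closed form is stated here precisely so
results are reproducible within the package; calculators built on the same
approximation may differ by small constant-factor conventions, which
matters little because power statements are usually threshold checks
(e.g. > 80%). `min_detectable_or()` inverts the formula by bisection to
1e-6.

## The synthetic-data generator

`sim_config()` / `simulate_sumstats()` generate paired
exposure/mediator/outcome summary statistics from the mediation diagram:
per-SNP exposure effects γⱼ ~ N(0, γ_sd²); mediator effects δⱼ = b₁γⱼ plus
mediator-specific instruments with their own effects; outcome effects
direct·γⱼ + b₂δⱼ + αⱼ, with αⱼ a pleiotropic term carried by a configurable
fraction of instruments (mean 0 = balanced, nonzero = directional).
Observed betas add normal noise with SE = 1/√(2·MAF(1−MAF)·n_eff), the
binary outcome using n_eff = N·K(1−K); p-values are the exact two-sided
normal p of β/SE. Palindromic allele pairs and swapped allele codings are
injected at configured fractions with full bookkeeping in the returned
truth, and the LD matrix defaults to identity because the pipeline
operates on clumped, quasi-independent instruments (a block-LD option
exercises the clumping code).

The defaults encode the study conditions the package is calibrated
against: 150 exposure instruments explaining ≈ 21% of exposure variance
(γ_sd = 0.0596 at MAF ∈ [0.1, 0.5], giving F-statistics mostly in the
30–150 range), exposure/mediator GWAS of 100,000, an outcome GWAS of
228,951 with 54% cases, total effect log(1.06) decomposed into
b₁ = 0.0438, b₂ = 0.1467 and the complementary direct effect (true
proportion mediated ≈ 0.110), and a 6% palindrome fraction (about nine
exclusions per 150 instruments). Fifty mediator-specific instruments
identify the mediator column in multivariable fits. Where the emulated
setting fixes no value (mediator GWAS size, mediator-specific instrument
count, MAF range), values were chosen once at magnitudes typical of
large-consortium behavioural GWAS and left alone.

What the generator does *not* emulate: genome-wide panels (only the
instrument neighbourhood is simulated), linked fine-scale LD, sample
overlap between the two samples, population stratification, and
winner's-curse-free instrument discovery (instruments selected in-sample
inherit a mild winner's curse, which attenuates β₀ and β₁ similarly and
largely cancels in the mediated proportion). Passing calibration tests on
this generator therefore demonstrates correctness of the estimators under
the stated model, not robustness to every pathology of real consortium
data.

## Numerical choices and degenerate inputs

Ties in clumping are broken deterministically (p, then SNP id);
`weighted_median` is bit-reproducible given its mandatory seed, as is
MR-PRESSO; RNG state is saved and restored around every seeded routine so
library calls do not perturb a caller's stream. Q-based model selection
uses strict inequalities exactly as stated above. Underdispersion is
clipped at 1 in every multiplicative-overdispersion SE. Wald ratios with
βexp = 0, empty harmonization intersections, all-outlier MR-PRESSO runs,
rank-deficient MVMR matrices and J ≤ K fits are hard errors with
informative messages. Validation drops rows violating hard invariants
(non-ACGT or identical alleles, SE ≤ 0, EAF outside [0,1], p outside
(0,1]) with counts, but a p-value merely inconsistent with β/SE (common
with rounded published statistics) only warns.

## Problem sizes used in the test suite

Unit tests run on instances of 3–50 instruments. The calibration suite
uses 500 replicates at J = 50 for IVW coverage and for the Egger
intercept's type-I rate under balanced pleiotropy, 100 seeds at J = 20
with 1000 simulations each for MR-PRESSO detection of a planted 10·SE
outlier, and 200 replicates at J = 150 for recovery of the mediated
proportion at the default effect sizes — sizes chosen to estimate the
relevant rates to within a couple of percentage points while keeping the
suite comfortably fast on a single core.

## Known limitations

No proxy-SNP lookup for instruments missing in the outcome GWAS; LD must
be supplied, never computed; no correlated-instrument (generalized) IVW,
mode-based estimators, MVMR-Egger, or Q-minimization MVMR; no bootstrap CI
for the mediated proportion (only the delta-method SE of the indirect
effect); power is for binary outcomes and univariable MR only. Figures are
left to the user: every result object is a plain data frame ready for
plotting.
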