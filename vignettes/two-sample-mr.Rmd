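---
title: "Bidirectional two-sample MR: model, decisions, and what the simulations show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional two-sample MR: model, decisions, and what the simulations show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimr)
```

## The estimation problem

Two-sample Mendelian randomization treats genetic variants as
instruments for an exposure. With summary statistics only — per-variant
effects γ̂ⱼ on the exposure and Γ̂ⱼ on the outcome, from non-overlapping
GWAS — the causal effect θ is identified under relevance, independence
and exclusion restriction. `bimr` targets the screening setting in which
dozens of molecular exposures (for instance a 91-protein cytokine pQTL
panel measured in ~15,000 people) are tested against a handful of
disease GWAS, and then the direction is reversed to ask whether disease
liability shifts the molecular traits.

Per variant the Wald ratio is Γ̂ⱼ/γ̂ⱼ with first-order standard error
σ_yⱼ/|γ̂ⱼ|. The pooled estimators are:

* **IVW**: weighted regression of Γ̂ on γ̂ through the origin, weights
  1/σ_yⱼ². This is exact inverse-variance meta-analysis of the Wald
  ratios and carries the most power when all instruments are valid.
* **MR-Egger**: the same regression with a free intercept after
  recoding every pair so γ̂ⱼ > 0. The intercept is the average
  directional pleiotropic effect; the slope remains consistent under
  InSIDE (instrument strength independent of direct effects).
* **Weighted median**: the 50% point of the weighted empirical
  distribution of ratios; consistent while valid instruments hold more
  than half the total weight.

Sensitivity statistics: Cochran's Q (weights γ̂ⱼ²/σ_yⱼ²) against the
IVW estimate; the Egger intercept t-test; and leave-one-out IVW, flagged
when any single exclusion flips the sign or moves the p-value across
0.05.

## Decision rule and multiplicity

A cell is called **robust** only when three criteria hold jointly:
no detectable pleiotropy (Egger intercept p > 0.05), direction agreement
across all available methods (IVW stays the designated primary estimate
when they disagree), and no leave-one-out outlier. Significance is
tiered per direction with a Bonferroni threshold of α/m over the m
exposures tested in that direction — 0.05/91 (displayed 5.5e-04) for the
forward screen, 0.05/3 (displayed 0.017) for the reverse — with p < 0.05
reported as *suggestive*. Criteria that need an unavailable method
(fewer than three instruments) are recorded as `NA`, never silently
passed.

## Tunable parameters

| parameter | default | rationale |
|---|---|---|
| primary / fallback selection p | 5e-8 / 5e-6 | genome-wide significance, relaxed only when fewer than `min_count` variants pass |
| `min_count` before fallback | 3 | smallest instrument set admitting MR-Egger |
| clumping window / r² | 10,000 kb / 0.001 | aggressive pruning appropriate for screening designs |
| weak-instrument cut | F ≥ 10, k = 1 per variant | conventional weak-instrument rule; the aggregate F (k = L, summed R²) is reported but not used for filtering, since the exclusion rule targets individual SNPs |
| palindrome ambiguity window | eaf ∈ [0.42, 0.58] | the conventional band within which A/T and G/C orientation cannot be inferred from frequency; pairs with a missing frequency are dropped rather than guessed |
| IVW variant | multiplicative random effects | the SE is never deflated below the fixed-effect SE; fixed effects by flag |
| ratio weights | first-order (ignore σ_x) | standard practice; exposure uncertainty enters the weighted-median bootstrap |
| weighted-median SE | parametric bootstrap, 1000 reps, seeded | canonical construction; the bootstrap runs on a private RNG stream so user-level reproducibility is unaffected |
| CI multiplier | 1.96 | 95% intervals throughout |
| p references | normal for Wald/IVW/WM; t with L−2 df for both Egger coefficients | small-sample conservatism where a residual variance is estimated |

Reverse-direction instrument selection uses the same primary threshold
and fallback rule as the forward direction; disease GWAS are large
enough that the fallback rarely triggers.

## Harmonization rules

Pairs are matched by variant id only (no positional or proxy matching).
Non-palindromic pairs are aligned by labels, complementing the outcome's
alleles when required; a swapped orientation negates the outcome beta and
reflects its frequency. For palindromic variants the labels carry no
strand information, so orientation comes from the allele frequencies:
both studies' frequencies must fall on the same side of 0.5, and the
pair is dropped when either frequency is missing or both lie in the
ambiguity window. Every action is recorded (`kept`, `sign_flipped`,
`strand_flipped`, `strand_flipped_and_sign_flipped`, `dropped_*`), and
the attrition table always sums to the instrument count. Two exact
invariances are enforced by tests: double-flipped outcome records
harmonize to the identical pair, and all causal estimates are invariant
to the exposure's allele-orientation convention.

## The synthetic generator

`generate_study_pair()` draws instrument loci with effects
γⱼ ~ N(0, `gamma_sd`²), resampled until the expected per-variant
F-statistic exceeds 10 (configurable), and simulates both studies'
summary statistics with the analytic standard error
1/√(2·maf(1−maf)·n) (times √(cf(1−cf)) extra shrinkage on the log-odds
scale for binary outcomes). Direct (pleiotropic) effects
αⱼ ~ N(μ, σ²) are attached to the *exposure-increasing* allele —
i.e. they enter the outcome as sign(γⱼ)·αⱼ. This is deliberate: with γ
symmetric about zero, a nonzero mean pleiotropic effect on an arbitrary
allele orientation is unidentifiable (the γ > 0 recoding inside MR-Egger
would average it to zero); the exposure-increasing orientation is
exactly the estimand the Egger intercept targets. An InSIDE violation
adds a mean-preserving component proportional to |γⱼ| − E|γ|.

LD is block-constant: loci are blocks of `ld_block_size` variants with
squared correlation `ld_within_r2` inside and 0 outside, tags carrying
attenuated effects √r²·γ. Blocks land on distinct chromosome/position
slots so greedy clumping is fully determined by block membership and
p-value order. Outcome files can be corrupted with allele-label swaps
and strand flips (probabilities per variant); both are pure
representation changes, so harmonization must — and, by test, does —
restore the uncorrupted effect pairs exactly.

Default conditions mirror a realistic well-powered screen: θ = 0.1,
30 loci, exposure n = 50,000, outcome n = 100,000, maf ~ U(0.05, 0.5),
`gamma_sd` = 0.1 (per-variant F from ~20 up to a few thousand at these
sample sizes). For the simulation studies shipped with the package, the
balanced-pleiotropy condition uses σ_α = 0.005 (direct effects small
relative to the median Wald-ratio noise) and the directional condition
μ_α = 0.02, σ_α = 0.01.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: winner's curse from discovery-stage
selection (instrument effects are drawn, not selected, from the same
sample), realistic human LD maps, sample overlap between studies,
allele-frequency differences between the two populations (frequencies
are shared exactly, which is also what makes the corruption-inversion
checks exact), and individual-level binary sampling (log-odds effects
are generated directly).

## What the simulations show

Problem sizes were chosen to give tight Monte-Carlo error at interactive
run times: 500 replicates for bias/coverage (θ = 0.1, L = 30), 1,000 for
the null rejection rate (θ = 0, L = 50, balanced pleiotropy), 500 for
Egger-intercept recovery (μ_α = 0.02), 200 random instances for the
estimator-vs-oracle comparisons, and a 5×2 study grid for the
determinism and completeness checks. Under these conditions IVW bias is
below 0.01 with empirical 95% CI coverage between 92% and 97%, and the
mean Egger intercept lands within two Monte-Carlo standard errors of the
generating μ_α; the exact values are recomputed, not quoted, by
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`.

## Numerical choices and degenerate inputs

* Greedy clumping breaks p-value ties lexicographically by variant id,
  making the retained set independent of input row order.
* Duplicate records keep the smallest p-value; ties keep the first
  encountered and are logged.
* `pval = 0` rows are rejected by default; a dialect flag clamps them to
  the smallest positive double and marks them instead.
* A single harmonized pair degrades `mr_fit()` to the Wald ratio; two
  pairs give IVW and Q but no Egger/weighted-median; those criteria are
  then not evaluable rather than passed.
* `beta_exp = 0` is a degenerate-instrument error for ratio-based
  estimators; bootstrap draws that hit zero are dropped from that
  replicate.
* Variance explained is capped just below 1 with a warning; the
  aggregate F uses the summed per-variant R² under the same cap.
* Missing optional columns disable exactly the stages that need them
  (positions → clumping, frequencies → palindrome resolution and R²,
  sample size → F), each with an explicit warning, never silently.

## Known limitations

The multiplicative random-effects IVW with an estimated overdispersion
factor and a normal reference is mildly anti-conservative under balanced
pleiotropy: at the shipped simulation conditions its type-I error sits
near the top of the 3.5–6.5% band rather than at 5%. MR-Egger's
intercept test has low power at realistic instrument counts, so
"no detectable pleiotropy" is weaker than "no pleiotropy". The package
deliberately omits proxy-SNP lookup, reference-panel LD estimation,
liftover, Steiger filtering and outlier-correction estimators
(MR-PRESSO-style); users needing those should pre-process their inputs
accordingly.
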