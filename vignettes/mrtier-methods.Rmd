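---
title: "Methods: summary-statistic causal inference and tiered gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-statistic causal inference and tiered gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtier)
```

mrtier chains five summary-statistic methods — two-sample Mendelian
randomization (MR), SMR with the HEIDI test, Bayesian colocalization,
two-step mediation MR, and a tiered evidence-integration rule — into a
causal-gene prioritization pipeline, together with a ground-truth simulator
for all of them. This vignette documents the models, their assumptions, the
defaults and why they were chosen, the numerical decisions, and what the
simulation-based validation does and does not establish.

## Data model and harmonization

All stages consume per-variant marginal association records (`sumstats`):
effect and other allele, effect-allele frequency, additive per-allele effect
(log-odds for binary traits), standard error, p-value, sample size. Records
violating basic invariants (se ≤ 0, p outside (0,1], non-ACGT or identical
alleles, duplicated ids) are dropped at construction and tallied rather than
propagated.

`harmonize()` aligns an outcome to the exposure's effect allele. Swapped
alleles flip the outcome beta and complement the frequency; opposite-strand
alleles are complemented and re-compared. Palindromic (A/T, C/G) variants are
the unsolvable case — complementation and swapping coincide — so they are
aligned by allele-frequency agreement, and dropped when the frequency is
missing or within 0.08 of 0.5 on either trait (band [0.42, 0.58]). The 0.08
half-width keeps a variant only when its minor allele is identifiable from
frequency with high confidence at typical GWAS sample sizes; it is a
parameter (`palindrome_eaf_window`), since cohorts with very accurate
frequencies can afford a narrower band.

`clump_variants()` implements greedy LD pruning: sort by ascending p-value,
ties broken lexicographically by variant id (this makes the output invariant
to input row order), retain a variant iff its r² with every retained variant
within the window is below the threshold. Defaults r² < 0.01 within
10,000 kb are the instrument-selection settings used throughout; the window
is a closed interval on base-pair distance. Variant pairs absent from the LD
matrix are treated as uncorrelated with a warning — the alternative
(dropping them) silently discards signal and was rejected. The unit test
suite checks the implementation against an independently written brute-force
oracle on all instances up to 12 variants.

Instrument strength uses the squared exposure z-statistic, F = (β/se)²,
with the conventional F > 10 filter; the set's mean F is reported.

## Two-sample MR

`run_mr()` is the central estimator and applies the method policy: one
instrument → Wald ratio; two or more → IVW as primary, with MR-Egger and the
weighted median added as sensitivity analyses from three instruments on.

- **IVW.** `β̂ = Σ β_Xj β_Yj w_j / Σ β_Xj² w_j`, `w_j = se(β_Yj)^{-2}`;
  fixed-effect se `(Σ β_Xj² w_j)^{-1/2}`. The default switches to a
  multiplicative random-effects se (inflation `max(1, √(Q/(n−1)))`) when the
  Cochran Q p-value falls below 0.05. Nothing in the pipeline depends on
  which variant is primary under homogeneity, since the inflation floor is 1;
  the switch guards against understated precision under heterogeneity while
  not rewarding underdispersion.
- **MR-Egger.** Weighted regression with free intercept after orienting all
  exposure effects positive; inference on n−2 df via the t distribution as a
  small-sample guard. The intercept estimates average directional
  pleiotropy.
- **Weighted median.** Ordered ratio estimates, estimate at the point where
  cumulative normalized inverse-variance weight crosses ½ with linear
  interpolation; first-order ratio variances `se_Y²/β_X²` as weights. The se
  comes from a parametric bootstrap (default 1000 draws, seed exposed) that
  resamples both exposure and outcome effects from their sampling
  distributions.
- **Diagnostics.** Cochran's Q on the per-instrument ratios with the same
  first-order weights; and an "outlier screen": a global test comparing the
  observed weighted residual sum of squares about the IVW fit with a
  parametric Monte-Carlo null (default 1000 simulations), plus leave-one-out
  standardized residuals with Bonferroni-corrected flagging at α = 0.05.
  This is a deliberately transparent stand-in for distortion-style outlier
  tests: it keeps the two decisions (is there global heterogeneity? which
  instruments drive it?) separable and fully seeded.

Assumptions inherited from the MR framework: instruments are associated with
the exposure, independent of confounders, and affect the outcome only
through the exposure; the two samples are non-overlapping; binary-trait
effects are log-odds and are exponentiated uniformly for OR reporting.

## SMR and HEIDI

`smr_test()` computes `T_SMR = z_x² z_y²/(z_x² + z_y²)` (χ²₁) at the top
cis-QTL, with effect `b = β_GWAS/β_eQTL` and se
`|b|·√(1/z_x² + 1/z_y²)`. `heidi_test()` asks whether `b` is constant across
SNPs in LD with the top QTL: candidates need QTL |z| ≥ 3.16 (p ≈ 1.6×10⁻³,
keeping the per-SNP ratio's delta-method variance trustworthy) and r² with
the top SNP in [0.05, 0.9] (excluding near-duplicates of the top SNP and
near-independent SNPs that carry no discriminating information), capped at
20 by descending |z|. These are the conventional settings of the published
SMR tooling and are all config-exposed. With fewer than three candidates the
HEIDI p is reported missing rather than computed from a 1–2 df statistic.

The deviations `d_i = b_i − b_top` get a covariance propagated from the LD
matrix by the delta method (both the QTL and GWAS layers contribute, scaled
by the respective sampling errors; the two samples are independent of each
other). `T_HEIDI = Σ (d_i/sd_i)²` is a weighted sum of χ²₁ with weights the
eigenvalues of the correlation matrix of d. Its tail is approximated by
moment matching a scaled non-central chi-square to the mixture's first three
moments (Liu–Tang–Zhang); two-moment Satterthwaite matching was measured
against a 100,000-draw Monte-Carlo oracle of the exact mixture and missed by
up to ≈0.022 in the mid-tail on 8-candidate regions, while the three-moment
match stays within ≈0.014 — inside the ±0.02 band the test suite enforces —
at negligible cost. Exact Imhof/Davies integration was not needed at that
accuracy.

FDR correction of SMR p-values (`smr_fdr()`) is Benjamini–Hochberg applied
*within one analysis* (one tissue/cohort at a time), matching the
column-wise criteria of the evidence matrix; pooling across analyses would
couple the columns and change the meaning of the per-column criterion.

## Colocalization

`coloc_abf()` re-implements the standard single-causal-variant Bayesian
framework: per-SNP Wakefield log-ABFs
`½[ln(V/(V+w)) + z²·w/(V+w)]` with prior effect variance `w = 0.2² = 0.04`
for both quantitative and binary (log-odds) traits, priors
p1 = p2 = 10⁻⁴, p12 = 10⁻⁵ (the conventional defaults; the constructor
enforces 0 < p12 ≤ min(p1,p2) < 1). All hypothesis mass is accumulated in
log space with log-sum-exp; the H3 cross term
`(ΣABF1)(ΣABF2) − Σ ABF1·ABF2` is computed as a log difference and clamped
at zero with a warning if floating cancellation drives it negative. A
single-SNP region yields PP3 = 0 identically, since no two-distinct-variant
configuration exists. Posteriors are checked against a naive
direct-summation oracle and must sum to 1 within 10⁻⁹. Grades: strong if
PP4 > 0.8, moderate if 0.5 < PP4 ≤ 0.8 (printed reports note the synonymous
"weak" label some tables use for this band), none otherwise — boundaries
strict.

## Mediation MR

`two_step_mediation()` combines exposure→mediator and mediator→outcome
estimates: indirect = product of coefficients, first-order delta se
`√(β_MY² se_XM² + β_XM² se_MY²)` (the second-order `se²se²` term available
behind a flag), proportion = indirect / total. The total is the direct
exposure→outcome MR estimate — not the sum of path products — because that
is the quantity a reader compares the indirect effect against; when the two
disagree in sign or the proportion exceeds 100% the value is reported
verbatim with a note, never truncated. The proportion's normal-theory
interval treats the three inputs as independent, which holds in the
three-sample design the simulator produces and is a stated approximation
otherwise. `screen_mediators()` gates step 1 by BH-FDR (q ≤ 0.05) and
step 2 by nominal p < 0.05 — both gates config-exposed — and ranks by
absolute mediation proportion.

## Evidence tiering

`build_matrix()` evaluates named criteria (source column, threshold,
direction) per gene; missing values never satisfy a criterion. A criterion
may `require` a companion: each HEIDI criterion requires its paired SMR
criterion, because a non-significant HEIDI p-value is only evidence *about*
a shared causal signal when the SMR association exists at all — without the
pairing, a gene with no SMR signal would collect HEIDI check-marks for free.
The packaged 11-gene worked example reproduces its reference tier labels and
all 99 per-cell marks only under this pairing.

`assign_tiers()` defaults: Tier 1 = all criteria satisfied; Tier 2 =
at least 4; Tier 3 = exactly 3; below that, unclassified (the worked example
contains no such gene, but new data can). The Tier-2 boundary is genuinely
ambiguous in prose ("more than four") versus practice (genes with exactly
four satisfied criteria labelled Tier 2); the default reproduces the
practice, and `tier2_strict = TRUE` selects the strict reading. Output
ordering (tier, descending count, gene name) makes the assignment
order-invariant.

## The simulator: what it emulates, and what it does not

`simulate_panel()` builds an AR(1) population LD structure
(`r_ij = ρ^|i−j|`) and publishes the *empirical* correlation of `n_ref`
simulated Gaussian haplotypes as the panel LD — the matrix a real analyst
would estimate from a reference cohort — while `simulate_gwas()` generates
marginal z-scores from the exact population matrix:
`z ~ MVN(√n·R·λ, R)` for standardized joint effects λ, then back-transforms
to the allelic scale via `1/√(2·maf·(1−maf))`. Generating from the empirical
matrix instead would amplify reference noise by √n into spurious cross-SNP
effects, which is a property of neither real data nor the model. The default
`n_ref = 5000` haplotypes reflects the reference sizes recommended for
region-level LD-aware tests.

Reference conditions (the defaults of `simulation_config()`):

| scenario | m | LD ρ | n (exposure / outcome) | effects |
|---|---|---|---|---|
| causal / pleiotropy / null | 50 instruments | 0 | 50,000 / 50,000 | λ_X ~ U(0.03, 0.08) per SD; β_XY = 0.2 (0 for null); pleiotropy offset 0.05 per allele |
| shared / linkage | 30-SNP region | 0.8 | 3,000 / 20,000 | QTL λ = 0.5 (top cis-eQTL scale), GWAS λ = 0.05; linkage r ≈ 0.6 |
| mediation | 2 × 30 instruments | 0 | 50,000 each | β_XM = 0.3, β_MY = 0.5, direct 0.1 → total 0.25, proportion 60% |

These are desk-scale stand-ins for biobank GWAS (tens of thousands of
cases+controls), eQTL cohorts (thousands of donors; top cis z-scores of
20–30 are routine), and genome-wide-significant instruments (z between ~7
and ~18, F between ~45 and ~320). The pleiotropy offset is defined per
allele so the planted Egger intercept is constant on the scale the
regression sees.

What the simulator does **not** model: binary-trait likelihood (log-odds
effects are generated on the Gaussian z-scale with an effective n — fine for
the moderate effects used, wrong for rare diseases), sample overlap between
exposure and outcome, population structure and relatedness, imputation
error, allele-frequency mismatch between cohorts, winner's-curse selection
of instruments, and multi-causal-variant regions. Passing calibration tests
on these simulations therefore shows internal correctness of the estimators
under their own assumptions, not robustness to the full failure catalogue of
real cohort data.

## Validation design and problem sizes

The test suite separates oracle identities from statistical calibration.
Oracles: IVW against a zero-intercept weighted regression; Egger against a
normal-equations solve; the weighted median against a cumulative-weight
scan; clumping against exhaustive greedy enumeration (≤12 variants); coloc
posteriors against naive direct summation; BH against hand-computed step-up
values; the HEIDI tail against the Monte-Carlo mixture oracle. Calibration,
at the reference conditions above: IVW 95% CI coverage within 95 ± 3% over
500 replicates and type-I error near 5% under the null; Egger recovery of
the planted 0.05 offset (a residual ≈2% attenuation from finite instrument
strength, mean F ≈ 150, is expected and tolerated); HEIDI rejection at
α = 0.05 within [0.02, 0.10] under a shared variant and far higher under
linkage; PP4 > 0.8 in ≥80% of shared-variant regions over 200 replicates;
mediation-proportion interval coverage 95 ± 4% over 300 replicates; and the
planted causal gene uniquely top-ranked in ≥90% of 20 end-to-end replicates
with four decoy genes. `scripts/acceptance.R` recomputes all of these from
scratch under a caller-supplied seed; replicate counts (500/500/200/500/150/
200/300/20) keep the full run under two minutes on one CPU.

## Known limitations

- Single-causal-variant assumptions throughout coloc and HEIDI; no
  conditional analysis or fine-mapping.
- No correction for sample overlap or winner's curse; no Steiger filtering
  or multivariable MR.
- The outlier screen replaces, and is not numerically identical to,
  MR-PRESSO's distortion test.
- The mediation proportion interval assumes independent legs; with shared
  samples it will be anti-conservative.
- Palindromic-variant resolution by frequency fails silently if both
  cohorts' frequencies are wrong in the same direction; the conservative
  drop band mitigates but cannot eliminate this.
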