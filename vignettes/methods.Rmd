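---
title: "Methods: two-sample MR and two-step mediation in mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR and two-step mediation in mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

# Scope and model

`mrmediate` implements summary-statistics Mendelian randomisation: all
inference is drawn from per-SNP GWAS effect estimates `β ± σ` for an
exposure, optional mediators and a (binary) outcome, never from
individual-level genotypes. The causal chain it targets is

> exposure *X* → mediator *M* → outcome *Y*, plus a direct *X* → *Y* path,

with SNPs as instruments for *X* (and, in the multivariable step, for
*M*). The usual instrumental-variable assumptions apply: instruments are
associated with the exposure, independent of confounders, and affect the
outcome only through the exposure. The sensitivity suite (Cochran's Q,
MR-Egger intercept, MR-PRESSO, Steiger) exists precisely because the third
assumption (no horizontal pleiotropy) is untestable per SNP and must be
probed in aggregate.

# Harmonisation

Two GWAS report effects relative to their own effect alleles, on either
strand. `harmonise()` aligns every shared SNP to the exposure's effect
allele: swapped alleles flip the outcome beta's sign and complement the
frequency; strand-complemented alleles are complemented first.
Palindromic SNPs (A/T, C/G) carry no strand information in their labels,
so they are resolved by allele-frequency concordance: retained only when
both frequencies fall on the same side of 0.5 *and* both lie outside
0.5 ± `palindrome_eaf_window`. The window defaults to **0.08**, a common
operating point for this rescue rule; it is a config knob, and a missing
frequency on either side drops the SNP (fail-safe). Dropped SNPs carry a
closed-vocabulary reason (`missing_in_outcome`, `palindromic_ambiguous`,
`allele_mismatch`) so audit trails are machine-checkable.

Harmonisation is idempotent and orientation-invariant (re-labelling every
outcome record's alleles with the matching sign/frequency flips leaves the
result unchanged); both properties are tested.

# Instrument selection

`select_instruments()` composes, in order: significance thresholding,
LD clumping, the outcome-association filter, harmonisation, the F filter,
the Steiger filter, and MR-PRESSO outlier pruning. The source criteria
are listed unordered; this order was fixed so that every filter needing
harmonised exposure–outcome pairs runs after harmonisation, and thresholds
needing only the exposure panel run first (cheapest first). Defaults:

| parameter | default | meaning |
|---|---|---|
| `p_primary` | 5e-8 | genome-wide significance |
| `p_fallback` | 5e-5 | used when < 5 SNPs pass `p_primary` |
| `clump_window_kb`, `clump_r2` | 500, 0.01 | greedy clump (`"bloodcell"` preset: 10,000, 0.001) |
| `p_outcome_min` | 0.05 | drop SNPs with outcome p ≤ 0.05 |
| `f_min` | 10 | weak-instrument cutoff, `F = (β/σ)²` |
| `steiger_filter` | on | drop SNPs with `r²(outcome) > r²(exposure)` |

The per-SNP F statistic is the squared Wald z — the standard single-SNP
approximation computable from summary data alone — and the variance
explained uses the scale-free form `r² = t²/(t² + n − 2)` rather than
`2p(1−p)β²`, so it needs no effect-scale assumptions.

Clumping is greedy on ascending p-value with lexicographic SNP-id
tie-breaking, which makes the retained set independent of input row order
(tested). PRESSO pruning iterates (re-test, remove flagged outliers) until
the global p exceeds 0.05 or fewer than 4 SNPs remain — 4 because the
resampling test needs leave-one-out variation to be meaningful.

## The outcome-association filter and the mediation stage

The "retain SNPs unrelated to the outcome (p > 0.05)" criterion is
designed to exclude SNPs with *independent* outcome associations
(pleiotropy). When the true causal effect is strong, however, valid
instruments are genuinely outcome-associated, and the filter then
preferentially removes the strongest valid instruments: conditioning on
|observed outcome z| < 1.96 selects SNPs whose outcome noise opposes their
signal and attenuates the total-effect IVW toward the null (in the
synthetic world below, from 0.20 to ~0.12, destroying delta-CI coverage).
In weak-effect screening regimes (odds ratios near 1.04) the filter is
nearly inert and is kept at its conventional default. In the mediation
stage the exposure–outcome and exposure–mediator effects are established
and strong by design, so `mediation_scan()` defaults to the
`"mediation"` profile with `p_outcome_min = 0` and delegates pleiotropy
exclusion to MR-PRESSO and Steiger. This is a deliberate design decision,
exposed as a parameter.

# Estimators

All confidence intervals use the fixed normal quantile 1.959964 (weights
treated as known, not t-based), so every reported odds ratio is exactly
the geometric mean of its CI bounds — an identity the tests assert to
floating precision and which also holds in published MR tables.

- **IVW** is the origin-weighted regression with weights `σ_Y⁻²`. The
  sources rarely state fixed- versus random-effects; the default is
  `"auto"` — multiplicative random effects when overdispersed
  (`Q/(n−1) > 1`), fixed otherwise — which matches prevailing two-sample
  MR practice and is conservative. Note `"mre"`'s
  `max(1, √(Q/df))` scaling makes `"auto"` and `"mre"` numerically
  identical; both names are kept for interface clarity.
- **Wald ratio** defaults to the first-order delta SE `σ_Y/|β_X|`; the
  second-order form adding `β_Y²σ_X²/β_X⁴` is behind a flag.
- **MR-Egger** orients all exposure effects non-negative before fitting
  (the intercept is only meaningful under a fixed sign convention, which
  the sources leave implicit) and scales SEs by `max(1, √(Q_E/(n−2)))`.
- **Cochran's Q** uses ratio-scale weights `(σ_Y/β_X)⁻²`, algebraically
  identical to the regression-scale residual sum of squares.
- **Steiger (set-level)** compares Fisher-transformed aggregate
  correlations `√Σr²` with effective sample sizes; a two-sided z-test, so
  exactly balanced variance explained gives p = 1.

# MR-PRESSO

The implementation follows the reference behaviour: the observed statistic
is the leave-one-out weighted residual sum of squares; each resample draws
`β*_X ~ N(β_X, σ_X²)` and `β*_Y ~ N(β̂₍₋ⱼ₎β_X, σ_Y²)` — conditioning on
the leave-one-out fitted values, not the full-set fit — and recomputes the
statistic identically. P-values use the add-one correction, so the global
p has resolution `1/(n_sim+1)` and is never zero. Outlier p-values are
Bonferroni-multiplied by the SNP count (BH behind a flag). Defaults
`n_sim = 5000`, outlier α = 0.05 are explicit choices; the sources name
the test without settings. The distortion test compares the IVW shift
after removing flagged outliers against removal of random subsets of the
same size.

# Multivariable MR and mediation

`mvmr_ivw()` solves weighted least squares of `β_Y` on the exposure-effect
matrix without intercept, weights `σ_Y⁻²`, with SEs from the
normal-equations covariance scaled by `max(1, √(Q_resid/(n−k)))`, and
refuses rank-deficient designs naming the collinear exposures. The
instrument set is the union of the per-exposure instruments, jointly
re-clumped — the dominant convention where the sources are silent. No
conditional-F statistic is computed (out of scope); a warning fires below
3 SNPs per exposure.

The mediation default is **pairwise** MVMR (exposure + one mediator),
matching the one-row-per-mediator structure of published mediation
tables; a joint all-mediators model is possible by calling
`build_mvmr_input()` directly.

`mediate()` is pure arithmetic plus the delta method:
`indirect = β_A β_B`, `SE = √(β_A²σ_B² + β_B²σ_A²)` (Sobel; second-order
term behind a flag), `direct = total − indirect`, signed
`proportion = indirect/total` with an `abs` companion. Published tables
sometimes print positive proportions for sign-opposed rows; the package
does not silently reproduce that convention — it emits both the signed
and absolute values and classifies such rows `inconsistent`.
Classification precedence (evaluated at level α, default 0.1, two-sided):
not-significant indirect → `none`; sign(indirect) ≠ sign(total) →
`inconsistent`; non-significant direct → `complete`; else `partial`.
The direct-effect SE uses the independence approximation
`√(σ_total² + σ_indirect²)`. No CI is reported for the proportion —
ratio distributions are unstable and published tables print it bare.

# Synthetic-data generator

`simulate_triplet()` draws, per exposure-instrument SNP *j*:
`eaf_j ~ U(eaf_range)`, true exposure effect `γ_j ~ N(0, sd_γ²)`, mediator
effect `α γ_j`, outcome effect `(θ_direct + α b_M) γ_j + u_j` with
pleiotropy offsets `u_j` on a configurable fraction of SNPs (mean
`pleio_sd` if directional, else 0). Observed effects add
`N(0, σ²)` noise with the standardised-genotype SE
`σ = 1/√(2p(1−p)n)`, which makes F and r² analytically checkable;
p-values are exact two-sided normal tails (floored at the smallest
positive double so panels always validate). Binary-outcome effects are
generated directly on the log-odds scale — two-sample MR consumes summary
effects only, and this keeps the generator closed-form. LD is
block-constant (sufficient to exercise greedy clumping), variants are
evenly spaced on one chromosome, and all allele pairs are non-palindromic
so harmonisation of generated data is always unambiguous (palindromic
logic is tested with hand-built fixtures instead).

Two generator choices deserve justification:

- **Mediator-specific variants.** If every SNP's mediator effect were
  exactly `α γ_j`, the exposure and mediator true-effect vectors would be
  perfectly collinear and multivariable MR would be unidentified — any
  apparent identification would come from measurement noise and shrink
  `β_B` severely. Real mediators have their own loci, so the generator
  adds `n_snps_med` SNPs with `δ_k ~ N(0, sd_M²)` on the mediator (and
  `b_M δ_k` on the outcome, no exposure effect). This is both realistic
  and the minimal structure under which the two-step decomposition is
  estimable.
- **Effect scale.** `exposure_effect_sd = 0.08` (and the same for
  mediator-specific effects) makes a default 30-SNP panel explain roughly
  8% of trait variance — typical of strongly instrumented molecular
  traits such as plasma metabolites — so most simulated instruments clear
  genome-wide significance at the default n = 50,000. Set once as the
  package's stated world; not a tuning knob.

What a green simulation test establishes: calibration and recovery under
a linear, homogeneous, summary-level world with exact normal noise and
known LD. What it does not: robustness to case-control ascertainment,
sample overlap between the two GWAS, allele-frequency mismatch between
populations, distance-decaying LD, or winner's-curse from discovery-based
instrument reuse — none of which the generator emulates.

# Screening and multiple testing

`mr_screen()` emits exactly one row per exposure (failures become status
rows, never exceptions), applies Benjamini–Hochberg within the family of
one screen invocation — the narrowest defensible family where the sources
do not name one; the choice is recorded in the run log — and classifies
significant rows `Risk` (OR > 1) or `Protect` (OR < 1). Because published
result sections often quote raw p < 0.05 while the declared criterion is
FDR < 0.1, both flags are reported (`raw_significant`,
`fdr_significant`); `significant` follows the FDR rule.
`reverse_screen()` is the same machinery with the roles swapped and the
stricter `"reverse_mr"` profile (p < 1e-8, 10,000 kb, r² < 0.001, F > 10).

# Numerical and degenerate-case policy

Ties: clumping breaks p-value ties lexicographically; the Steiger filter
retains exact ties (strict inequality removes). Degenerate inputs:
`β_X = 0` is a degenerate-instrument error for the Wald ratio; zero SNP
overlap is an empty-overlap error; an all-flat exposure panel is a
no-instrument error naming the failing stage. All comparisons against
oracles in the tests are at 1e-10 or tighter; stochastic calibration
bands follow the stated acceptance criteria, with replicate counts chosen
so the Monte-Carlo standard error is well inside each band.

# Known limitations

- LD must be supplied; the package never estimates it from genotypes.
- No weighted-median/mode estimators, no MVMR-Egger, no radial MR.
- The delta-method CI ignores the (small) covariance between `β_A` and
  `β_B` induced by shared mediator summary statistics.
- The generator's allele frequencies are identical across panels — no
  trans-ancestry frequency structure — so frequency-based palindrome
  rescue always succeeds on generated data.
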