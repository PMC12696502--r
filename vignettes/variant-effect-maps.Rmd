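---
title: "Scoring and calibrating variant-effect maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and calibrating variant-effect maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vemap)
```

This vignette explains the models behind `vemap`, the parameters that matter
and their defaults, the numerical choices made at the edges, and what the
synthetic-screen generator does and does not emulate. It is the package's
design record: wherever a choice was genuinely open, the reasoning is here.

## The screen being modelled

A tiled mutagenesis screen expresses a saturation library of protein
variants (one variant per cell on average), applies a selection that links
the assayed phenotype to cell frequency — competitive growth under a
restrictive condition for an activity readout, or a high-fluorescence sort
gate for an abundance readout — and sequences short tiles of the ORF deeply
before and after selection. A wild-type clone sequenced alongside estimates
the base-call/PCR error background. The measurable signal per variant is the
change in its read frequency between conditions.

Two anchor classes calibrate the score scale internally: stop gains
(nonsense) behave as complete loss of function, and silent changes
(synonymous) behave as wild type. After rescaling, score 0 means null, 1
means wild-type-like, values above 1 are "hyper" activity/abundance, and
0.5 — the anchor midpoint — is the conventional deleteriousness cutoff.

## Scoring pipeline

`score_pipeline()` composes six stages, each available separately.

**Frequencies.** Counts become reads per million: `f = count / depth * 1e6`.

**Filters.** A variant is excluded within a replicate when its pre-selection
count is below 10 or its pre-selection frequency does not exceed the 90th
percentile of wild-type-control frequencies. The percentile is computed per
tile by default (`wt_strata = "tile"`) because error rates are tile-specific
in tiled sequencing designs; whether the published pipelines pool across
tiles or classes is not documented, so the stratification is a switch.
Separately, `well_measured` requires a pre-selection frequency of at least
10 ppm; this flag gates downstream biological analyses but does not remove
the score.

**Error-corrected enrichment.** The wild-type-control frequency (the mean
over control replicates; per-replicate pairing is not documented for the
published pipelines, and the mean is the lower-variance choice) is
subtracted from both the pre- and post-selection frequencies. The ratio is
taken in log2 — the published descriptions say only "relative enrichment",
and the base cancels after rescaling, so any base would yield the same final
scores (a property the tests assert via affine invariance). The variance of
`log2(phi)` comes from the delta method with Poisson count noise,
`Var(f) = f * 1e6 / depth` on the ppm scale, propagated through the
subtraction; a parametric-bootstrap test confirms the approximation to
within 5% at representative frequencies.

**Flooring.** A corrected post-selection frequency at or below zero is
floored at half a read per depth: depletion to zero is real signal, and the
floor gives it a finite, conservative log-ratio. A corrected pre-selection
frequency at or below zero instead marks the variant unmeasurable — absence
before selection carries no usable information. This asymmetry is
deliberate.

**Rescaling.** Within each replicate,
`s = (log_phi - median_nonsense) / (median_synonymous - median_nonsense)`.
The operation requires at least 10 measurable variants in each anchor class
(configurable) and errors out when the synonymous median does not exceed
the nonsense median — a screen with no selection separation has failed, and
emitting rescaled scores from an inverted or null separation would be
meaningless. Stop gains at the final codon are excluded from the nonsense
anchor (they truncate almost nothing and cannot represent loss of
function); position-1 variants are enumerated but flagged `start_codon`,
since start-loss is not a missense map entry.

**Error regularization.** Replicate-level standard errors are shrunk toward
a robust trend of `log(se)` on `log10(f_pre)`:
`var_reg = (m * se_model^2 + df * se_emp^2) / (m + df)` with prior degrees
of freedom `m = 2` and one degree of freedom credited to each replicate's
own estimate. The trend fit is least absolute deviations (via iteratively
reweighted least squares): the cloud of per-variant error estimates has
heavy tails, and LAD ignores them without a tuning constant. Fewer than 20
usable variants leaves errors unregularized with a warning.

**Combination.** Inverse-variance weighting: `s = sum(w_r s_r) / sum(w_r)`
with `w_r = 1/se_r^2`, `se = sqrt(1/sum(w))`, degrees of freedom by
Welch–Satterthwaite. A single-replicate variant passes its error and
degrees of freedom through unchanged; a variant with no measurable
replicate is absent from the map.

## The synthetic-screen generator

`sim_config()` defaults describe the study conditions the package targets:

| parameter | default | meaning |
|---|---|---|
| `n_replicates` | 2 | biological replicates (activity screens often run 4) |
| `depth` | 2e5 | reads per tile; full screens exceed 1.3e6, scaled down so the suite runs in seconds |
| `theta` | 0.3 | deleterious missense fraction (observed maps: ~25% activity, ~33% abundance) |
| `mode_deleterious`, `mode_neutral` | 0, 1 | missense mixture centres on the anchor scale |
| `sd_deleterious`, `sd_neutral` | 0.15, 0.12 | mixture spreads, chosen to reproduce the clear bimodality of real maps |
| `lambda` | 0.64 | mean codon substitutions per cell (0.83 for abundance-style screens); sets each tile's variant read fraction |
| `clones_per_variant` | 50 | minimum clone multiplicity; pre-selection dispersion is the mean of this many log-normal clone sizes |
| `selection_fold` | 16 | post/pre enrichment fold between effect 1 and effect 0 under growth selection |
| `gate_slope`, `gate_midpoint` | 8, 0.5 | logistic gate-pass probability for sort selection |
| `error_rate` | 5e-6 | wild-type-control background frequency per SNV-reachable variant |

Effects are drawn per class — synonymous exactly 1, nonsense exactly 0,
missense from the two-component normal mixture clipped to [−0.5, 1.5] so
that above-wild-type ("hyper") scores exist while the mixture stays proper.
The growth model multiplies pre-selection frequency by
`selection_fold^score`; the exponential link is a stand-in (no published
functional form links growth rate to score in the yeast assay) and is
isolated behind the `assay` argument. The gate model uses a logistic
pass probability — the minimal smooth gate given only "high-fluorescence
sort" as a description. The unmutated background behaves as an effect-1
competitor, so deleterious variants deplete relative to it. Sequencing
error adds `error_rate` to the expected frequency of every SNV-reachable
variant in all three conditions; restricting error to single-base-miscall
neighbours approximates base-calling error structure without read-level
simulation. Observed counts are one multinomial draw per (tile, condition,
replicate) at the configured depth.

What the generator does *not* emulate: read-level errors and posterior
base-calling (the pipeline starts at count tables), multi-mutant clone
genotypes and their marginal-count confounding (`lambda` is used only to
set tile read fractions), tile-boundary edge effects, and replicate-level
batch effects. Passing tests therefore demonstrate correctness of the
computation and calibration machinery under a faithful noise model — not
that any particular real screen meets these assumptions.

`simulate_reference_set()` produces clinical-style labels: positives from
the low-effect extreme, negatives from the high-effect extreme, with an
`overlap` knob that mixes in effect-independent labels (0 = perfectly
separable, 1 = labels independent of effect, giving AUBPRC near 0.5).

## Map analyses

Quadrant classification thresholds both maps at 0.5 with a strict `<`
(a variant exactly at 0.5 is non-deleterious, following the "<0.5"
convention), restricted to variants well measured in both maps. The
dominant per-position quadrant is a strict plurality; ties give no label.
Group contrasts use the Mann–Whitney U test (exact for small samples
without ties, normal approximation otherwise) with Benjamini–Hochberg
adjustment across the tested pairs — the published "adjusted p" values do
not name a method, and BH is the field default. Burial classes use fixed
solvent-exposure thresholds (exposed > 35%, buried < 20%); stability
classes use the ΔΔG conventions (negative = destabilizing;
stabilizing-or-neutral above −0.1, destabilizing below −0.5), and
"stable-but-inactive" variants are those deleterious in a map
(score < 0.5) yet stabilizing-or-neutral. The moving window defaults to 10
positions with step 1 — no published window size exists; 10 residues spans
a secondary-structure element, which is the granularity the analysis is
after. Depletion odds ratios use the Haldane–Anscombe 0.5 correction for
zero cells (the Fisher exact p is unaffected). Phenotype and substitution
correlations default to Spearman for robustness, with Pearson available,
since published figures mix both.

## Clinical calibration

Balanced precision reweights the positive and negative sets 50/50 by Bayes'
rule: `bp = recall / (recall + fpr)`. With equal-sized sets it reduces to
ordinary precision (an identity the tests check), and it is invariant to
reference-set imbalance. The curve evaluates every unique score as a
threshold (called positive when `score <= t`; lower score = more
pathogenic, as both assays are loss signals). Endpoints: the curve extends
to recall 0 carrying the tightest threshold's balanced precision, and to
recall 1 with balanced precision 0.5 (the uninformative limit) when the
loosest threshold does not already reach it; AUBPRC is the trapezoidal
integral over recall; R80BP is the maximum recall among thresholds with
balanced precision at least 0.80.

LLRp is the log10 ratio of Epanechnikov kernel density estimates of the
positive and negative reference score distributions. The bandwidth is
Sheather–Jones (solve-the-equation) for a Gaussian kernel, converted by the
canonical-bandwidth ratio `15^(1/5) / (1/(2*sqrt(pi)))^(1/5)` (about
2.214), since direct SJ selection for non-Gaussian kernels is not standard.
Because the Epanechnikov kernel has compact support, each density is
floored at `1/(10 * n * range)` before the ratio — without a floor, any
score outside one set's support would give an infinite LLR; floored points
are flagged. With equal-sized reference sets the floors cancel, so scores
outside both supports get LLR exactly 0 rather than an arbitrary sign.
Confidence intervals come from a percentile bootstrap that resamples each
reference set with replacement (the published work does not state its
resampling unit; resampling the reference sets propagates the dominant
uncertainty, which is the small size of the labelled sets). Evidence
strengths use log10 so the Tavtigian combined-odds constant applies
directly: with `C = log10(350)`, pathogenic supporting/moderate/strong/very
strong thresholds sit at `C/8, C/4, C/2, C` and the benign ladder mirrors
the first three. The prior (default 0.1) and odds constant are exposed in
the configuration because adapted calibrations vary between studies.

## Numerical notes and degenerate inputs

- Rescaled anchor medians are exact by construction; with an even anchor
  count the reported median can differ from the exact value by one ulp
  (averaging two rescaled values rounds differently than rescaling the
  median).
- `kde_density()` refuses fewer than 5 points or zero-variance data unless
  an explicit bandwidth is supplied; `bw.SJ` failures on degenerate
  bootstrap resamples fall back to the original bandwidth.
- Reference-set sampling breaks effect ties randomly under its seed, so
  `overlap = 0` gives strict separability up to exact score ties at the
  clipped support boundary.
- All readers reject malformed input (unknown conditions, duplicate
  variants, conflicting labels, unknown configuration keys) rather than
  coercing it.

## Problem sizes in the test suite

The suite exercises the full pipeline at a 154-codon ORF (3,234 variants,
5 tiles, 2 replicates, 2e5 reads per tile), which recovers simulated truth
at Pearson r ≈ 0.97 in a few seconds; oracle-equivalence checks run on
toy bundles of at most 20 variants against spreadsheet-style
recomputation at 1e-12 relative tolerance, and exact-test checks enumerate
all arrangements for group sizes up to 8. Bootstrap coverage is checked
with 400 resamples over 150-point reference sets. These sizes are the
package's choice of a desk-scale experiment: large enough for the
stochastic properties to hold with pinned seeds, small enough to iterate
on.

## Known limitations

- The exponential growth link and logistic gate are plausible stand-ins,
  not fitted models; inference about absolute selection strength should not
  lean on them.
- Scores for variants with a single measurable replicate inherit that
  replicate's (regularized) error and are only as trustworthy as the trend
  fit.
- The LLR calibration is only as good as the reference sets; with
  proxy-benign negatives, performance estimates are conservative, and the
  evidence strengths have not been endorsed by any curation body.
- Multi-mutant clones, which can confound marginal counts in real
  libraries, are outside the generator and the scoring model; high clone
  multiplicity mitigates but does not remove this in real data.
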