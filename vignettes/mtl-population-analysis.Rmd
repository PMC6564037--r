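---
title: "Population analysis of MTL single-neuron recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population analysis of MTL single-neuron recordings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtlpop)
```

`mtlpop` analyses single-unit spike trains recorded from the human medial
temporal lobe (amygdala AM, hippocampus HC, entorhinal EC, parahippocampal
PHC cortex) during a screening paradigm in which 100 images — 10 semantic
categories of 10 exemplars — are each shown once per run in 10 pseudorandom
runs (1,000 trials).  This vignette documents the statistical procedures,
the generative model behind the synthetic sessions, the defaults and their
rationale, the numerical decisions taken where the literature is silent, and
what the synthetic conditions can and cannot show about real recordings.

## The synthetic population: a semantic tuning-curve model

Real sessions of this paradigm are clinical data without a public accession,
so every analysis here is exercised on synthetic sessions with known ground
truth.  The generator is *not* a neutral fixture: its structure encodes the
scientific hypothesis under test — that MTL firing is graded along a
semantic tuning curve rather than all-or-none — so that each analysis stage
has a condition under which it must fire and a null under which it must not.

**Trial timeline.**  Each trial is a blank inter-trial gap drawn uniformly
from 200–400 ms, a 300 ms fixation period, the 1,000 ms response window, and
a 200 ms post-window viewing tail; successive onsets are therefore
1.7–1.9 s apart, and the −500–0 ms baseline window always falls in
unmodulated time.  Within each run the stimulus order is a fresh
permutation.

**Firing model.**  Unit $u$ fires as a piecewise-constant-rate Poisson
process, simulated by thinning a homogeneous process at the unit's maximal
rate: the rate is the baseline $b_u$ everywhere except during the 0–1,000 ms
response window of a trial showing stimulus $s$, where it is
$b_u\,(1 + g_{us})$.  Baselines are lognormal with `meanlog = log(2)`,
`sdlog = 0.6` (median 2 Hz), matching the low spontaneous rates typical of
MTL microwire units.  Thinning with a single rate ceiling is exact for a
piecewise-constant intensity and is the simplest process consistent with
the rate model; there is deliberately no bursting, refractoriness or latency
dynamics (see *Limitations*).

**Semantic tuning.**  The ten categories live at fixed coordinates in a
two-dimensional embedding (`default_semantic_geometry()`): man-made objects
on one side, natural objects on the other, the two food categories adjacent
across that divide, and the three animal categories clustered.  A tuned unit
(probability `p_responsive = 0.6`) draws a preferred category (region
profiles can bias this draw), jitters its preferred point around that
category's coordinates (`pref_jitter_sd = 0.15`), and receives a category
gain that decays as a Gaussian in embedding distance with length scale
`tuning_width = 0.7`, peaking at `category_gain = 1.0` (a rate doubling).
On top of that graded curve, each exemplar receives an additive gain
perturbation shared across its trials (`exemplar_gain_sd = 0.15`), and a
Poisson-distributed number of exemplars of the preferred category
(`n_supra_exemplars = 1`) receive a large supra-threshold gain
(`supra_gain = 12`).  Gains are floored at −0.9 so rates stay positive.

The two-tier structure mirrors the phenomenology the analyses are meant to
dissect: the sparse supra-threshold responses are what the screening
criterion detects, while the graded sub-threshold curve is what makes
*non-responsive* units still carry category information at the population
level.

**Region profiles.**  AM-profile units sample their preferred category with
a 3-fold weight on the two food categories (the recorded food preference of
amygdala units); PHC-profile units are less selective — weaker graded gains
(scale 0.7) spread over more supra-threshold exemplars (Poisson mean 2.5,
gain 9), which reproduces the lower fraction of single-stimulus responders
in parahippocampal cortex.  EC and HC use the shared defaults.

**Calibration of defaults.**  No quantitative sub-threshold effect size is
available for the real populations, so the defaults above were fixed once so
that the qualitative headline phenomena hold robustly at desk scale (320
units): roughly a third to a half of units pass the screening criterion,
per-category response probabilities land in the sub-percent to few-percent
range, within-category population vectors are reliably more similar than
between, category decoding generalises far above the 10% chance line, and
identity decoding exceeds 1% with within-category confusion excess.  These
defaults are a statement about the synthetic study conditions, not a
measurement of the real data.

**Null generator.**  `generate_null_population()` forces every gain to zero;
it is the calibration bed for the screening criterion's false-positive rate
and for the permutation tests' null behaviour.

**Control images.**  `generate_images()` builds one smooth random template
per category (low-passed white noise, mean 128, SD 40 on a declared 0–255
scale) and adds per-pixel noise per exemplar.  Within- versus
between-category pixel similarity is thereby controllable: `noise_sd = 0`
makes exemplars identical; very large noise removes category structure.

## Response screening

For each unit × stimulus pair, spike counts in 19 overlapping 100 ms bins —
edge lists 0:100:1,000 ms (10 bins) and 50:100:950 ms (9 bins), all bins
half-open $[a, b)$ — are each compared against the distribution of baseline
counts (−500–0 ms) over *all* 1,000 session trials, with a one-sided
Mann–Whitney rank-sum test for increases only.  The 19 p-values enter the
Simes rule: the pair is a response if the sorted p-values satisfy
$p_{(i)} \le i\,\alpha/19$ for some $i$, at $\alpha = 0.001$.  Two filters
apply on top: more than 5 of the 10 trials must contain at least one
response-window spike (strict inequality), and the mean response-window
rate must exceed 2 Hz.

Numerical decisions:

* **Ties.**  Counts are small integers, so ties dominate.  For combined
  samples up to 20 observations the rank-sum p-value is computed by
  exhaustive enumeration conditional on the observed values; beyond that the
  normal approximation with mid-ranks, tie-corrected variance and a 0.5
  continuity correction is used.  In a session the baseline sample has
  1,000 trials, so the approximation path is the one that matters; the
  enumeration path exists so that small hand-checkable instances are exact.
* **Unequal windows.**  The criterion literally compares 100 ms response
  counts against 500 ms baseline counts.  This makes the test conservative:
  a response bin must beat baseline windows five times its length, i.e.
  only strong (several-fold) rate increases are detectable.  That is the
  intended character of the criterion — it selects sparse, burst-like
  responses and leaves graded modulation sub-threshold.
* **Rate filter.**  The 2 Hz filter is applied to the mean across the
  stimulus' trials of the response-window rate (the natural reading of an
  "average firing rate during the response window").
* **Response probabilities.**  The per-(region, category) response
  probability divides flag counts by units × stimuli.  The default uses the
  per-category stimulus count (10) so categories are directly comparable;
  `normalisation = "total"` (all 100 stimuli) is available as the printed
  convention of earlier work.  Confidence intervals subsample 700 units
  without replacement 2,000 times; a region with fewer units falls back to
  80% of its size with a warning.
* **Category preference.**  Fisher's exact test on the 2 × 2 table of
  responses/non-responses in a category versus all others, Bonferroni
  corrected at $0.05/(\text{regions} \times \text{categories})$ — 0.05/40
  for the full design.  (A printed "α = 0.0540" in the source literature is
  typographically ambiguous; 0.05/40 is the reading consistent with a
  Bonferroni correction over 40 cells.)

## Representational similarity

Each unit's response-window rate is z-scored with the mean and SD of its
baseline-window rates across all trials; stimulus-level rows average the
10 trials of a stimulus before z-scoring.  Dissimilarity between two
population vectors is $1 - R$ (Pearson), giving values in $[0, 2]$.

* Units with zero baseline SD carry no z-scale and are excluded with a
  message (an epsilon floor is available via `sigma_zero = "floor"`).
* A constant row vector has no defined correlation; its pairwise distances
  are set to 1 ($R$ treated as 0) and reported, keeping the matrix complete
  while marking the rows as uninformative.
* Clustering uses unweighted average linkage (UPGMA) on the correlation
  distances; merge-height monotonicity is checked and violations warned
  about.  Leaf-order category contiguity quantifies the "exemplars line up"
  observation.
* The embedding is classical (Torgerson) metric MDS; axes beyond the number
  of positive eigenvalues are zero-padded.

**Permutation inference.**  The observed statistic is the Mann–Whitney
rank-sum of within-category distances among all upper-triangle distances
(dissimilarity matrices are symmetric, so the triangle avoids
double-counting).  The default null shuffles the assignment of matrix cells
to the within/between partition, preserving the two set sizes — exactly the
published cell-index-shuffling procedure.  The reported p is the percentile
of the observed statistic in the null distribution, without the $+1$
correction (available via `plus_one = TRUE`); with $10^5$ shuffles the
smallest reportable value is 0, read as $p < 10^{-5}$.  Because cells of a
distance matrix are not exchangeable (two cells sharing a stimulus are
dependent), this null is liberal in principle; the stricter
`null = "stimulus-label"` permutes category labels over stimuli instead and
is provided for sensitivity analyses.  Exhaustive enumeration over all
partitions replaces Monte Carlo on small instances (`exact = TRUE`).

## Decoding

Both decoders use one-vs-all linear max-margin classifiers: for each class a
binary hinge-loss SVM (positive class versus rest) is trained, and a test
row is assigned to the class with the maximal decision value, ties broken by
the lowest class index.  The binary problems are solved in the dual by
coordinate descent (the standard large-scale linear-SVM scheme) with a
deterministic permutation stream, so decoding is bit-reproducible; the
soft-margin constant defaults to 1 on the already z-scored inputs and is
exposed in `decoding_scheme()`.

* **Category generalisation** trains on the stimulus-level matrix
  ($N_S \times N_U$) using half the exemplars of every category and tests on
  the held-out exemplars — above-chance performance requires the category
  code to generalise to unseen stimuli.  Chance is 10%.
* **Identity decoding** trains on the trial-level matrix ($N_T \times N_U$)
  using half the trials per stimulus; chance is 1%.

Performance is summarised per split as accuracy and Cohen's
$\kappa = (P_O - P_C)/(1 - P_C)$; $P_C$ comes from the confusion-matrix
marginals (standard Cohen), with `chance = "uniform"` ($1/K$) as a switch
since "chance agreement" is not otherwise pinned down.  Confusion matrices
are aggregated over the 100 splits before inference (matching the use of a
single confusion matrix per analysis); the within- versus between-category
confusion test uses all off-diagonal cells of the aggregated (asymmetric)
matrix — diagonal cells are correct classifications, not confusions — with
the same partition-shuffling null, one-sided for within excess.

## Image controls

Four pixel-level measures are computed per image pair: Euclidean distance,
MSE, PSNR and SSIM.  PSNR and SSIM are similarities and are also reported as
distances (`max(psnr) − psnr`, `max(ssim) − ssim`); identical pairs have
infinite PSNR, are excluded from the `max(psnr)` reference and assigned
distance 0.  SSIM uses the standard constants $K_1 = 0.01$, $K_2 = 0.03$
and an 8 × 8 uniform window on grey-scale intensities with the declared
dynamic range; inputs are assumed grey-scale (a luminance conversion is the
caller's responsibility, as the measures are defined on single-channel
arrays).  `image_rsa()` wraps any of the four distance matrices as a
dissimilarity object so clustering, MDS and the permutation test apply
unchanged — the control asks whether pixel-level similarity alone reproduces
the semantic organisation seen in the neuronal matrices.

## Problem sizes and reproducibility

The packaged analyses run at desk scale: 320 units (80 per region),
100 stimuli, 1,000 trials, $10^5$ permutation shuffles, 100 decoding
splits.  The test suite exercises most operations on a reduced 4 × 3 × 4
design (12 stimuli, 48 trials, 12 units) and reserves the full design for
the end-to-end checks; `scripts/acceptance.R` recomputes every headline
quantity from a single seed in a few minutes on one CPU.  All stochastic
stages — generation, subsampling, shuffles, splits, the classifier's
internal permutation stream — are seeded, and a config hash stamps pipeline
outputs.

## Limitations

* The generator's units are conditionally independent Poisson processes
  with a flat response profile over the full 1,000 ms window.  Real MTL
  responses are transient and latency-structured, units share noise
  through common input, and sessions differ in unit yield; passing tests
  therefore demonstrate the *correctness of the procedures* under the
  tuning-curve model, not the effect sizes of the clinical data.
* Because population noise is clean and exemplar gains are stable across
  trials, identity decoding on the default population is far more accurate
  (median around 90%) than reported for real recordings; the qualitative
  contrasts — above-chance generalisation, within-category confusion
  excess, and the dissociation under exemplar-only tuning — are the
  meaningful outcomes.
* The screening criterion's responsive fraction (roughly 40% at defaults)
  emulates the *profile* of regional selectivity, not the exact responsive
  percentage of the recorded populations, which depends on spike sorting
  and unit yield outside this model.
* The permutation test's default cell-shuffling null inherits the published
  procedure's exchangeability caveat discussed above; conclusions that
  survive the stricter stimulus-label null are the robust ones.
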