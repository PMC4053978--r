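---
title: "Methods: fitness profiling across a carbon-by-nitrogen grid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fitness profiling across a carbon-by-nitrogen grid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnscreen)
```

# The experiment this package models

A prototrophic yeast deletion collection (4,772 non-essential gene
deletions plus a wild-type control strain) is pinned onto an array of
sixteen 384-format plates (16 rows x 24 columns) and grown on minimal
media built from every pairwise combination of four carbon sources
(glucose, galactose, ribose, glycerol) and seven nitrogen sources
(ammonium, proline, glutamate, glutamine, arginine, urea, allantoin) --
28 conditions. One entire plate carries the wild-type strain and further
wild-type replicates are scattered over the rows and columns of every
other plate, 701 wild-type positions in all. The reference condition,
glucose:ammonium, is screened as six replicate plate sets. Plates are
imaged at 0, 5, 10 and 24 hours (48 h added for glycerol) and colony
areas are extracted from the images; those per-colony area time courses
are where this package's work begins.

The question asked of each mutant x condition cell is a
*gene-environment interaction*: did this deletion strain grow slower (or
faster) in this condition than expected from its own fitness in the
reference condition and from the condition's effect on the wild type?

# The pipeline

## Growth rates

Each colony's growth rate is the ordinary least-squares slope of area
(pixels) on time (seconds), with an intercept because pinned colonies
start at the pin area. Fewer than two usable scans give a missing rate;
a negative fitted slope is defined to be 0 (the colony did not grow).
Positions manually curated as "correctly plated but non-viable" are
forced to rate 0 while staying distinct from missing data.

## The glucose:ammonium reference

For each array plate, the six glucose:ammonium replicates are merged:
the replicate with the fewest missing values is held out as the anchor,
the other five are LOWESS-normalized to it, and all six are averaged
positionwise into the reference plate. The positionwise standard
deviation of the six normalized replicates about the reference gives the
strain-wise SD used later in the z-score denominator.

`lowess_normalize()` implements the rate-dependent rescaling used
throughout: the ratio target/plate is smoothed against the plate's own
rate (locally linear LOWESS, one robustifying iteration, window = 50% of
the jointly finite positions, evaluated at the observed rates with
linear interpolation), and each rate is multiplied by the smoothed
ratio. Identical plates are a fixed point; a constant scale factor is
recovered to machine precision; zero rates are excluded from the ratio
fit (the ratio is undefined there) and pass through so dead colonies
stay dead. When the robustness pass degenerates (an exact fit has zero
residual MAD) the plain pass is used, and a plate with a single distinct
rate falls back to the mean ratio.

## Condition normalization and spatial filtering

Every experimental plate is LOWESS-normalized against its array plate's
glucose:ammonium reference, removing the wholesale growth-rate
difference between the condition and the reference so that residuals
reflect strain-specific deviation only.

The spatial filter then removes smooth plate artifacts: extreme values
(top and bottom 5%) and missing positions are temporarily replaced by
the plate mean, refined over three passes to their two-dimensional
Gaussian-filtered value, and the zero-mean residual of the smoothed
plate is subtracted. Refining *all* masked cells (not only the missing
ones) matters: a plate-wide gradient's tails are exactly the trimmed
extremes, and anchoring them at the mean caps gradient removal near
83%; with refinement the filter removes >90% of a planted linear
gradient. Because only a zero-mean residual is subtracted, the plate
mean is preserved exactly on complete plates. The Gaussian kernel uses
sigma = 2 grid units, truncated at 3 sigma, with reflective boundaries:
wide enough to ignore single colonies, narrow enough to follow
plate-scale trends. Filtering is applied to normalized rates, between
normalization and z-scoring, so the subtracted residual is on the
reference scale; `run_pipeline(spatial_smooth = FALSE)` switches it off.

## Modified z-scores and the wild-type null

For each position on each experimental plate,

$$z = \frac{\mathrm{norm} - \mathrm{ref}}{\sqrt{sd_\mathrm{strain}^2 + sd_\mathrm{plate}^2}}$$

where `sd_strain` is the positionwise SD across the six reference
replicates and `sd_plate` is the SD of the residuals across the finite
positions of that plate, separately per condition -- it absorbs the
general growth variation of the plate. `sd_plate` is computed on
residuals (not raw normalized rates) and over all finite positions
including wild-type. Negative z means slower growth than the nutrient
environment alone predicts. Strains occupying several array positions
are averaged at the z level (z is the per-position unit of the formula).
A zero combined variance makes z undefined and is reported as an error
listing the offending positions rather than silently propagated.

Note that this z is *not* standard normal under the null: combining the
strain-wise and plate-wise SDs double-counts measurement variance, so
wild-type z have SD well below 1. This is precisely why the null is
*fitted*: the mean and SD of the 701 wild-type replicate z-scores define
the normal distribution from which one-sided p-values are computed
(lower tail for slow, upper for fast).

## Hit calling at a condition-specific FDR

Within each (condition, direction) family the Benjamini-Hochberg step-up
rule is applied at the desired FDR (10% and 20% thresholds are always
computed; hits default to 20%). The reported threshold is the *least
extreme* rejected z -- the boundary delimiting the rejection region --
so that calling `z <= threshold` (slow) or `z >= threshold` (fast)
reproduces the BH rejection set exactly; an infinite sentinel marks
families with no rejection. Glycerol conditions are never z-scored:
mutant growth there is too slow and noisy to call effects, though
glycerol wild-type rates still feed the growth model below.

Downstream summaries: per-condition fast/slow counts (the six reference
replicate instances averaged into one, possibly fractional, count per
pair), per-gene effect counts over distinct nutrient pairs outside an
exclusion set, and source-sensitivity sets (e.g. genes slow in at least
4 of the 7 galactose conditions).

## Wild-type carbon-by-nitrogen model

Wild-type replicate rates across all 28 conditions are fit by OLS on the
natural-log scale with carbon and nitrogen main effects and their
interactions, reference-cell coding with glucose and ammonium as
baselines -- so the intercept is the log reference rate and a
significant interaction term (alpha = 0.01 per term) flags a condition
whose wild-type rate is not the product of its sources' independent
contributions. Replicate-level fitting (not condition means) yields the
displayed standard errors. Zero rates are excluded from the log fit and
counted. `compare_model_families()` fits the same design additively on
the raw scale and compares information criteria on a common response
scale (the log-model likelihood converted by the log-normal change of
variables); on multiplicatively generated data the multiplicative family
wins essentially always, and vice versa.

Under reference-cell coding only the 3 x 6 = 18 non-reference cells
carry interaction terms; the 10 reference-row/column cells have none by
construction. `independent_conditions()` therefore reports
non-significant cells out of 18, the model's analogue of the "conditions
predicted by independent contributions" count.

## Source signatures by fixed-coefficient NMF

Gene-level z-scores are binarized at the 20% FDR condition-specific
thresholds (slow effects only by default -- the signatures are read as
per-source *sensitivity* lists; a flag admits both directions). Glycerol
columns are absent by construction, only the first glucose:ammonium
replicate column is kept so the source-composition columns stay
distinct, and all-zero gene rows are dropped. The binary `Data` (genes x
21 conditions) is approximated as `Signatures x Coefficients`, where
`Coefficients` is the fixed 10 x 21 binary matrix with a 1 in the carbon
row and a 1 in the nitrogen row of each condition column, and only the
non-negative `Signatures` matrix is learned: uniform random
initialization in (0, 1), multiplicative update
`W <- W * (V H') / (W H H' + eps)` with `eps = 1e-9`, 20 iterations by
default (the fit converges in fewer than 10; planted-factor recovery
benchmarks in the tests run longer to push the reconstruction error
below 1% of the data norm). The Frobenius error is recorded every
iteration and is non-increasing -- a property of the multiplicative
update that the implementation asserts. Fixing the coefficients gives
each source equal weight and prevents over-fitting driven by the
sparsity of the data. A gene joins a source's signature when its raw
signature value exceeds 0.4 (no column rescaling before the cutoff).
Membership is stable across random initializations (Jaccard above 0.9
in practice).

## Profile analyses

* `profile_similarity()`: pairwise Pearson over jointly finite
  conditions; pairs sharing fewer than 10 conditions (of ~21 scored)
  are undefined because shorter overlaps make correlations unstable.
* `precision_recall()`: unordered gene pairs ranked by similarity (ties
  broken lexicographically for determinism) against a co-annotation
  standard built from term-to-gene files; the background is the
  co-annotation rate among evaluable pairs and precision at full recall
  equals it exactly.
* `cluster_conditions()`: the 500 highest-variance genes, agglomerative
  clustering of both dimensions on correlation distance (average
  linkage by default, switchable).
* `hypergeometric_overlap()` / `term_enrichment()`: upper-tail
  hypergeometric set overlap, Bonferroni over the number of terms.
* `gene_set_sign_test()`: per-condition medians over a gene set, exact
  binomial tail at probability 1/2 for the hypothesized sign pattern
  (14 matches of 14 conditions gives p = 0.5^14, about 6.1e-5).
* `cross_profile_similarity()`: inner products between condition
  profiles and external (e.g. genetic-interaction query) profiles over
  the shared gene universe after zeroing missing values and alternating
  row/column Euclidean normalization for 10 passes. For a rectangular
  matrix both row and column norms cannot simultaneously be 1 (the
  squared Frobenius norm would have to equal both dimension counts);
  the passes converge to exactly-unit rows and all-equal column norms,
  a global scale that cannot change similarity rankings. The top decile
  of queries per condition is returned for enrichment.
* `liquid_adjusted_score()`: liquid-assay rates as maximum optical
  density divided by time to saturation, where saturation is the first
  time the OD reaches 95% of its maximum (the saturation instant is
  otherwise undefined on noisy series); mutant/wild-type ratios are
  renormalized by the same ratio in glucose:ammonium so 1 means no
  condition-specific effect.

# The synthetic-data generator

`synthetic_truth()` + `simulate_experiment()` generate complete screens
with known ground truth. Expected colony rate is a product:

```
rate = base_rate x carbon_mult x nitrogen_mult x interaction_mult
            x strain_fitness x ge_effect
```

with a smooth additive low-order polynomial bias surface per plate on
the rate scale, linear area growth from the pin area, multiplicative
log-normal observation noise per scan, and colonies dropped entirely
with a small probability. Defaults are the screen design itself: 16
plates of 16 x 24, 4,772 mutants, 701 wild-type positions, six
glucose:ammonium replicate sets, scans at 0/5/10/24 h (48 h for
glycerol).

Parameter defaults, chosen once:

* `base_rate = 0.02` px/s: a colony grows by ~1,700 px over 24 h from a
  50 px pin, a realistic plate-scanner scale.
* Carbon multipliers 1 / 0.9 / 0.35 / 0.15 (glucose, galactose, ribose,
  glycerol) and nitrogen multipliers from 1 (ammonium) down to 0.55
  (urea) reproduce the qualitative ordering seen in wild-type growth:
  sugars far ahead of glycerol, ammonium/glutamine preferred, urea
  poorest.
* 15 of the 18 non-reference interaction cells deviate from 1 (e.g.
  ribose:glutamate 1.4, reflecting a poor carbon source rescued by a
  nitrogen source that doubles as a carbon skeleton), and exactly 3 are
  left at 1, so the generator's truth mirrors a grid in which most but
  not all condition pairs interact.
* Mutant fitness is a mixture: a quasi-neutral majority (log-normal,
  sdlog 0.03) and a 25% deleterious class log-uniform on (0.3, 0.95).
  Deletion-collection fitness distributions have exactly this shape,
  and the broad slow tail is load-bearing: it populates the low-rate
  end of the LOWESS ratio fit, without which an isolated slow colony
  would interpolate its own ratio and normalize its phenotype away.
* Planted gene-environment effects: 200 slow (x0.5) and 40 fast (x1.5)
  strain-condition pairs outside glucose:ammonium and glycerol.
* `noise_sd = 0.05` (5% multiplicative area noise per scan),
  `missing_prob = 0.02`, spatial amplitude 5% of the condition's
  wild-type rate.

What the generator does *not* emulate: colony-colony competition,
pinning artifacts, image segmentation errors, batch effects between
condition runs, and biologically structured sensitivity profiles (each
planted effect is an independent strain-condition pair, so e.g.
source-wide sensitivity sets are much smaller than in real data).
Passing tests demonstrate that the pipeline recovers what this
generative model plants at realistic noise; they cannot certify
behavior under artifacts the model omits.

# Numerical and design notes

* **Normalization formula.** The reference and condition normalization
  are implemented as multiplication by the LOWESS-smoothed target/plate
  ratio regressed on the plate's own rate -- the MA-style reading under
  which identical plates are a fixed point.
* **BH threshold convention.** Thresholds delimit the rejection region
  (least extreme rejected z), so thresholds plus z-scores reproduce the
  BH set exactly and thresholds at FDR 10% are at least as extreme as
  at 20%.
* **Calibration of the null FDR.** The wild-type replicates are an
  exchangeable null for mutants only insofar as mutants behave like
  wild-type colonies under the null. Three departures, all measured in
  this package's tests: (i) strains arrayed at two positions are
  averaged and become conservative; (ii) the plate SD estimated from
  the plate's own residuals self-normalizes extremes, noticeably on
  sub-384-position plates; (iii) with a realistic fitness spread the
  rate-dependent normalization leaves atypical-fitness strains noisier
  than the wild-type null admits, inflating calls -- consistent with
  the very large per-condition hit counts this design produces on real
  data. The calibration benchmark therefore runs at the real 384-format
  plate geometry with a single-position, unit-fitness complement, where
  realized per-family false-discovery proportion averages ~0.13-0.16
  against the nominal 0.20 over 20 seeds.
* **Problem sizes.** Unit and property tests run on 4-plate, 96-format
  arrays with ~200 mutants and condition sub-grids (chosen to keep the
  full suite fast while preserving every structural feature: six
  reference replicates, a dedicated wild-type plate, scattered
  controls); the calibration benchmark uses 384-format plates as noted;
  the acceptance script runs the full 16-plate, 4,772-mutant, 28-
  condition design.
* **Degenerate inputs.** All-missing plates pass through with a
  warning; all-missing normalization inputs return all-missing; an
  all-wild-type noiseless plate (a single distinct rate) falls back to
  a constant-ratio fit; zero combined variance in z is an error, not a
  NaN.

# Known limitations

* The wild-type null models only wild-type variability; mutant-specific
  normalization error is not propagated into the p-values (see
  calibration notes above). Interpret nominal FDR accordingly.
* LOWESS normalization assumes the low-rate region is populated; on
  arrays with few slow strains, strong condition-specific effects can
  be partially absorbed by the smoother.
* The spatial filter targets smooth bias; periodic pinning artifacts at
  single-colony scale are outside its reach.
* Signature decomposition fixes the source-composition matrix; it
  cannot discover sources beyond the ten nutrient rows it is given.
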