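---
title: "Methods: Holocene pollen diversity, uncertainty propagation and land-use response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Holocene pollen diversity, uncertainty propagation and land-use response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pollendiv)
```

This vignette is the package's own account of its science: the models and
their assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, the numerical choices, and the known
limitations. It states no empirical result that the test suite does not
itself compute.

## 1. The estimation problem

A pollen record is a depth-ordered sequence of count samples from one
sediment core, dated indirectly through a handful of chronological
controls. Comparing diversity across hundreds of such records confounds
three nuisance processes with the ecological signal: counting effort
(more grains, more rare types found), chronological uncertainty (each
sample's age is a distribution, not a number), and heterogeneous sampling
designs (dating density, sample density, counting depth). The pipeline
addresses these with, respectively, fixed-count rarefaction, Monte-Carlo
age-model draws, and explicit inclusion criteria — and propagates the
first two *jointly* by building `R` complete resampled datasets and
carrying every analysis through all of them.

## 2. Inclusion criteria and sections

A record (or a contiguous section of one) is kept when, inside the
analysis window of 11,700–100 cal yr BP:

* it has ≥ 3 Holocene chronological controls (a control is "Holocene"
  when its calibrated posterior **median** falls in the window — the
  straddling case is not defined by convention elsewhere, so the median
  rule is this package's choice);
* consecutive controls are ≤ 3,000 yr apart (gaps split a record into
  candidate sections; a section needs ≥ 3 controls of its own);
* it has ≥ 5 samples with ≥ 300 terrestrial pollen grains each
  (after taxonomic harmonization, which merges synonymous names and
  removes spores and aquatics).

When several sections qualify, the one with the most controls wins, ties
broken by longer time span, then by the older section. Rejections carry
one of four reasons (`too-few-controls`, `control-gap`,
`too-few-samples`, `low-count-samples`), and the filter is idempotent on
its own output.

## 3. Chronology: calibration and monotone age draws

Radiocarbon controls are calibrated on a curve grid:
`posterior(cal) ∝ Normal(measured; curve_mean(cal), sqrt(err² + curve_sigma(cal)²))`,
normalized to unit mass. Calendar-kind controls skip the curve. The curve
is chosen by hemisphere (site latitude ≥ 0 → northern curve); no mixed
curve is used.

Full Bayesian sediment-accumulation modelling is out of scope. The
sampler honors the same contract the pipeline consumes — *an individual
draw from the record's age-model distribution* — by:

1. drawing one calendar age per control from its calibrated posterior,
   jointly conditioned on monotonicity in depth (rejection sampling in
   blocks with a 10⁵ cap, falling back to sorting the draw — unbiased
   whenever rejection succeeds, always terminating);
2. interpolating piecewise-linearly to sample depths; ends are
   extrapolated with the adjacent segment's slope but any sample more
   than 3,000 yr (in age) beyond the outermost control is marked
   age-undefined.

With degenerate (near-zero-error) controls the draws collapse to exact
piecewise-linear age models; with wide errors the draw dispersion at a
control depth matches a rejection-sampling oracle (both are asserted in
the test suite).

## 4. The joint resampling engine

Each of the `R` resamples rarefies every sample to exactly 300 grains
(multivariate hypergeometric, i.e. drawing grains without replacement)
and dates every record by its `r`-th age draw. Samples that land outside
the window (or are age-undefined) are dropped; a record falling below 5
in-window samples is excluded *for that resample only* — realized record
counts therefore vary slightly across resamples, exactly the mechanism by
which window-straddling uncertainty enters the analysis.

Seeds: a counter-based splitting rule derives an independent seed for
every (purpose, resample, record, sample) path from one master seed, so
results do not depend on iteration order, and the full pipeline is a pure
function of (config, seed) — the determinism test compares output trees
byte by byte.

`R` defaults to the study-scale 1,000 in `default_pipeline_config()`;
tests and the bundled `test_pipeline_config()` use 8–25, which the median
and interquartile summaries are taken over.

## 5. Diversity metrics

Per rarefied sample: richness `S` = number of types with nonzero counts;
Pielou `J = (−Σ pᵢ ln pᵢ)/ln S`, undefined (`NA`, excluded from models)
for monotypic samples. Per successive sample pair, Bray–Curtis and
Jaccard dissimilarity. Because longer gaps imply more turnover, pairs are
adjusted by an expected-turnover model: an OLS fit of raw dissimilarity
on `log(interval + 1)`, pooled over all pairs of the dataset, one fit per
metric per resample; `adjusted = raw − expected`, so adjusted values are
mean-zero and may be negative. The functional form is this package's
choice (the source analysis's detailed note was unavailable); a smoothing
spline alternative is available via `adjust_turnover(model = "spline")`
and makes little difference on log-spaced intervals. Turnover points are
dated at the pair midpoint.

Heterogeneity (spatial beta diversity) uses multiple-site dissimilarities
of the Baselga family: with `b_ij` types exclusive to site *i* versus
*j*, and pooled shared surplus `a_M = Σ Sᵢ − S_T`, multi-site Jaccard is
`Σ(b_ij + b_ji) / (a_M + Σ(b_ij + b_ji))`; the abundance analogue
replaces exclusive type counts with exclusive abundances and uses the
Sorensen-type doubled shared term. Both reduce exactly to the pairwise
index at two sites. Within each region and 500-yr bin (edges anchored at
100 cal yr BP, a terminal 11,600–11,700 stub), one sample per record
(nearest the bin center, so dense records do not dominate) enters; bins
are repeatedly subsampled without replacement to the minimum record count
across bins (`B = 100` repeats, averaged) so differing record counts do
not masquerade as differing heterogeneity. Regions below 20 records are
skipped. The one-sample-per-record and without-replacement choices are
interpretations (the source is silent); both are logged here and
configurable. Note that these indices are *not* monotone under replacing
a record by a duplicate of another (removing a generalist can raise
them); the suite asserts bounds, symmetry, pairwise reduction and
equality with an independent oracle instead.

## 6. Regional trend models

Diversity is standardized within region (z-scores, denominator `n − 1`;
the inverse transform is exact and applied to predictions). The model,
fit with mgcv — the same engine class the source analysis used — is

```
value_st ~ region + s(age, by = region, bs = "tp", k = 50) + s(record, bs = "re")
```

with REML (or fast REML with discretization for ≥ 4,000 rows) selecting
the smoothing and ridge penalties. `k = 50` bounds each region smooth's
wiggliness; requesting `k` above the unique-age support is an error
rather than a silent shrink. The Gaussian family is the default; `scat`
(scaled-t) handles heavy-tailed conditional distributions, and
`family = "auto"` selects it when the Gaussian fit's residual excess
kurtosis exceeds 1 (a package convention; the source's criterion is
unstated). The penalty order is exposed (`spline_m`): order *p* leaves
degree-`< p` polynomials unpenalized, which is also how the suite
verifies exactness on noiseless polynomial truths.

Model comparison: AIC defined as `2·edf − 2·loglik` (edf = total
effective degrees of freedom), and a drop of ≥ 2 units relative to a
pooled single-smooth model reads as evidence for region-structured
trends. Smooth p-values are reported (Wald-type, edf-adjusted) but gate
nothing.

Per-resample prediction curves (random intercepts excluded,
back-transformed) are summarized pointwise by median and quartiles
(linear-interpolation percentile convention).

## 7. Land-use response

Each region's ALCC series is the unweighted mean over its grid cells'
annual land-use fractions, 8,000–100 cal yr BP. Points are matched to the
series at the rounded year, predictor `sqrt(ALCC)`. The model is
`value ~ sqrt_alcc + s(record, bs = "re")` (REML); turnover, evenness and
heterogeneity are standardized first and back-transformed after.
Residual lag-1 autocorrelation is pooled within records (each record in
chronological order); if `|acf₁| > 1.96/√N` the model is refit with AR(1)
working residuals at `rho = acf₁` (mgcv's `rho`/`AR.start` machinery).
Heterogeneity has one value per bin and no record structure, so it uses
ordinary regression with a Prais–Winsten AR(1) refit under the same
trigger rule — a package decision where the source formula's random
effect has no analogue at bin level.

## 8. The synthetic world

The generator emulates the statistical structure the analysis assumes,
with known truth:

* **Composition.** Each region has a geometric rank-abundance profile
  over ~56 core taxa (baseline dominance 8: about a 3.5-order abundance
  range) plus a disturbance pool. Smooth background drift (one sinusoid
  per region, period 9–14 kyr, random taxon loadings, amplitude 1)
  stands in for climate-driven turnover.
* **Causal land use.** Regional ALCC is a logistic ramp
  `plateau/(1 + exp(−rate (onset − t)))` (defaults: onsets 6,000/4,000/
  2,500 BP, plateaus 0.5/0.4/0.3). Signed per-region effects enter
  generatively: the evenness effect scales the dominance exponent; a
  positive richness effect mixes in disturbance taxa while a negative one
  steepens the core tail; the turnover effect adds drift along a second
  loading vector at a velocity proportional to ALCC (cumulative ALCC in
  the log-abundances). Each metric thus has its own knob, though the
  knobs are not perfectly orthogonal (adding rare disturbance taxa also
  nudges evenness) — matching real communities more than an orthogonal
  design would.
* **Records.** 5–120 samples (default 20–50), terrestrial grain totals
  uniform on [300, 5,000], multinomial counts around the composition at
  the sample's true age (Dirichlet-overdispersed at concentration
  `1/noise_sd²`; default `noise_sd = 0.05`), record intercepts
  `N(0, 0.15)` on the log-dominance scale, and depositional environments
  (6 labels) shifting intercepts only — by design, so the sensitivity
  analysis has a true null. A few taxa are always emitted under two raw
  names and spore/aquatic counts are added, so harmonization is exercised
  everywhere.
* **Chronology.** Controls are built by pushing true ages through an
  identity-with-wiggles calibration curve (amplitude 35 yr, period 1,100
  yr — invertible but nontrivial) and adding lab error (uniform 30–90
  yr); control counts and spacing guarantee compliance, and a `defect`
  switch produces records violating exactly one named criterion for
  filter tests.
* **Truth.** Trend functions are defined as the *expected value of each
  metric for a 300-grain sample* at the zero-intercept composition —
  richness in closed form `Σ(1 − (1 − pᵢ)³⁰⁰)`, evenness and turnover by
  a seeded 400-draw Monte-Carlo expectation. (A population plug-in
  definition is tempting but wrong: it sits on a different scale and its
  shape can decorrelate from what a 300-grain sample measures.)

Defaults were calibrated once, before any acceptance criterion was run,
to magnitudes a palynologist would recognize (rarefied richness ~15–45,
evenness ~0.6–0.85, raw Bray–Curtis between successive samples ~0.2) and
frozen. What a green test establishes: the pipeline recovers trends,
effect signs and slopes *under the generator's assumptions* — shared
regional composition up to intercepts, well-behaved chronologies,
causally clean ALCC effects. What it does not: robustness to taphonomic
bias, pollen-productivity differences between taxa, spatially varying
pollen source areas, or age-model pathologies beyond what the monotone
sampler produces.

## 9. Site slopes and sensitivity

Per-record OLS slopes over three fixed 1,849-yr periods (Early Holocene
11,700–9,851, Mid Holocene 6,725–4,876, Common Era 1,949–100 cal yr BP;
CE mapped by `BP = 1950 − CE`): log richness, logit evenness, logit
*raw* turnover (adjusted turnover is unbounded below 0, so the logit
applies to the raw [0, 1] values — a logged interpretation), slope × 1,000
= millennial change on the transformed scale; records need ≥ 5 in-period
points; {0, 1} values are clamped to `[10⁻⁶, 1 − 10⁻⁶]` before the logit.
Slopes use median-over-resamples diversity values (the source is silent
on this; the median convention matches its own sensitivity analysis).

The leave-one-environment-out sensitivity analysis refits trends and
land-use models on the median values with each depositional environment
excluded in turn. Comparisons are made on **per-region mean-centered
curves**: environments shift record intercepts, so excluding one shifts
the regional level by that environment's intercept share — an expected
effect the robustness claim explicitly sets aside, while the claim itself
concerns functional forms.

### A known-red check

One acceptance property — every leave-one-out curve inside the
full-analysis across-resample IQR band at ≥ 95% of grid points — fails at
desk scale and is left failing. The reason is structural, not a defect:
with 60 records in 6 environments an exclusion perturbs ~17% of the
record set, while the IQR band encodes only rarefaction and age-draw
noise (half-width ≈ 0.14 richness units here); record-subset variation is
simply a larger uncertainty source than resampling noise at this `n`. The
full-analysis median-over-resamples curve *does* sit inside the band
(97% of points), and the LOO offsets match the excluded environments'
known intercept shares. At the source study's scale (1,763 records, 82
environments, each exclusion a ~1% perturbation) the property is
attainable; at 60 records it is not, and the generator was not adjusted
after the fact to make it so.

## 10. Numerical conventions

* Ages in cal yr BP (1950 CE = 0), larger = older; depths in cm,
  increasing downcore.
* Calibrated posteriors normalized to unit mass on the curve grid
  (asserted to 10⁻⁹).
* Percentiles: R type-7 (linear interpolation) everywhere.
* Standardization uses the `n − 1` standard deviation; zero-variance
  regions are an error, not a silent pass-through.
* Monotonicity of age draws is enforced exactly (ties allowed — flat
  segments are legal stratigraphy).
* All file formats are plain text: CSV (UTF-8, header, "." decimal) and
  JSON; the ALCC grid is a dense wide CSV; calibration curves use the
  3-column layout of the published curve files so real curves drop in.

## 11. Known limitations

* No pollen-productivity correction, no source-area modelling, no
  rarefaction-extrapolation estimators (Chao/Hill) — deliberately out of
  scope.
* The age sampler is not a full accumulation-rate model; priors on
  sedimentation have no analogue here.
* Multiple-site heterogeneity is computed per resample with the bin
  record-count minimum derived within that resample.
* The AIC specificity of the region/pooled comparison is calibrated on
  simulated series; at very small record counts the region term's edf
  cost can mask weak real structure.
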