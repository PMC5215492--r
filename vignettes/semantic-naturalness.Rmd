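---
title: "Calculated Semantic Naturalness: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calculated Semantic Naturalness: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenview)
```

## The statistic and its assumptions

An image classification service returns, for each image, a list of label
strings ("tree", "road", "residential area", ...). A human curator assigns
every label in the vocabulary to one of exactly three semantic classes —
*natural*, *artificial* or *ambiguous* — once, independently of any
particular image. Calculated Semantic Naturalness for an image with `N`
natural, `A` artificial and `T` total labels is

$$\mathrm{CSN} = \frac{N}{T} - \frac{A}{T} \in [-1, +1].$$

The statistic assumes that:

* the curated assignment is meaningful — broad classes keep this
  uncontroversial, and the scoring functions expose a perturbation route
  (swap entries in the taxonomy and re-run) for sensitivity analysis;
* label *counts* carry the signal. Classifier confidence scores are accepted
  in input files but deliberately ignored: CSN is defined as an unweighted
  count statistic, and a confidence-weighted variant is out of scope. An
  optional minimum-confidence row filter (`min_confidence`, default off)
  exists purely for sensitivity analysis;
* every occurrence of a duplicated label counts. Classifiers typically
  return distinct labels, so this is a tolerated edge case rather than an
  expectation; it keeps CSN a pure function of the label multiset.

Perceived Naturalness (PN) is the arithmetic mean of 1–7 Likert ratings for
an image; raw means, with no per-rater centring — inter-rater disagreement
is summarised as the per-image sample standard deviation and averaged, and
nothing fancier is attempted. The package's central empirical question is
always the Pearson correlation between CSN and PN.

## Degenerate inputs and exactness rules

* An image with zero labels is a scoring **error**, not CSN = 0. Silently
  coercing empty label lists to the scale midpoint would bias corpus
  summaries; the error names the image.
* A label absent from the taxonomy is an error under the default `"strict"`
  policy (a curated registry should be complete). The `"ambiguous"` policy
  routes unknown labels to the ambiguous class with a warning, for
  exploratory runs against an evolving classifier vocabulary.
* The corpus sign partition (how many images score below / at / above zero)
  is decided on the integer counts — an image is "zero" iff `N == A` — never
  by floating-point comparison of `N/T − A/T` with 0.
* Standard deviations use the sample (n−1) denominator throughout and are
  reported as 0 with an explicit `sd_undefined` flag when n = 1.
* Kurtosis is reported on the non-excess (Pearson) convention: a normal
  distribution scores 3, a uniform one 1.8, and no distribution can fall
  below 1. Skewness and kurtosis use population central moments; the tests
  cross-check both against an independent implementation.

## Correlation intervals

`pearson_with_ci()` returns the sample Pearson `r`, a two-sided p-value from
the exact t statistic $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of
freedom, and a confidence interval from the Fisher z-transform:
$z = \operatorname{atanh}(r)$ is treated as normal with standard error
$1/\sqrt{n-3}$, and the interval is mapped back through $\tanh$.
`ci_from_r()` exposes the interval standalone so that *published* (r, n)
pairs can be checked without the underlying data — the acceptance tests do
exactly that, at a tolerance of ±0.002 per bound, which absorbs the rounding
of a correlation printed to four decimals. The normal quantile at the
default `alpha = 0.05` is 1.959964. Perfectly collinear input (|r| = 1) is
rejected explicitly since atanh diverges; p-values are reported at machine
precision but should only ever be *compared* as bounds.

## Geospatial sampling

Sample points are generated on a regular lon/lat grid at `spacing_deg`
(default 0.005 decimal degrees, the conventional city-scale choice) over the
polygon's bounding box, with a uniform random offset in (−spacing/2,
+spacing/2) per axis. Conventions, fixed so tests can be exact:

* grid nodes start at the bounding box's south-west corner; west/south edges
  are inclusive, east/north exclusive (a 0.02° square at 0.005° spacing
  holds exactly 16 nodes);
* offsets are redrawn (up to 100 times) until the jittered point lies inside
  the polygon, preserving both the point count and the approximately even
  density; a boundary cell whose redraws all escape falls back to its (in-
  polygon) grid node;
* point-in-polygon is the even-odd ray-casting rule, so multi-part polygons
  and holes need no orientation bookkeeping. No geometry package in the
  package's dependency footprint provides this, so it is implemented
  directly (and exercised against closed-form rectangle/hole cases).

Distances are great-circle on a sphere of radius 6,371,000 m (haversine).
At city scale the relative error against an ellipsoid is far below one
metre, which is the precision anything downstream reports; the tests verify
agreement with an independent geodesy library on the spherical reference.
Bearings are initial great-circle bearings, degrees clockwise from true
north in [0, 360). A virtual-camera request faces from the matched panorama
towards its sample point, so `heading = bearing(pano → point)` exactly, with
a 90° field of view at 640×640 pixels by default.

Nearest-panorama matching is straight-line nearest (as a nearest-panorama
web service behaves), implemented as a grid-bucket search with exact
haversine refinement so large panorama tables stay fast; exact distance ties
break towards the lexicographically smallest panorama id. The tests compare
every match against a brute-force all-pairs scan. Sample points are *not*
snapped to their panoramas: CSN is attributed to the sample point and the
offset distance is retained as a covariate.

## The quintile-stratified panel subsample

To rate a representative subset, CSN scores are split into five strata at
the empirical 20/40/60/80 percentiles (R's default quantile definition),
with boundary ties assigned to the lower stratum, and a fixed number of
images (default 20) is drawn uniformly without replacement per stratum under
a caller-supplied seed. An understocked stratum is an error naming the
stratum and its size.

## What the synthetic world emulates

`world_config()` / `generate_world()` build a fully offline stand-in for the
street-imagery and classification services. Its defaults are the study
conditions the pipeline is designed around:

| parameter | default | rationale |
|---|---|---|
| polygon | 0.24° × 0.08° rectangle at 55.9° N | ≈133 km², a city-scale area whose 0.005° grid holds exactly 768 nodes |
| street segments | 750 × 1200 m, panoramas every 12 m | calibrated so nearest-panorama offsets average ≈68 m, the scale real street-view networks produce |
| label count / image | round(N(8.17, 3.55²)) clipped to [1, 18] | published corpus moments and support; the only distributional constraints available |
| class mix at naturalness u | p_nat = 0.1 + 0.7u, p_art = 0.8 − 0.7u, p_amb = 0.1 | linear interpolation whose extremes give cleanly separated scores while mid-range images mix classes; tunable, not canonical |
| raters | 15, noise sd 1.15 | panel size and observed inter-rater sd on the 7-point scale |
| rater model | round(clip(1 + 6u + ε, 1, 7)) | a 7-button interface driven by ground truth plus Gaussian noise |
| deprivation | vigintile per 0.01° block, independent of u; 756/768 points linked (exact subset) | embodies the null hypothesis; incomplete reverse-geocoding coverage as a fixed count |
| vocabulary | 60 bundled frequent street-scene labels, 20 per class | synthetic label files always resolve under the bundled taxonomy |

The ground-truth naturalness field is a sum of 12 random signed Gaussian
bumps (width 0.03°), **standardized to zero mean and unit variance over the
polygon** and then shaped as `u = 0.5 + 0.32·tanh(1.5·z)`. Standardization
guarantees every seed realises the same field contrast (without it,
occasional seeds produce a nearly flat field and an uninformative world);
the tanh bound keeps `u` in [0.18, 0.82], so panel latent scores rarely hit
the 1/7 clip boundaries and the realised inter-rater sd stays near the
configured 1.15, while still giving CSN enough signal to track the field.
Label emission is independent across labels given u — the joint distribution
of classes within an image is unknown, so independence-given-u is an
assumption, stated as such.

What the synthetic world does **not** emulate: real label co-occurrence
structure (classifiers return correlated labels), the heavy tail of
panorama offsets caused by sea/parkland voids (the synthetic maximum is
around 400 m, real networks produce ~800 m), classifier failure modes
(missed foreground trees), and any coupling between deprivation and
greenspace. Passing tests therefore demonstrate that the *pipeline* recovers
the relationships built into the generator — a positive CSN–PN association
in the published range and clean nulls where couplings are switched off —
not that CSN would achieve any particular correlation on real imagery.

## Problem sizes in the test suite

Unit tests run on an eighth-size world (0.06° × 0.04°, 90 street segments)
so the default suite stays quick. The acceptance checks use the full-size
defaults: 1,000 random label multisets against a brute-force CSN oracle,
20 seeds of the 100-image end-to-end recovery (asserting corr(CSN, PN) in
[0.45, 0.95]), 10 seeds each for the decoupling and deprivation nulls at
n ≈ 756, and one full 768-point city run whose every reported number is
re-derived from the paired table the report carries. Monte-Carlo moment
checks use 10,000 images (label counts within 0.1 / 0.15 of the configured
mean / sd, the slack covering clipping bias) and 100 images for the rater-sd
calibration (±0.15, covering clipping attenuation).

## Known limitations

* Reproducing a *specific* published point set or label matrix requires the
  original deposited tables; re-generation cannot recover them (the study
  polygon and the classifier's label stream are not re-derivable). The
  acceptance test that consumes those tables fails until they are supplied.
* The deprivation lookup is a deterministic input contract
  (point → vigintile); live reverse geocoding, and the choice of deprivation
  domain behind the vigintile, are outside the package.
* Straight-line nearest matching ignores street topology; a panorama across
  a river may be "nearest". This mirrors the behaviour of the real
  nearest-panorama service it stands in for.
* CSN treats every label equally within a class; no attempt is made to
  weight by prominence, area or confidence, and the package deliberately
  performs no regression modelling or spatial autocorrelation correction —
  its correlations are the simple bivariate ones.
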