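# greenview

Semantic naturalness scoring of street-level imagery.

Exposure to natural environments — even to images of them — has measurable
restorative effects, and an image's restorative value tracks its **Perceived
Naturalness (PN)**: the mean of human ratings on a 7-point Likert scale from
1 (not natural) to 7 (natural). Collecting panel ratings does not scale to
city-sized studies. `greenview` implements a scalable proxy: run each image
through an off-the-shelf image classifier, curate the classifier's label
vocabulary into three semantic classes (*natural*, *artificial*,
*ambiguous*), and score each image by its **Calculated Semantic Naturalness**

```
CSN = N/T − A/T
```

where, for one image, `N` is the number of natural labels, `A` the number of
artificial labels and `T` the total number of labels. CSN lives on
[−1, +1]: −1 when every label names something artificial, +1 when every
label names something natural; ambiguous labels count only in `T` and pull
the score towards 0.

The package covers the full pipeline around that statistic, for researchers
in environmental health and urban greenspace perception:

- **taxonomy** — load/validate the human-curated label → class registry
  (`load_taxonomy()`, `classify_label()`, `count_by_class()`);
- **scoring** — per-image CSN and corpus summaries (`csn()`,
  `score_images()`, `summarize_scores()`);
- **geosampling** — pseudo-random grid sampling of a study polygon, offline
  nearest-panorama matching and virtual-camera requests
  (`generate_sample_points()`, `match_panoramas()`,
  `build_image_request()`);
- **panel** — Likert aggregation into PN, distributional diagnostics and the
  quintile-stratified image subsample (`aggregate_pn()`,
  `panel_distribution()`, `stratified_quintile_subsample()`);
- **linkage** — joining scored points to small-area deprivation vigintiles
  (`join_deprivation()`);
- **analysis** — Pearson correlations with Fisher-z confidence intervals and
  end-to-end experiment runners (`pearson_with_ci()`, `ci_from_r()`,
  `run_experiment1()`, `run_experiment2()`);
- **synthetic world** — a fully offline generator (street network,
  ground-truth naturalness field, mock classifier, mock panel, mock
  deprivation lookup) that emulates the statistical structure of a real
  city study, so every stage is testable without any imagery or
  classification service (`world_config()`, `generate_world()`,
  `simulate_experiment2()`).

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods for results, `autoplot()` / `plot_map()` for figures.

## Worked example

Score one label list against the bundled street-scene taxonomy:

```r
library(greenview)
csn(c("tree", "grass", "road"), default_taxonomy())
#> # A tibble: 1 × 5
#>     csn n_natural n_artificial n_ambiguous n_total
#>   <dbl>     <int>        <int>       <int>   <int>
#> 1 0.333         2            1           0       3
```

Two natural labels and one artificial out of three give
CSN = 2/3 − 1/3 = 0.333.

Check a published correlation's confidence interval from just `r` and `n`
via the Fisher z-transform:

```r
ci_from_r(0.7644, 307)
#>    ci_low   ci_high
#> 0.7135129 0.8072650
```

Run a complete synthetic city study — 768 sample points over a ~133 km²
area, nearest-panorama matching, mock classification, a 15-rater panel on a
100-image quintile-stratified subsample, and deprivation linkage of 756 of
the 768 points:

```r
rep <- simulate_experiment2(world_config(seed = 5))
rep
#> <gv_report: sampled-city pipeline>
#>   images: 768  (CSN < 0: 337, = 0: 64, > 0: 367)
#>   labels/image: mean 8.07 sd 3.41 range [1, 18]
#>   pn correlation: Pearson r = 0.6643, 95% CI [0.5381, 0.7614], p = 4.886e-14, n = 100
#>   deprivation correlation: Pearson r = -0.0718, 95% CI [-0.1424, -0.0005], p = 0.04842, n = 756
#>   pano offsets: mean 67 m, sd 63, max 370

tidy(rep)
#> # A tibble: 2 × 6
#>   term            estimate conf.low conf.high  p.value     n
#>   <chr>              <dbl>    <dbl>     <dbl>    <dbl> <int>
#> 1 csn_pn            0.664     0.538  0.761    4.89e-14   100
#> 2 csn_deprivation  -0.0718   -0.142 -0.000506 4.84e- 2   756
```

The CSN–PN correlation is strongly positive (the classifier-derived score
recovers what the panel perceives), while the CSN–deprivation correlation
hovers near zero — the synthetic world couples label emissions to its
naturalness field but leaves deprivation spatially independent of it, so
this is the expected null. `autoplot(rep)` draws the PN-vs-CSN scatter and
`plot_map()` maps points, panorama offsets and deprivation halos.

## Documentation

The methods vignette (`vignettes/semantic-naturalness.Rmd`) describes the
model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic world does and does not emulate, and known
limitations.
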