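# tillerview

Top-view image phenotyping of spaced perennial-ryegrass (*Lolium
perenne*) plants: ensemble segmentation of field images and extraction of
image-based growth traits.

Breeding nurseries evaluate hundreds of genotypes as individual spaced
plants that are cut repeatedly through the season. Photographing each
plant from above — directly after a cut (base area, *W0*) and one week
later (outgrowth area, *W1*) — turns regrowth and lateral expansion into
measurable, objective traits. The hard part is segmentation: outdoor
light, soil colour, algae, weeds and post-cut yellow-brown plant sectors
defeat any single rule.

`tillerview` implements the robust approach for this setting:

* **Eight complementary segmentation operators** — HSV colour windows
  (C1: H ∈ [35, 100], S ∈ [50, 255], V ∈ [40, 226] on a 0–255 scale),
  blue/green ratio (C2: B/G < 0.625), an FFT raised-cosine low-pass
  (T1), a 100 × 100 sliding-window Shannon-entropy operator (T2,
  threshold 4.7 bits), and four Prewitt-based edge operators (E1–E4),
  each followed by one shared clean-up: dilate, fill holes, erode,
  keep the largest connected component.
* **Majority-vote fusion** — a pixel is plant when at least **4 of the
  8** cleaned masks contain it; the largest component of that composite
  is the detected plant (equivalent to stacking the masks at 1/8 of
  intensity 255 each and thresholding at 128).
* **Agreement evaluation** — precision `P`, recall `R` and
  `F = 2PR/(P + R)` between any two masks; the 28-pair agreement matrix
  over the eight methods; per-method scores against the composite.
* **Growth traits** — pixel areas to cm², daily thermal time
  `max(0, (tmin + tmax)/2)` above a 0 °C base, regrowth
  `W1 − W0` (per °C·day), first-year lateral expansion as the OLS slope
  of base area vs cumulative thermal time (≥ 3 valid observations per
  plant), genotype means over clonal replicates, and Pearson
  correlations against manual measurements.
* **A seeded synthetic-scene generator** — field-like tufts on noisy
  brown soil with algae, weeds, brown sectors, illumination gain and
  white-balance shifts, plus exact ground-truth masks and programmed
  growth series, so the whole pipeline is testable end to end.

## Worked example

```r
library(tillerview)

# A synthetic field scene with known ground truth
scene <- generate_scene(scene_params(seed = 42))
scene
#> <synthetic_scene 512 x 512, true area 53.0 cm2, seed 42>

cfg <- seg_config(pixels_per_cm = 28)   # thresholds of the field protocol
masks <- segment_all(scene$image, cfg)  # the 8 cleaned method masks
det <- validate_detection(composite_vote(masks, cfg$min_votes),
                          truth = scene$truth)
det
#> <plant_detection 'image': ok, area 44843 px>

precision_recall_f(det$composite, scene$truth)
#> # A tibble: 1 × 3
#>   precision recall f_value
#>       <dbl>  <dbl>   <dbl>
#> 1     0.926  0.999   0.961

pixels_to_area(det$area_px, 28)
#> [1] 57.1977
```

The composite recovers 99.9 % of the true plant (recall) with an F value
of 0.96; the measured area (57.2 cm²) slightly exceeds the 53.0 cm²
truth because edge-based votes add a thin band around every leaf
boundary — see the methods vignette.

How strongly do the eight methods agree with one another on this image?

```r
am <- pairwise_f_matrix(list(masks))
glance(am)
#> # A tibble: 1 × 5
#>   n_images n_pairs min_f mean_f max_f
#>      <int>   <int> <dbl>  <dbl> <dbl>
#> 1        1      28 0.332  0.788 0.993

dplyr::arrange(tidy(am), dplyr::desc(mean_f))
#> # A tibble: 28 × 4
#>   method_a method_b mean_f n_images
#>   <chr>    <chr>     <dbl>    <int>
#> 1 E1       E3        0.993        1
#> 2 C1       C2        0.990        1
#> 3 E2       T1        0.965        1
#> ...
```

All 28 unordered pairs are scored; the two Prewitt edge operators agree
most, followed by the two colour operators — the texture operators are
the intentional outliers that pay off under difficult light.
`autoplot(am)` draws the matrix as a heatmap, `autoplot(det)` the vote
image with the red outline overlay.

Thermal time from a daily temperature table:

```r
temps <- generate_temperature_series(140, seed = 1)
thermal_time(temps)   # degree-days over the 140-day window
#> [1] 2367.658
```

For batches, `parse_manifest()` reads a CSV (or a directory of files
named `<genotype>_<rep>_<Y#C#>_<W#>.png`), `run_batch()` produces
per-image detections, overlays and a per-timepoint success summary, and
`as_observations()` feeds the detections into `regrowth()`,
`lateral_expansion()`, `genotype_means()` and `correlation_table()`. A
thin command-line driver with subcommands `segment`, `batch`,
`evaluate`, `traits` and `synth` is installed under `inst/cli/`.

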