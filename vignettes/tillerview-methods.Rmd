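---
title: "Ensemble segmentation and growth traits for top-view ryegrass images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble segmentation and growth traits for top-view ryegrass images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Spaced perennial-ryegrass (*Lolium perenne*) plants in field nurseries are
photographed from above, once directly after each cut (the *base area*,
week W0) and once a week later (the *outgrowth area*, W1). The projected
ground cover of the plant, extracted from these images, yields three
growth traits:

* **regrowth** — outgrowth area minus base area for the same cut, in cm²,
  optionally divided by the thermal time of the regrowth week
  (cm² °C⁻¹ day⁻¹);
* **base area** itself, a proxy for tiller number;
* **first-year lateral expansion** — the ordinary-least-squares slope of
  the base area against cumulative thermal time over the first season's
  cuts (cm² °C⁻¹ day⁻¹), estimated only for plants with at least three
  valid observations.

Outdoor imagery makes the segmentation step hard: illumination and white
balance drift through the day and season, soils change colour with
moisture, algae and weeds are green like the plant, and freshly cut plants
carry yellow-brown sectors. No single segmentation rule is reliable under
all of these conditions, so the pipeline runs **eight complementary
operators** and fuses their masks by a **majority vote**.

## The eight operators and the composite mask

All operators produce a binary *raw mask* which is then *cleaned* by one
shared sequence: dilation with a disc structuring element, hole filling
(background regions not connected to the image border), erosion with the
same disc, and selection of the largest 8-connected component.

| Name | Domain   | Input      | Rule (raw mask) |
|------|----------|------------|------------------|
| C1   | colour   | HSV        | H ∈ [35, 100], S ∈ [50, 255], V ∈ [40, 226] (0–255 scale, inclusive) |
| C2   | colour   | RGB        | blue/green ratio < 0.625 |
| T1   | frequency| S channel  | FFT → radial raised-cosine low-pass (half amplitude at radius 25, DC gain 1) → inverse FFT → intensity > 110 |
| T2   | texture  | S channel  | Shannon entropy (256-bin histogram, 100 × 100 window) > 4.7 bits |
| E1   | edge     | S channel  | 5 × 5 Gaussian (σ = 1) → Prewitt L2 gradient magnitude > 29 |
| E2   | edge     | S channel  | Gaussian → 3 × 3 high-boost kernel (centre 15, rest 1) / 13, clipped to [0, 255], ≥ 230 |
| E3   | edge     | S channel  | Gaussian → Prewitt L1 gradient > 27 |
| E4   | edge     | S channel  | Gaussian → Prewitt L2 > 15 → morphological thinning → ≥ 1 |

A pixel belongs to the **composite mask** when at least four of the eight
cleaned masks contain it; of the resulting foreground only the largest
connected component is kept as the plant. Integer vote counting is used
internally. It is equivalent to the historical formulation in which every
mask contributes 1/8 of a maximum intensity of 255 and the stacked image
is thresholded at 128: four votes give exactly 127.5, whose 8-bit half-up
rounding is 128; counting avoids that rounding knife-edge altogether.

The composite area in pixels divided by the squared image scale
(pixels per cm) gives the area in cm².

### Design choices inside the operators

Several of the original operators come from a proprietary imaging
toolbox, so their exact semantics are not recoverable; this package fixes
concrete, documented interpretations and isolates each behind its own
function:

* **E1 vs E3.** Both are Prewitt-based. They are realised with the L2
  norm (gradient magnitude) and the L1 norm respectively — the minimal
  faithful differentiation for two operators that agree strongly but not
  perfectly in practice.
* **E4** ("refine edges") is threshold-then-thin: the gradient band is
  reduced to 1-px-wide curves by Zhang–Suen thinning; the clean-up's hole
  filling then recovers the enclosed object.
* **T1's cosine filter** is a radial raised cosine with gain 1 at DC,
  1/2 at the configured radius and 0 from twice that radius outward, on
  the centred spectrum.
* **Entropy (T2)** uses base-2 logarithms over a full 256-bin histogram,
  square window, stride 1 (exact, via an incremental sliding histogram);
  a strided approximation with nearest-neighbour upsampling is available
  behind `t2_stride` for very large frames.
* **Threshold comparisons.** Window bounds are inclusive; scalar
  thresholds are strict (`> x`), except E2 where the response is clipped
  to [0, 255] first, making 255 a mass point, so `>= 230` is used.
* **Hue convention.** Hue is stored on a 0–255 scale (degrees × 255/360,
  rounded half up); achromatic pixels get hue 0. The 1.41°-per-step hue
  quantisation means an HSV round trip can move a saturated channel by up
  to 3 intensity steps — this is inherent to the 8-bit scale, not a
  conversion error.
* **Structuring element.** The disc radius is 5 px at the reference
  scale of 74.36 px/cm and scales proportionally with `pixels_per_cm`
  (minimum 1 px). Dilate–erode with the same element (a closing) removes
  nothing by itself; it is the largest-component step that discards small
  objects, and the closing's role is to bridge the plant into one
  component and to let hole filling work on closed contours.
* **Connectivity.** Foreground components are 8-connected; the
  background during hole filling is 4-connected (the standard
  complementary pair).
* **Failure policy.** One operator failing on one image never aborts a
  batch: the method's mask is recorded empty with a warning, and the
  remaining seven still vote.

## Evaluating masks: precision, recall, F

For a predicted mask against a reference mask, precision `P` is the
fraction of predicted pixels that are truly object, recall `R` the
fraction of object pixels captured, and `F = 2PR/(P + R)` their harmonic
mean. Degenerate cases score 0 (empty prediction, empty reference, or
both); a configuration flag can instead exclude such images from
aggregation, mirroring protocols that drop incorrectly analysed images.
`pairwise_f_matrix()` scores every unordered pair of the eight methods —
28 comparisons per image, F being invariant to which mask is called the
reference — and `methods_vs_reference()` scores each method against a
per-image reference (typically the composite mask of a correctly analysed
image), reporting means and standard errors (sample SD/√n).

## Growth traits on a thermal-time axis

Daily thermal time is `max(0, (tmin + tmax)/2 − T_base)` with
`T_base = 0 °C`; cumulative sums over the season give each cut a position
in °C·day. `regrowth()` pairs W0/W1 observations per plant and cut;
`lateral_expansion()` fits the per-plant OLS slope of base area against
cumulative thermal time, refusing an estimate below three valid
observations; `genotype_means()` averages the clonal replicates
(invalid replicates are dropped, not imputed — the mean of the remaining
replicates is used, and genotypes with no valid replicate are excluded);
`pearson_correlation()` / `correlation_table()` relate image-derived
traits to manual measurements (tiller counts, leaf growth) on genotype
means with the standard two-sided test and pairwise-complete deletion.
No multiple-testing correction is applied across cuts or groups.
Negative regrowth is retained (cut damage and segmentation noise are
real) but reported.

## The synthetic scene generator

The original field archive is not available, so the package ships a
seeded generator of field-like scenes with exact ground truth
(`generate_scene()`), used by the test-suite and the acceptance script.
A scene is:

* **soil** — a base brown (RGB 145, 130, 115 — a dry, greyish brown with
  saturation well below the plant's) under multi-octave multiplicative
  lightness noise, a moisture gradient along a random direction, and
  per-pixel sensor noise;
* **algae patches** on the soil margin — plant-like hue but fine-scale
  texture, exercising the colour/texture complementarity;
* **weeds** — small green blobs away from the plant, removed only by the
  largest-component rule;
* **the plant** — a tuft of tapering, curved strokes radiating from a
  crown disc, with per-leaf hue (inside the green window), saturation,
  value, droop and curvature; an angular wedge of leaves can be
  recoloured yellow-brown (post-cut sectors); a small fraction of leaf
  pixels become near-white specular highlights;
* **illumination last** — a global gain and per-channel white-balance
  multipliers applied after everything else, consuming no randomness, so
  the same seed under a different gain re-renders the identical scene
  under different light.

The ground-truth mask is the rasterised union of the drawn leaves
(including brown sectors); algae and weeds are excluded. All randomness
derives from one seed through independent per-component sub-streams, so
the truth-only rasteriser used by the area solver reproduces the leaf
geometry exactly.

Default geometry: a 512 × 512 frame at 28 px/cm (about 18 cm of soil,
the plant filling a similar fraction of the frame as in a tripod
protocol at 74.36 px/cm), 240 leaves of 3.0 ± 0.5 cm length and
0.5 ± 0.06 cm width from a 2.2 cm crown — a dense, just-cut stubble tuft.
Density matters scientifically: a freshly cut tuft is mostly solid
cover, which is what makes "projected area" a meaningful trait; the
edge operators necessarily add a ~1-px band around every boundary, so
the relative area bias shrinks as plants grow denser and larger.

`generate_growth_series()` programs a whole first season for one plant:
W0 target areas follow `base + slope × gdd (+ noise, floored at a
minimum plant size)`, W1 targets add `regrowth_rate × gdd_week`, the
leaf count grows in proportion to the target area (as tiller number does
with base area), and a bisection solver adjusts leaf length (and, below
scale 1, width as the square root of the scale) until the rendered truth
area matches each target within 5 %. The default cutting schedule places
four cuts at 0, 550, 1150 and 1700 °C·day — roughly six-week intervals
in a temperate season — with one-week regrowth windows of about
100 °C·day. `generate_temperature_series()` produces matching daily
min/max records (seasonal sinusoid, fixed diurnal range, Gaussian noise,
`tmin ≤ tmax` enforced).

### What passing on synthetic scenes does and does not show

The generator emulates the *structure* of the field conditions — green
thin-leaved tufts on brown soil, illumination drift, confusable green
patches, brown sectors — with colour distributions that sit inside the
operator windows the way ryegrass foliage sits inside them in calibrated
field images. Passing the end-to-end suites therefore shows that the
fusion logic, the clean-up, the evaluation machinery and the trait
algebra are correct and robust to the modelled perturbations. It does
not certify field performance: real scenes have shadows, specular soil,
overlapping neighbours, wind blur and white-balance errors beyond the
modelled multipliers, and the printed field success rates cannot be
reproduced without the original archive.

## Numerical choices

* Convolutions use reflect (symmetric) padding; the Gaussian kernel is
  normalised to sum 1, so image means are preserved.
* The FFT low-pass operates on the unshifted spectrum with an
  analytically centred radial transfer function; only the real part of
  the inverse transform is kept.
* Vote counting is integer arithmetic; no 8-bit accumulation is
  involved.
* Component ties in `largest_component()` (equal pixel counts) are
  broken toward the component whose top-left pixel comes first in
  row-major order — deterministic across platforms.
* The area solver stops within 4 % of the target (tested bound 5 %),
  after at most 14 bisection steps on the monotone area-vs-length curve.
* Empty-mask conventions: P, R and F are 0 rather than undefined; an
  empty raw mask short-circuits the clean-up.

## Problem sizes used by the test-suite and acceptance script

Segmentation accuracy is assessed on 50 seeded default scenes;
illumination robustness on one scene re-rendered under gains 0.8/1.0/1.2
and ±5 % white-balance shifts; trait recovery on 50 seeded genotypes
with four W0 scenes each (programmed slopes drawn around
0.059 cm² °C⁻¹ day⁻¹, truncated to [0.03, 0.08]; base areas 16–24 cm²;
per-cut area noise of 10 % of the genotype's mean area) plus one
noise-free W0/W1 series for regrowth. P/R/F identities are checked
against a counting oracle on 1000 random 32 × 32 mask pairs, and the
vote rule by exhaustive enumeration of all 256 membership patterns.
These sizes give stable estimates (the slope study's median relative
error is dominated by the programmed noise, not by simulation error)
while a complete run of suite plus script stays within minutes on a
single core.

## Known limitations

* The composite mask carries a systematic boundary band of roughly one
  pixel around the true object — visible as a few-percent area
  overestimate on synthetic truth. It is nearly constant in relative
  terms across plant sizes, so slopes and correlations are only mildly
  affected; absolute areas inherit it.
* Operators with fixed pixel-scale parameters (the 100-px entropy
  window, the radius-25 low-pass) change character when images are
  rescaled; configurations tuned at one pixels-per-cm are not
  automatically optimal at another. Only the structuring element is
  rescaled automatically.
* The plausibility heuristic (border contact > 25 % of the border,
  cover > 60 % of the frame) is a stand-in for human inspection of
  overlays and will pass a wrong-but-plausible mask.
* Canny-style edge detection, learned segmentation and per-image dynamic
  parameter adaptation are out of scope.
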