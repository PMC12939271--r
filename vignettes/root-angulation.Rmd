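---
title: "Measuring mesiodistal root angulation from panoramic tooth segmentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring mesiodistal root angulation from panoramic tooth segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootangle)
```

## The problem

Orthodontic finishing aims at *root parallelism*: the long axes of adjacent
teeth should be parallel on a panoramic radiograph (orthopantomogram, OPG).
In routine practice this is judged by eye, which is subjective and
observer-dependent. Given a per-tooth semantic segmentation of an OPG — a
33-class label map with one class per permanent tooth in FDI notation plus
background — the mesiodistal angulation of each tooth can instead be
measured automatically and reproducibly. `rootangle` implements that
measurement pipeline together with the agreement statistics needed to
validate it and a synthetic phantom generator that provides label maps with
known ground truth.

## The measurement model

For one tooth the pipeline is:

1. **Instance extraction.** The binary mask of the tooth's class is split
   into 8-connected components and the largest is kept. 8-connectivity is
   chosen because rasterized roots often taper into thin diagonal necks
   that 4-connectivity would sever. Components below `min_pixels`
   (default 50; at the 512 × 1024 working resolution a real tooth covers
   thousands of pixels) are treated as segmentation debris and dropped.

2. **Initial long axis.** With 0-based pixel coordinates $(r, c)$ (origin
   top-left, rows increasing downward) and central moments
   $\mu_{20} = \sum (r-\bar r)^2$, $\mu_{02} = \sum (c-\bar c)^2$,
   $\mu_{11} = \sum (r-\bar r)(c-\bar c)$, the orientation of the major
   principal axis measured from the **vertical image axis** is
   $$\theta = \tfrac{1}{2}\,\mathrm{atan2}\!\left(2\mu_{11},\; \mu_{20}-\mu_{02}\right) \in (-90^\circ, 90^\circ].$$
   $\theta = 0$ for a vertical tooth. The sign convention is purely
   image-based: the axis vector's row component is forced positive
   (pointing down), and $\theta > 0$ when the inferior end of the axis
   tilts toward increasing column index. A single convention for both
   arches (rather than one tied to each tooth's occlusal end) keeps the
   algebra of whole-image transformations simple: an in-plane rotation of
   the radiograph by $\delta$ adds $\delta$ to *every* angle.

3. **Apical exclusion.** The apical root segment frequently exhibits
   curvature and dilaceration, so including it makes the axis estimate
   unstable. Pixels are projected onto the unit vector of the initial
   axis; with extent $E = p_{\max} - p_{\min}$, the apical 22% of the
   extent is removed: maxillary apices point toward the image top and sit
   at minimum projection (retain $p \ge p_{\min} + 0.22\,E$), mandibular
   apices at maximum projection (retain $p \le p_{\max} - 0.22\,E$).
   Pixels exactly on the cutoff are retained, which makes `fraction = 0`
   an exact identity. The fraction is a tunable parameter
   (`apical_fraction`, unitless in $(0, 0.5)$, default 0.22 —
   approximately the apical third of the root once the crown's share of
   the extent is accounted for).

4. **Final angle.** $\theta$ is recomputed on the trimmed region and
   reported in degrees. Because the clinical reference lines — the upper
   film border for the maxilla, the lower border for the mandible — are
   both horizontal, the border-referenced angle is simply the complement
   $90^\circ - |\theta|$; both values are emitted, and the sign is carried
   by the vertical-axis angle. Whether downstream agreement statistics
   should consume signed or unsigned angles is genuinely open (clinical
   reports are often unsigned); both columns are present and the agreement
   functions default to signed values with an unsigned switch.

Isotropic regions ($\mu_{20} = \mu_{02}$, $\mu_{11} = 0$: squares, disks)
have no defined major axis. They are reported as $0^\circ$ with a
degenerate flag rather than as errors, so a batch run over hundreds of
images never aborts on one pathological mask; the same flag marks teeth
whose trimmed region collapses.

By default only the posterior teeth are measured — canines, first and
second premolars, first and second molars in all four quadrants, at most
20 records per image. Incisors suffer the most superimposition and
distortion on OPGs, and third molars are commonly absent or impacted, so
neither is part of the default selection (`tooth_selection` accepts any
subset of the eight tooth types).

## Agreement statistics

Validation of such a measurement method compares it against a manual
reference standard. The package provides the standard toolbox:

* **ICC.** Single-measures intraclass correlation from the two-way ANOVA
  mean squares ($MS_R$ subjects, $MS_C$ raters, $MS_E$ residual):
  ICC(2,1) two-way random, absolute agreement, for interchangeable human
  examiners, and ICC(3,1) two-way mixed, for the comparison of a fixed
  automated method against a reference. 95% confidence intervals use the
  exact F-distribution method (two-sided); the familiar interpretation
  bands (< 0.50 poor, 0.50–0.75 moderate, ≤ 0.90 good, above excellent,
  boundaries belonging to the lower band) are attached. Estimates are
  verified in the test suite against an explicit sum-of-squares oracle at
  10⁻¹⁰ and against an independent implementation's frozen values.

* **Bland–Altman.** Bias = mean difference, limits of agreement
  bias ± 1.96 × sample SD (the $n-1$ denominator is the conventional
  choice). Proportional bias is assessed by OLS of the differences on the
  pair means with a two-sided t-test on the slope — the standard check
  when no specific test is prescribed.

* **Dice coefficient** for segmentation overlap, **grouped MAE/ICC** by
  tooth type, arch and side, and **repeat-acquisition sensitivity**
  summaries (mean, 95th percentile and maximum absolute tooth-wise
  difference, fractions exceeding 1° and 2°) for repeat images of the same
  individuals, which quantify variability due to head positioning and
  projection geometry rather than to the algorithm.

* **Screening accounting** (`exclusion_accounting()`): a bookkeeping check
  that per-reason exclusion counts and the remaining sample size balance;
  `example_screening_counts()` ships a worked example of a retrospective
  archive screen (7751 collected, nine exclusion reasons, 214 remaining).

## The phantom generator

No public dataset of tooth-wise labelled OPGs with certified per-tooth
angles exists, so validation runs on synthetic phantoms
(`default_dentition()` → `generate_phantom()`). Each phantom is a
512 × 1024 label map of 32 stylized teeth: capsule-shaped shafts arranged
along two arch curves, with per-type lengths (90–112 px), widths
(16–24 px) and plausible base mesiodistal tilts (2–7°, apices tipped
distally). Per-tooth ground truth is the base tilt plus Gaussian noise
(default SD 3°, truncated at 2.5 SD — post-treatment angulation scatter of
a few degrees, and truncation keeps interproximal spaces open), and a
tooth receives an apical hook (dilaceration) with probability 0.15, with
deflection uniform in 10–30° and random direction over the apical 20% of
its length. A conservative clearance screen redraws a tooth's noise/hook
when it would touch its mesial neighbour, so generated teeth always occupy
disjoint pixel sets; everything is deterministic given the seed.
`perturb_acquisition()` emulates repeat acquisitions: in-plane rotation
(≤ 10°), horizontal shear and translation jitter, with truth angles
updated analytically and nearest-neighbour resampling to preserve label
integrity.

What the phantoms *do* capture: elongated, tilted, possibly hooked tooth
regions on two arches — exactly the geometry the moments-based axis
estimate and the apical exclusion respond to. What they do *not* capture:
crown morphology, multi-root bifurcations, inter-tooth superimposition,
segmentation errors, and grayscale appearance. Passing the phantom suites
therefore demonstrates correctness of the geometry pipeline under known
truth, not segmentation quality on real radiographs — on real data the
method's accuracy is bounded by the upstream segmenter, which this package
deliberately does not include (it consumes label maps from any source).

## Numerical choices and degenerate inputs

* Label maps are resampled with nearest-neighbour interpolation only;
  interpolating class indices is meaningless, and nearest-neighbour
  provably never introduces a class absent from the input. Grayscale
  images use bilinear interpolation followed by per-image min–max
  normalization (the simplest testable normalization contract); a constant
  image is returned as all zeros with a warning. Inputs already at
  512 × 1024 are not resampled, making preprocessing idempotent.
* Moments are computed as raw sums in double precision over integer pixel
  coordinates; translation invariance of the orientation is exact.
* Tie-break at the exclusion cutoff: inclusive retention (see above).
* The class-index ↔ FDI assignment is not standardized anywhere; the
  canonical table shipped with the package maps 1–8 → 11–18,
  9–16 → 21–28, 17–24 → 31–38, 25–32 → 41–48, and any consistent
  bijection can be supplied as a config file.
* Fragmented class masks (a real artefact of CNN segmenters) follow a
  largest-component rule; the dropped fragment sizes are reported in a
  message.

## Problem sizes used in the validation suite

The test suite exercises the full pipeline at the scale a desk validation
needs: rotation equivariance on ~3000-pixel rectangles over ±30°,
parameter recovery on 50 seeded straight-root phantoms (≥ 95% of teeth
within 1.0°), paired exclusion-vs-no-exclusion comparison on 50 hooked
phantoms, and a 214-phantom batch reproducing the 4280-record count of a
full posterior-selection study. The same batch is recomputed from scratch
by `scripts/acceptance.R`.

## Known limitations

* Angulation is measured in the image plane only; buccolingual inclination
  is invisible on an OPG.
* The border-referenced angle assumes the film borders are truly
  horizontal in the raster; rotated scans should be deskewed upstream.
* Phantom teeth are stylized (see above); absolute agreement numbers
  obtained on phantoms do not transfer to clinical images.
* ICC confidence intervals assume the usual two-way ANOVA normality
  conditions; with 20 records per image and effect sizes of interest near
  ICC 0.9 this is adequate, but heavy-tailed measurement error would call
  for bootstrap intervals, which are not implemented.

## A worked example

```{r example}
set.seed(1)
ph <- generate_phantom(default_dentition(seed = 1))
rec <- measure_image(ph$map)
head(rec[, c("fdi_code", "tooth_type", "angle_deg", "angle_vs_border_deg")])

# recovery against ground truth
m <- merge(rec, ph$truth, by = "fdi_code")
summary(abs(m$angle_deg - m$true_angle_deg))

# a repeat acquisition with 3 degrees of head rotation
rep2 <- perturb_acquisition(ph$map, ph$truth, rotation_deg = 3)
repeat_sensitivity(measure_image(rep2$map), rec)
```
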