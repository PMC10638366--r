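---
title: "Measuring bolivinid pore patterns and calibrating pore density as a nitrate proxy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring bolivinid pore patterns and calibrating pore density as a nitrate proxy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poremorph)
```

## The measurement problem

Several bolivinid foraminifera thrive in oxygen-depleted sediments, where
they respire nitrate through the pores of their calcareous tests. The
density of those pores responds to ambient bottom-water nitrate, which
makes pore patterns on fossil tests a candidate quantitative paleo-proxy.
Turning that idea into numbers requires measuring, on SEM images of
individual specimens, three quantities:

* **pore density** (PD), pores per µm² of test surface;
* **mean pore size** (MPS), the mean individual pore area in µm²;
* **porosity**, the percentage of the measured area occupied by pores.

These are linked per specimen by the identity

$$\mathrm{porosity} = 100 \cdot \mathrm{PD} \cdot \mathrm{MPS},$$

which holds to machine precision for every specimen record this package
produces — but *not* for location means of the three parameters, since a
mean of products is not the product of means. The test suite asserts
both facts.

`poremorph` implements the full measurement chain — specimen detection,
pore segmentation, ontogenetic size normalization, per-pore and
per-specimen morphometrics — together with the statistical toolkit used
to analyse pore patterns and the pore-density → bottom-water-nitrate
transfer function. A synthetic SEM-image generator with exact ground
truth makes every stage testable end to end without external data.

## The synthetic specimen generator

`synthetic_spec()` / `generate_specimen()` render a biserial bolivinid
test: chambers alternate left and right of a midline running down from
the apex (the proloculus, i.e. oldest, end), with chamber areas growing
geometrically (`chamber_growth`, default 1.1) from `first_chamber_area`
(default 3,800 µm²). Fourteen such chambers give a test of roughly
100,000 µm² whose ten oldest chambers cover 50–60 thousand µm², matching
the morphology the measurement protocol assumes. The biserial layout was
chosen because it makes the ontogenetic chamber order unambiguous; the
chamber map partitions the silhouette by assigning each pixel to the
chamber of smallest normalized elliptical distance.

Pores are dark ellipses on the brighter shell. Pore areas are drawn
log-normally from `pore_area_mean` and `pore_area_cv` (a log-normal was
chosen as the standard positive, right-skewed family parameterized by
mean and CV; nothing deeper is claimed for it), eccentricities uniformly
from `pore_eccentricity_range`, and placement is rejection-sampled so
pores never overlap; a geometrically impossible density request fails
with an error naming the limiting chamber. Each pore is rasterized as
*exactly* `round(area / pixel_size^2)` pixels (the pixels of smallest
elliptical radius), so declared areas equal pixel counts times the pixel
area and the porosity identity above is exact by construction.

Imaging artifacts are additive Gaussian intensity noise (`noise_sigma`,
default 0.03 of the intensity range), bright irregular debris particles
on the shell (`debris_count`), and an optional multiplicative cosine
shading toward the lateral test edges emulating surface curvature (off
by default, since the measurement protocol prefers flat specimens). A
debris particle occludes any pore it touches; occluded pores are removed
from the visible ground-truth mask and flagged, so emulated manual
corrections can be scored. All randomness flows from the single `seed`:
identical seed and spec reproduce bit-identical rasters.

`generate_cohort()` draws per-specimen PD and MPS targets from
location presets (`cohort_presets()`): Gulf of Guayaquil
(PD 0.0043 ± 0.0008 pores/µm², MPS 17.13 ± 4.37 µm²), Sea of Okhotsk
(MPS 20.67 ± 3.54 µm²), the Mexican margin, core-top samples, and an
across-location default (PD 0.004, MPS 17.83 µm²). Where a location's PD
is not directly part of the published summaries it is derived from
porosity/(100·MPS) (Okhotsk: 0.1083/20.67 ≈ 0.0052) or taken consistent
with the core-top manual/automated mean of 0.0059 pores/µm². Draws are
truncated at physical bounds (PD 0.0015–0.009 pores/µm², MPS 6–48 µm²,
the observed specimen ranges). Specimen test size varies uniformly
(first chamber 3,500–4,100 µm²), giving cohorts a natural spread of ROI
areas.

What the generator does **not** emulate: real SEM texture (charging,
topographic shading inside pores, detector noise correlation), curved
and broken specimens, partially infilled pores, and the
microspheric/megalospheric dimorphism (the measurement protocol
restricts itself to megalospheric specimens — a sampling note, not a
rendering problem). Passing tests therefore demonstrate that the
operator chain is correct and unbiased on well-behaved flat specimens,
not that it is robust to every pathology of real material.

## Pore segmentation

### Classical operator chain

`segment_pores_classical()` is fully deterministic:

1. **Test detection** (`detect_test_mask()`): global Otsu threshold,
   largest bright 8-connected component, holes filled.
2. **Illumination flattening**: subtraction of a large-kernel
   (σ = 40 px) Gaussian background estimate. The estimate is
   mask-weighted (normalized convolution), because a plain blur lets the
   dark off-test background bleed a bright halo across the silhouette
   edge that widens the shell intensity mode and derails thresholding.
3. **Thresholding** within the test mask. Default `otsu_global`: Otsu on
   the flattened on-test intensities, refined to the midpoint of the two
   class means — for a two-level scene with blurred edges that midpoint
   tracks the half-contrast contour, which recovers pore areas without
   the systematic erosion of the raw Otsu cut. A contrast guard rejects
   the split when the dark class is more than 0.75 times as bright as
   the rest of the test: such a split is only shell texture (suture
   lines, shading) and the specimen is reported poreless. Both the
   threshold and the guard use intensity ratios, so label maps are
   invariant to rescaling the image by a positive constant.
4. **Morphological opening** (3×3), applied only when the smallest
   admissible pore (`min_pore_area`) survives the kernel — below that,
   isolated noise specks are left to the area filter so genuinely small
   pores are not destroyed.
5. Optional **watershed splitting** of touching pores on the distance
   transform, off by default: well-preserved flat specimens have
   separated pore openings and watershed can over-split elongated single
   pores. The merge tolerance is the radius of the smallest admissible
   pore.
6. **Filters**: component area within [`min_pore_area`,
   `max_pore_area`] (defaults 1 and 200 µm²; the smallest mean pore
   sizes on record are near 6 µm², and the floor is kept configurable so
   the known failure mode on very fine-pored species such as
   *B. argentea* is reproducible), and solidity ≥ `solidity_min`
   (default 0.5) to reject ragged blobs. Components are 8-connected —
   standard for blob detection and consistent with anti-aliased ellipse
   rendering.

### Trainable segmenter

`train_pore_model()` / `segment_pores_learned()` provide a trainable
alternative standing behind the same interface: each pixel is described
by a multiscale filter-bank feature vector (Gaussian scale space at
σ = 1, 2, 4, 8, a pore-scale difference-of-Gaussians, local standard
deviation, gradient magnitude) and classified pore/non-pore by a
single-hidden-layer neural network (8 hidden units). Training pixels are
sampled stratified from each image; one epoch is one warm-started
optimization round (30 iterations), and the loss after each epoch is
recorded in the model's training manifest along with image ids, seed and
epochs. Training is deterministic given the seed. The probability map is
thresholded at 0.5 (ties to background) and post-processed by exactly
the same chain as the classical path. A model records the pixel size it
was trained at and warns when applied at another scale.

On held-out synthetic specimens this classifier reaches pixel IoU above
0.95 and exact pore counts; the classical chain is the deterministic
reference it is validated against.

## Ontogenetic size normalization

Pore density increases with each newly built chamber, so raw
whole-test measurements confound ontogeny with environment. The
normalization measures only the oldest chambers whose cumulative area
falls in a fixed window, 50,000–70,000 µm² by default.
`order_chambers()` uses explicit ontogeny ranks when present and
otherwise ranks chambers by centroid distance from the apex.
`select_roi()` accumulates whole chambers from the oldest and returns
the smallest prefix reaching the lower bound; specimens totalling less
than 50,000 µm² are rejected ("specimen too small"), and a prefix that
overshoots 70,000 µm² fails ("window unattainable") rather than
splitting a chamber — the protocol removes whole chambers beyond the
threshold, so partial chambers are never cropped. The "about ten
chambers" this typically covers is descriptive; only the area window
binds, and the window is configurable but enforced strictly.

## Morphometrics

`measure_pores()` includes a pore iff its centroid lies inside the ROI
mask, and an included pore contributes its full pixel area. The
centroid rule keeps expected counts unbiased at ROI boundaries and
makes pore density additive across chamber unions; clipping areas at
the boundary would bias MPS low. Eccentricity comes from the second
central moments. `specimen_params()` computes PD = n/area, MPS = mean
pore area (reported missing, with a warning, for poreless specimens —
zero would corrupt porosity–MPS regressions), porosity = 100 · total
pore area / ROI area. `summarize_location()` reports mean, sample SD
(n − 1 denominator) and SEM = SD/√n per parameter, with SD/SEM missing
for single-specimen locations.

## Statistical toolkit

The analyses use ordinary least squares, Student's/Welch's t,
the Wilcoxon rank-sum and Shapiro–Wilk tests, implemented closed-form in
`ols_fit()`, `t_test()`, `wilcoxon_test()` and `shapiro_wilk()` and
cross-checked in the test suite against independent oracles
(normal-equations solves, exhaustive rank enumeration, permutation
simulation, and base R's reference implementations). Conventions, all
configurable where meaningful:

* two-sided p-values everywhere; no multiple-testing correction is
  applied;
* the regression p comes from the slope t-test with n − 2 df (identical
  to the F-test for simple regression);
* the rank-sum statistic W is the rank sum of the *first* group;
  tie-free samples with combined n ≤ 20 use the exact null distribution
  (dynamic-programming enumeration), larger or tied samples the normal
  approximation with tie and continuity corrections;
* Shapiro–Wilk uses the standard order-statistic coefficient
  approximation with polynomial corrections to the two outermost
  weights, and the standard log-normal normalizing transformations for p
  (exact for n = 3; valid for 3 ≤ n ≤ 5000).

`manual_auto_agreement()` scores automated counts against manual
reference counts: per-specimen relative difference
100·|manual − auto|/manual (the manual count is the denominator because
it is the reference method), the mean and range of those differences,
and a t test comparing mean pore densities. Both the unpaired comparison
of group means and the natural paired variant are reported.

## The nitrate transfer function

`fit_calibration()` fits unweighted OLS of bottom-water nitrate
(µmol/kg) on location-mean pore density over core-top calibration
points. Unweighted, because the published coefficients are reproduced by
an unweighted fit of the location means even though the points carry
1-SEM error bars; the regression direction is nitrate-on-PD, the
direction in which the transfer function is published and applied. In
its published form the function is

$$[\mathrm{NO_3^-}]_\mathrm{BW} = -3896\,(\pm 350)\ \mathrm{PD} + 61\,(\pm 1),$$

available as `published_calibration()` (R² = 0.93 over 9 core-top
points; the coefficient covariance is not published and is taken as
zero, making prediction SEs from that object slightly conservative).

The calibration applies to *B. spissa* and *B. subadvena* only.
*B. subadvena accumeata* and *B. argentea* build far denser, finer pores
that are offset from the regression, so `predict_nitrate()` refuses them
unless explicitly overridden (and then warns): the species guard encodes
a scientific applicability constraint, not a numeric one.
Uncertainty is propagated to first order — coefficient covariance plus
the slope² · SEM(PD)² term — and t-based 95% prediction intervals
including residual variance are available behind a flag for fitted
models.

`covariate_screen()` regresses PD on oxygen, temperature, salinity and
water depth (records for the nine core-top locations ship as
`coretop_env()`) and flags whether nitrate remains the strongest
correlate — the condition for reading pore density as a nitrate rather
than an oxygen or temperature signal.

## Numerical and design notes

* Pixel coordinates are 0-based, row-major, origin top-left in all
  outputs; areas are reported in µm² only, and PD in pores/µm²
  (written `pores/um^2` in CSV headers).
* CSV outputs are UTF-8, comma-separated, '.' decimal, mandatory header;
  all outputs are re-parseable by the package's own readers.
* Rendered intensities are quantized to the declared bit depth (8 or
  16), which is what makes regeneration bit-identical.
* Cohort seeds are derived per specimen from the cohort seed and logged
  in the run manifest; the manifest plus the configuration reproduces a
  run byte-for-byte.
* Degenerate inputs are first-class: blank images, poreless specimens,
  constant covariates, single-specimen locations and under-sized
  specimens all have defined, tested behavior (errors or flagged
  missing values, never silent zeros — except PD = 0 for a genuinely
  poreless specimen, which is a measurement).
* Problem sizes used by the validation suite (50-specimen recovery
  cohorts, 40 + 12 training/held-out split, 500 calibration replicates,
  1,000 normality-test simulations) were chosen as the smallest sizes at
  which the checked properties are statistically meaningful.

## Known limitations

* The classical chain assumes pores are the darkest extended structures
  on the shell; deep topographic shadows on curved or broken specimens
  would be mis-segmented. Use flat, well-preserved specimens.
* Chamber maps come from the generator or from user annotation; the
  package does not segment chamber outlines from raw images.
* The trainable segmenter is a shallow pixel classifier: appropriate for
  the two-level contrast of well-imaged tests, not a general-purpose
  deep segmentation model, and it should be retrained per species and
  imaging setup.
* The species applicability set of the transfer function is a whitelist
  of two; extending it to other bolivinids requires new core-top
  calibration data, not an override flag.
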