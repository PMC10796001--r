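---
title: "From LiDAR point clouds to per-plot growth curves: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From LiDAR point clouds to per-plot growth curves: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldchm)
```

`fieldchm` extracts per-plot crop height and growth dynamics from
repeated UAV LiDAR surveys of field-plot trials. This vignette explains
the model behind each stage, the tunable parameters and their defaults,
the numerical choices, what the synthetic-data generator does and does
not emulate, and the known limitations.

## The processing model

A LiDAR survey of flight *t* is a set of returns $(x, y, z)$ in metres
in a projected frame shared by all flights. The pipeline reduces it to a
2.5D image and works in image space from then on — the key to speed,
since every subsequent operation is a cheap raster filter rather than a
point-cloud neighbourhood query.

**Outlier filter.** A return is kept iff each of its three coordinates
lies inside the central 99.9% probability interval of that coordinate's
empirical distribution, i.e. between the 0.05% and 99.95% empirical
quantiles. We read the conventional "99.9% quantile" cleaning rule as
*two-sided*: stray echoes occur both above the canopy (birds, dust) and
below the ground (multipath), and a symmetric trim is agnostic about
which tail is contaminated. `central_mass` is configurable; 1 disables
the filter.

**Rasterization.** A uniform grid of `pixel_size` (default 0.05 m) is
laid over the x–y bounding box of the *first* (filtered) cloud; every
point falls into exactly one pixel (half-open pixel squares, row 1 =
northernmost) and a pixel's elevation is the arithmetic mean of its
points' z. Using the time-zero bounding box for every flight makes all
rasters of a series pixel-aligned by construction, which is what lets a
single ROI and segmentation transfer across flights. 0.05 m resolves a
1.2 m plot into ~24 columns while keeping a ~80 × 35 m field at a
desk-sized 1600 × 700 pixels.

**Median imputation.** At realistic densities (a few hundred points/m²)
a 0.05 m pixel receives on the order of 0.5 points, so roughly half the
pixels are empty. Each empty pixel takes the median of the defined
values in its 3 × 3 window; the pass repeats until no fillable pixel
remains, so larger voids close from the rim inward (a single pass would
leave any gap wider than the window). The median, unlike the mean, does
not bleed canopy elevations into alley pixels at plot boundaries.
Remaining unfillable pixels (only possible if a whole connected region
of the raster never received points) are reported.

**Quantization and storage.** Elevations are mapped linearly to 16-bit
levels, `level = round((z - z_min)/z_scale)` with
`z_scale = (z_max - z_min)/65535`, and written as 16-bit greyscale PNG
with a JSON sidecar carrying the georeference (`origin_x`, `origin_y`,
`pixel_size`) and the quantization metadata. The representable error is
at most `z_scale/2` per pixel — for a field with 10 m of relief, under
0.1 mm, far below sensor noise. If a raster still contains missing
pixels when written, level 0 is reserved as the missing marker and the
quantizer uses 65534 steps so defined data shifts to 1..65535; the
sidecar records the scheme and the round trip stays bit-exact either
way. The PNG encoder is part of the package (filter-0 scanlines, zlib
via the linked system library); decoding delegates to `png::readPNG`,
which handles 16-bit greyscale exactly.

**ROI.** Interactive region selection does not belong in a reproducible
pipeline, so the ROI is a config object: a counter-clockwise rotation
about the raster centre followed by a pixel crop. Multiples of 90° are
pure index permutations (exact); other angles use bilinear resampling
onto the rotated bounding box. The applied transform is recorded so
pixel→field coordinate mapping (`px_to_xy()`) stays available after
rotation.

**Plot segmentation.** In a grown crop the plots stand ~0.5–1 m above
the alleys, so the column means of the image form a square-wave profile:
plot interiors high, alleys low. After normalizing the profile to [0, 1]
its first difference has a positive peak at every west plot edge and a
negative peak at every east edge. A peak must exceed `min_prominence`
(default 0.1 of the normalized range — well above profile noise, well
below the ~1.0 swing of a true edge) and be at least half the expected
plot pitch away from a stronger same-sign peak. Peaks are reduced to a
strictly alternating start/stop sequence. The same procedure on row
means finds the block bands; block bands × plot intervals give the
rectangles, indexed row-major (block 1 = northernmost, variant 1 =
westernmost). When the expected layout is configured, any disagreement
between detected and expected counts is a hard error naming both — a
miscounted field must never silently produce mislabelled genotypes.

Segmentation runs on the canopy height model of a configurable flight,
by default the **last** one. The first flight cannot be used: it is the
pre-emergence ground survey that defines the DEM, and a bare field has
no plot edges. Because all rasters share the time-zero grid, rectangles
found on one flight index all of them.

**Skew rectification.** Long thin plots are often imaged as
parallelograms (drilling direction not perpendicular to the block axis).
The distortion is modelled as one shear per block: plot boundaries drift
east–west linearly along the plot length. The shear that, when undone,
maximizes the sharpness of the column-mean profile — the sum of squared
first differences, largest when edges are vertical — is found by a
31-point grid search over ±0.15 followed by golden-section refinement
(`stats::optimize`) between the best grid point's neighbours; the
objective is smooth and unimodal near its peak, so this finds the
optimum to ~1e-4. The correction warps each row by linear interpolation
(border-replicated). One coefficient per block (not per plot) matches
the single-pass drilling geometry that causes the skew; per-plot shear
would add 48 fragile 1-parameter fits per block for no modelled benefit.

**Canopy height model.** Neighbouring pixels sample different depths
into the canopy, so the raw raster is "rough". A 3 × 3 maximum filter —
each pixel replaced by its neighbourhood maximum, morphological dilation
— drapes a tight surface over the canopy top (0.15 m footprint at
default resolution; large enough to bridge between-ear gaps, small
enough not to fuse plots across a 0.4 m alley). The CHM is then the
max-filtered flight raster minus the time-zero DEM, clamped below at 0
(negative crop height is physically meaningless and arises only from
noise). The DEM is deliberately **not** max-filtered: dilating the
ground would raise it by the terrain slope over the window and bias all
heights low. The max filter does introduce a small *positive* bias — the
maximum of ~9 noisy pixels sits ~1.5 noise-sd above their mean — which
is visible in validation as a positive mean error of 2–3 cm at 0.03 m
point noise; this is the accuracy cost of tracing the canopy top rather
than the canopy mean.

**Per-plot statistics.** Statistics are computed over each rectangle
inset by `margin_px` (default 2 pixels = 0.10 m) so pixels straddling
the plot/alley boundary — and the max filter's 1-pixel spill — never
enter. Reported per plot and flight: mean, sd, median, min, max and
empirical quantiles (defaults 0.1, 0.25, 0.75, 0.9) with linear
interpolation between order statistics (R type 7; stated because
implementations differ). The *median* is the headline height: a plot is
thousands of plants and the median is insensitive to residual alley
pixels and lodged patches.

## Growth models

With $S(t)$ the median crop height of one plot at day $t$ (days since
the first flight):

* **Relative growth rate** between consecutive flights:
  $RGR(t_1, t_2) = (\ln S(t_2) - \ln S(t_1)) / (t_2 - t_1)$, per day.
  Undefined when either height is 0 (pre-emergence); such intervals are
  reported `NA` rather than dropped, keeping the table rectangular.
* **Logistic growth curve**
  $S(t) = A \,/\, (1 + e^{-Bt - C})$ with $A$ the asymptotic height
  (m), $B$ the growth velocity (1/day), $C$ the onset/offset
  (dimensionless; inflection at $t = -C/B$ where $S = A/2$). Time is
  measured in days from the first flight, and $C$ is reported in that
  convention.

The fit minimizes the residual sum of squares by Levenberg–Marquardt
with box constraints (`minpack.lm::nlsLM`): $A \in (0, 3]$ m (no cereal
exceeds 3 m), $B \in (0, 2]$ /day ($B > 0$ enforces growth, not decay),
$C$ free. Initialization is data-driven — $A_0 = 1.05 \max S$, then
$\ln(S/(A_0 - S))$ is linear in $t$ with slope $B_0$ and intercept
$C_0$, fitted on the interior points ($0.01 < S/A_0 < 0.99$) — plus four
randomly perturbed restarts, keeping the best optimum; with more starts
the best RSS can only improve. A fit is flagged non-converged when every
start fails or the optimum pins $B$ at a bound (e.g. a constant series,
where $B$ and $C$ are unidentifiable); flagged plots stay in the output
with `NA`-masked parameters and never abort the batch. Four time points
is the hard minimum (three parameters plus one residual degree of
freedom); seven, as in a typical campaign, is comfortable.

The curve family is pluggable in principle (a Gompertz curve has the
same signature and an asymmetric inflection); only the logistic is
implemented, as the symmetric sigmoid fits spring cereal height well.

## The synthetic field generator

`generate_field()` is the package's test bed and defines the conditions
under which accuracy is claimed. It emulates:

* a **terrain** of two orthogonal sinusoids (amplitude 0.2 m,
  wavelength 25 m by default) — the simplest smooth stand-in for gentle
  real-field relief, exercising the DEM subtraction;
* the **study layout**: 3 blocks × 48 plots of 1.2 × 9 m, 0.4 m alleys,
  2 m block gaps and margins (a ~80 × 35 m field, matching the printed
  dimensions of the emulated trial);
* **canopy** as a solid top surface: inside a plot, returns sit at
  terrain + $S(t)$ with that plot's logistic parameters. The pipeline
  only ever consumes the upper surface (the max filter discards
  everything below), so simulating a volumetric return profile would add
  parameters without changing any tested behaviour;
* per-plot parameters with **spatially correlated** $A$ (a smooth
  sinusoidal field ± 2% plot-level jitter, mean 0.9 m) and uniform
  $B \in [0.12, 0.18]$/day, $C \in [-7, -5]$ — mid-growth around day
  35–50 of a ~84-day campaign, the shape of a spring-barley season;
* uniform random **point scatter** at 200 points/m² (the density is a
  free parameter — flight parameters determine it in reality) with
  additive Gaussian elevation noise, sd 0.03 m;
* optional **parallelogram skew** of the plot columns (ground stays
  axis-aligned), exercising the rectification stage;
* **determinism**: a design seed fixes every draw bit-exactly.

It does **not** emulate: beam divergence and multiple returns, occlusion
and density variation across scan lines, lodging, weeds in alleys,
within-plot emergence gradients, or georeferencing error between
flights. Passing tests therefore demonstrate the correctness of the
*algorithmic chain* under known geometry and noise — not robustness to
every failure mode of a real survey; the expected-count guard and the
validation RMSD against independent reference heights are the tools for
catching those in practice.

## Numerical choices and degenerate inputs

* Pixel assignment uses half-open intervals; points exactly on the
  east/south bounding-box edge land in the last pixel, so no point is
  dropped and ties are unambiguous.
* A constant raster quantizes to all-zero levels with `z_scale = 1` (a
  zero range cannot define a scale).
* `quantize → dequantize → quantize` is an exact fixed point; only the
  first quantization loses (≤ `z_scale`/2 per pixel).
* Profiles with zero range (constant image), searches on uniform blocks,
  all-missing rasters, all-zero height series and non-increasing time
  vectors are hard errors, not warnings: each indicates an upstream
  failure the user must see.
* The interpolating shear warp replicates border pixels; composing a
  shear with its inverse reproduces the interior to within twice the
  local gradient step (two linear interpolations).
* Per-plot fit failures are data, not exceptions: the batch always
  completes with `converged` flags.

## Problem sizes used in the validation suite

The test-suite fixtures are chosen to exercise every code path at the
smallest size that is not trivial: oracle comparisons (brute-force
group-by rasterization, sliding-window maximum, neighbourhood-median
imputation, sort-and-threshold filtering) run on dozens of random
instances of 10–64 pixel rasters and 10²–10⁴-point clouds; geometry and
growth tests use 2-block × 5-plot fields. The end-to-end accuracy claim
is computed at the full emulated study scale — 144 plots × 7 flights,
~0.56 million points per cloud — once in the test suite and again,
from scratch, by `scripts/acceptance.R`, which reports the RMSD between
per-plot median CHM and generator truth (2.5 cm at the default noise of
0.03 m; the field-validation figure of the emulated study, 5.7 cm, is
the acceptance bound).

## Known limitations

* Plots must form a rectangular grid (blocks of side-by-side plots);
  there is no support for irregular or staggered layouts.
* The rotation angle of the ROI is supplied, not auto-detected.
* One shear per block; per-plot distortion is out of scope.
* Terrain handling is exactly "subtract the time-zero DEM": if the
  first flight is not pre-emergence bare ground, all heights are biased
  by the crop present at time zero.
* The logistic fit assumes monotone growth; senescence-driven height
  loss late in the season will inflate residuals rather than be
  modelled.
* LAS support is read/write of the uncompressed 1.2 / point-format-0
  subset; LAZ and newer point formats are not parsed.
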