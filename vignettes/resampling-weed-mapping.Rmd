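---
title: "Resampling quality and object-based weed mapping: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resampling quality and object-based weed mapping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uavweed)
```

## The question the package models

Site-specific weed management (SSWM) needs a weed map early in the season,
when weeds and crop look alike both spectrally and in shape. Ultra-high
resolution UAV imagery (1-2 cm/pixel, flown at ~30 m) supports accurate
object-based (OBIA) weed mapping, but covering a whole farm at 30 m is slow.
Flying higher is faster but coarser. The alternative studied here: fly low
*once*, then produce the coarser maps by **nearest-neighbour (NN) resampling**
of the 30 m ortho-mosaic to the pixel sizes a 60 m or 100 m flight would have
delivered, and ask two questions of the resampled product:

1. **Spatial quality** — does it still meet the ASPRS 1990 horizontal
   accuracy standard, and are the band statistics untouched?
2. **Agronomic quality** — does the OBIA weed map derived from it prescribe
   the same Treatment/No-Treatment decisions as the map from a real
   higher-altitude image?

Real paired flight imagery is not redistributable, so the package answers
both questions on **synthetic fields with exact ground truth**, plus exact
arithmetic for everything that is pure rule (GSD, ASPRS limits, thresholds).

## Camera model and GSD arithmetic

`camera_model()` carries sensor size, image size and focal length; the
ground sample distance is

\[ \mathrm{GSD} = \frac{\text{altitude} \times \text{pixel pitch}}{\text{focal length}}. \]

Two conventions make the reference pixel sizes reproducible exactly and are
therefore fixed in `pixel_pitch()`: the pitch is taken along the sensor
**width** axis, and it is rounded to **0.1 µm** before use. With the two
presets (a 4032×3024 px, 17.3 mm-wide visible camera at 14 mm, and a
1280×1024 px, 6.66 mm-wide multispectral camera at 9.6 mm) this yields
pitches of 4.3 and 5.2 µm and the four resampling targets:

```{r gsd}
for (cam in c("RGB", "TTC")) for (alt in c(60, 100))
  cat(cam, alt, "m:", gsd(flight_spec(alt, camera_preset(cam))), "cm/px\n")
```

The 30 m mosaic GSDs (1.07 cm visible, 1.6 cm multispectral) are properties
of a bundle-adjusted mosaic, not of single frames, and are therefore
configuration inputs rather than derived values.

## The synthetic field generator

`field_scenario()` + `generate_scene()` build a field in *continuous*
geometry first (so it can be rasterised consistently at any GSD):

* **Crop rows**: parallel lines at `row_orientation` (default 0°) and
  `row_spacing` (default 0.70 m, a typical sunflower row spacing), random
  phase; along each row, 0.25 m planting slots are occupied with probability
  `crop_coverage_along_row` (default 0.85), giving realistic within-row gaps.
* **Weeds**: circular patches placed **on the inter-row midlines** (never on
  a row centreline), clustered around `weed_patch_count` centres, until the
  target field cover (default 8 %) is reached.
* **Sampling frames**: 32 disjoint 1 m² frames, 8 per infestation category.
  Categories are *constructed*, not sampled: each non-zero frame receives
  deliberately sized discs (n discs of radius \(\sqrt{A/(n\pi)}\)) on the
  inter-row midline chords inside the frame, sized to hit per-category
  target covers of 0 / 4.5 / 11.25 / 21 %. These sit comfortably inside the
  category bands used downstream (0, (0, 7.5], (7.5, 17.5], > 17.5 %) so
  that rasterisation jitter cannot flip a category. Category-0 frames are
  kept weed-free by exclusion buffers.
* **Control points**: ≥ 20 saturated (DN 255) square markers of 0.30 m side,
  ≥ 5 m apart — large enough to be detectable at the coarsest pixel size
  (5.42 cm) yet small against the field.
* **Field size**: 24 × 24 m rather than the ~1 ha of a real field. This is a
  deliberate computational scaling; every *per-area* quantity (cover
  percentages, densities, spacings) is unaffected, and 24 m still hosts the
  full 32-frame and 20-marker design.

`render_image()` rasterises the labels at any GSD by the pixel-centre rule
and draws each pixel's DN from a per-class, per-band normal model (defaults:
soil (R,G,B,NIR) = (161,122,87,120), crop (60,110,50,180), weed
(70,120,55,170), σ = 8), quantised and clamped to 8 bits. Weeds are
deliberately close to crop spectrally; soil is far from both, so vegetation
segmentation is easy but crop/weed discrimination must come from *position*,
which is exactly the situation the OBIA procedure addresses. Rendering is
deterministic: the render stream is derived from the scenario seed, the GSD
and the band set, so the 30 m and 60 m renders of one field are *different
noise realisations* of the same ground truth — as two real flights would be.

What the generator does **not** emulate: radiometric physics, shadows, BRDF,
perspective, mosaicking seams, wind-blown plant shapes, or georeferencing
error in the reference itself.

## Nearest-neighbour resampling

`nn_resample()` follows the defining convention of NN degradation: output
dimensions are `floor(dim × factor)` with `factor = source_gsd/target_gsd`;
each output pixel centre is mapped into source grid units and copies the DN
of the source pixel with the nearest centre (exact ties break toward the
upper-left). **No DN is ever modified** — the output values are a
sub-multiset of the input values, which is why NN (and not bilinear/cubic)
is the method of interest for preserving band statistics.

For integer factors 1/k this must coincide with simply taking every k-th
pixel starting at `ceiling(k/2)`; `striding_oracle()` implements that
independently and the test suite asserts bit-exact agreement.

## Spatial quality: ASPRS 1990

`asprs_test()` implements the 1990 ASPRS large-scale map standard: per-axis
RMSE of ≥ 20 check points (fewer is a hard error), compared against the
Class-1 allowable RMSE `class1_limit(denominator) = 0.025 cm × denominator`
(1.25 cm at 1:50); Classes 2 and 3 allow 2× and 3×; the *worse* axis decides.
Check points are measured with `measure_pairs()`: the DN-weighted centroid
of saturated pixels in a window around each marker's true position, in both
images, giving sub-pixel positions without any knowledge of the generator.

## The three-step OBIA classifier

`run_obia()` mirrors a classical row-crop OBIA chain:

1. **Vegetation index**: NDVI when a NIR band exists, otherwise ExG on
   chromatic coordinates (`vegetation_index()`; zero denominators → 0).
2. **Segmentation**: Otsu's threshold on the index histogram, 8-connected
   components, objects below `min_object_area` (4 px) returned to soil. If
   Otsu degenerates (mask fraction < 0.1 % or > 95 %, as on unimodal
   histograms), a fixed fallback (NDVI 0.2 / ExG 0.05) is used with a
   warning.
3. **Crop-row detection and classification** (`detect_crop_rows()`):
   * the row **orientation** maximises the variance of the across-row
     projection profile, swept 0–180° — a coarse 1° pass on a ≤ 40 k pixel
     subsample, then ±1.5° refinement at 0.25° on the full mask;
   * the across-row **density profile** is support-normalised: raw counts
     are divided by the per-bin pixel support of the rotated footprint
     (bins with < 60 % of maximal support dropped), otherwise the
     footprint envelope fakes long-range correlation; a half-bin offset
     avoids exact boundary aliasing at axis-aligned orientations;
   * the **spacing** comes from the profile's autocorrelation, smoothed
     with a (¼, ½, ¼) kernel (pixel-width binning aliases a non-integer
     period into a 2-bin oscillation), taking the smallest-lag local
     maximum comparable to the global peak as the fundamental (the global
     maximum may sit on a harmonic), then least-squares fitting
     `spacing = Σ k·lag_k / Σ k²` through all harmonic peaks with
     parabolic per-peak refinement;
   * detection **fails loudly** ("row detection failed") when the top
     autocorrelation peak is below `max(2 × median |ac|, 0.15)` — e.g. on a
     rowless random mask;
   * the row **phase** is the centroid of the folded across-row coordinate
     near its modal bin (64 bins, ± 0.25 spacing window).

   An object whose centroid is within `row_halfwidth`
   (default `max(0.15 m, 2 px)`) of a detected centreline is **crop**; all
   other vegetation is **weed** (`classify_objects()`).

## Assessment: treatment maps and concordance

`frame_covers()` evaluates per-frame weed cover on the classified raster
(pixel-centre membership). `treatment_decision()` prescribes Treatment when
cover **strictly exceeds** the threshold — strictness makes the 0 %
threshold mean "treat on any weed presence". `threshold_series()` is the
seven-value ladder 0–15 % in 2.5-point steps, and `concordance()` reports,
per threshold, the percentage of frames with identical decisions from two
maps, plus per-category breakdowns and the 2×2 decision tables.
`full_run()` chains everything over two fields × two cameras × two target
altitudes (minus one excluded flight, giving seven resampled images) and
writes byte-reproducible JSON/CSV reports.

## Numerical choices and limitations

* Effective 0.25° orientation resolution bounds the spacing bias from
  mis-rotation to ≪ 1 % at this field size.
* All stochastic steps draw from a single documented per-seed stream;
  `with_seed()` restores the caller's RNG state, so library calls never
  perturb user code.
* The generator's regular geometry makes row detection easier than on real
  fields with curved rows or gaps from planter failures; detection accuracy
  here should be read as an upper bound, and the failure gate — not the
  accuracy — is what protects against silent nonsense.
* 8-bit I/O only (TIFF/PNG + ESRI world file + JSON sidecar); no projection
  handling beyond a local planar frame.

```{r example, eval = FALSE}
# the complete experiment, reproducibly
report <- full_run(default_config(seed = 42), out_dir = "runs/demo")
```
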