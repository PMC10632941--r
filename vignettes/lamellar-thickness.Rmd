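---
title: "Measuring lamellar thickness from annotated polarized-light micrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring lamellar thickness from annotated polarized-light micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamellaR)
```

## The measurement problem

Cortical bone is built from lamellae, thin sheets of mineralized collagen
whose fiber orientation alternates from one sheet to the next.  Under
crossed polarizers (with a quarter-wave compensator) this alternation
renders a stack of lamellae as parallel bright and dark bands.  Band
thickness is a morphometric readout of bone formation and is altered in
collagen disorders such as osteogenesis imperfecta, but measuring dozens of
lamellae by hand with a screen caliper is slow and samples each lamella at
a single point.

lamellaR automates the measurement.  The operator's part is annotation and
counting: draw a yellow rectangle (RGB 255,255,0) around a regular stack of
roughly 16–20 lamellae, recolor one pixel at each top corner of the
rectangle red (RGB 237,28,36) and at each bottom corner green
(RGB 34,177,76), and count the bright and dark bands the program should
find.  Everything downstream is deterministic image processing:

1. **Reorient.** The two red fiducials define the lamellar direction; the
   image is rotated so they share a pixel row, with the red pair kept above
   the green pair to resolve the 180° ambiguity
   (`detect_markers()`, `compute_rotation_angle()`, `rotate_image()`).
2. **Crop.** The image is cut to the area strictly inside the innermost
   yellow rows and columns (`crop_to_roi()`).
3. **Binarize.** The crop is converted to grayscale, contrast-stretched so
   1% of pixel mass saturates at each end, and each pixel is classed
   bright/dark against the mean of the 20 nearest pixels in its own column
   (`to_grayscale()`, `stretch_contrast()`, `binarize_columns()`).  Runs of
   at most 2 wrong-color pixels enclosed within a lamella are recolored
   (`fix_floating_pixels()`).
4. **Measure.** Every column is run-length encoded; each run is one
   lamella crossing that column and its length is a thickness sample
   (`run_length_encode()`).  Columns that start with the minority
   first-pixel color, or that do not contain exactly the expected number of
   bright and dark lamellae, are rejected (`filter_columns()`).  Each
   lamella's thickness is the mean of its run length over retained columns,
   converted to micrometers (`average_thicknesses()`).

`measure_lamellae()` chains the stages and returns a
`lamellar_measurement`; `count_assist()` stops after binarization and
returns the preview used for counting.

```{r}
fx <- generate_fixture(fixture_spec())   # 4 bright + 3 dark bands
m <- measure_lamellae(fx, n_bright = 4, n_dark = 3)
m
```

## Parameters that matter

* `pixel_length_um` (default **0.3185 µm/px**): the physical size of one
  pixel at the acquisition magnification (20x on the reference microscope).
  All reported thicknesses are run lengths multiplied by this calibration;
  it must be re-derived for any other optics.
* `window_size` (default **20 px**): the column-local neighborhood for the
  adaptive threshold, half above and half below the pixel, excluding the
  pixel itself, shifted inward at the image edges so exactly `window_size`
  pixels are always averaged.  The window must exceed the thickest
  *bright* lamella: a bright pixel whose whole window is equally bright
  has intensity exactly equal to the mean, and the strict-inequality rule
  then classes it dark.  In the interior the floating-pixel repair buys
  back `max_floating_run` pixels (so bright bands up to
  `window_size + max_floating_run` survive), but a thick bright band
  touching the top or bottom of the crop has no such margin, because the
  inward-shifted window can sit wholly inside it.  At the default
  calibration 20 px ≈ 6.4 µm, comfortably above normal human lamellar
  thickness (~1–3 µm); for coarser structures raise `window_size`
  (`threshold_params(window_size = 32)` handles bands up to ~30 px).
* `saturation_fraction` (default **0.01**): tail mass clipped at each end
  of the contrast stretch.  The stretch is monotone, so it changes the
  binarization only through 8-bit re-quantization; its real purpose is
  making the stage figures legible.
* `max_floating_run` (default **2 px**): the largest isolated wrong-color
  run, strictly inside a lamella, that is recolored before measurement.
  Edge-touching runs are never repaired — a short run at the frame edge is
  a truncated lamella, not noise inside one.
* `n_bright`, `n_dark`: the operator's counts.  They are a quality
  contract, not a hint: a column disagreeing with them is dropped rather
  than reinterpreted.  Counting stops at a band mostly cut off by the
  bottom of the frame; since that partial band still shows up as a final
  run in most columns, a column with exactly one surplus run is counted
  with its bottom run ignored (`drop_partial_bottom = TRUE`, switchable).

## The synthetic fixtures

The validation data behind the method are confidential clinical
micrographs, so the package carries a generator instead
(`fixture_spec()` / `generate_fixture()`).  It renders alternating
hard-edged bands of stated pixel thicknesses, adds optional Gaussian
intensity noise and disk "lacuna" defects, rotates the whole scene, and
draws the annotation — a 2-px yellow rectangle aligned with the bands,
red pixels on its top corners, green on the bottom — exactly as the
protocol prescribes, returning the image together with ground truth
(band mask, per-band thickness, marker coordinates, expected counts).

Two generator choices are worth knowing:

* The rotated scene is produced **analytically** (each canvas pixel center
  is back-rotated into the band frame and classified there), not by
  resampling an axis-aligned render.  Band edges are therefore geometrically
  exact at any angle; the only resampling in the system is the
  nearest-neighbor rotation *under test*.
* Bands are two-level by default so that exact-recovery oracles exist.
  Real polarized-light lamellae grade sinusoidally into one another, carry
  canaliculi and staining texture, and their "true" thickness is itself
  operator-defined.  Passing the fixture suite therefore demonstrates the
  geometry, bookkeeping and rejection logic of the pipeline — not that the
  adaptive threshold places biological band boundaries where a histologist
  would.

Default generator conditions: a 4 bright + 3 dark stack (the protocol's
worked counting example) of 4–7 px bands (~1.3–2.2 µm, mid-range for human
lamellae), 120 px wide, contrast 200 vs 60, no noise, no rotation.  When
noise is requested the two levels must differ by ≥ 40 so bands remain
separable.  The test suite works at these desk scales throughout
(canvases of roughly 65–160 px per side, angle grid ±5/±10/±15°,
band thicknesses 3–30 px, 5–21 bands per stack).

## Numerical choices and edge cases

* **Rounding** is half-up everywhere an 8-bit value is produced
  (grayscale, stretch, resampling coordinates); base R's round-half-even
  would make results parity-dependent.
* **Grayscale weights** are the standard luma triple 0.2989/0.5870/0.1140.
* **Quantiles** in the stretch are linear-interpolation (type 7) over all
  cropped pixels; on 8-bit data the difference between quantile
  definitions is sub-level.
* **Equality to the window mean is dark** — the bright class is a strict
  inequality.  A constant column therefore binarizes all-dark.
* **Rotation resampling is nearest-neighbor** with black fill.  Bilinear
  would blend the fiducial and rectangle colors away before the crop stage
  could find them; the cost is ±1 px jaggedness on band boundaries, which
  column-averaging absorbs (recovery on rotated fixtures is accurate to
  ~0.05 px).
* **Annotation bleed repair.** Nearest-neighbor rotation can scatter
  single marker-colored pixels just inside the rectangle.  After cropping,
  any remaining marker-colored pixel is replaced by the nearest non-marker
  pixel value in its column, so the crop invariant (no marker colors
  inside the measurement area) holds without shaving extra rows off the
  ROI.
* **Yellow-line localization** calls a row/column "yellow" when ≥ 50% of
  its span across the yellow bounding box matches the code, tolerating
  perforated lines.
* **Ties**: when exactly half the columns start bright, the majority first
  color is bright.  When the two leveling rotations both satisfy (or both
  violate) red-above-green, the smaller-magnitude angle wins.
* **Window boundary behavior**: the "nearest 20" neighborhood excludes the
  center pixel and shifts inward at the edges, keeping the count at
  exactly 20; the alternative 21-pixel centered reading is rejected
  because the quoted count is 20.
* **Percent differences** use the *manual* measurement as denominator —
  it is the reference method.  Mean absolute percent difference is
  denominator-sensitive, so comparisons against numbers computed with the
  automated or midpoint denominator are not like-for-like.
* **Sign test**: zeros are discarded, and the p-value is the exact doubled
  binomial tail `min(1, 2·P(X ≤ k))`, X ~ Bin(n, ½) — no normal
  approximation, since lamellar validation sets are small-to-moderate.
  The accompanying normality check that motivates a nonparametric test is
  delegated to standard implementations (e.g. `nortest::lillie.test`) and
  not re-implemented here.

## Known limitations

* One rectangle per image; multi-ROI images must be split upstream.
* No shear or perspective correction: the rectangle is assumed drawn with
  truly perpendicular tools and the section cut without obliquity.
* Thickness is averaged per lamella; within-lamella variance along its
  length is not reported.
* Bright lamellae thicker than the window (plus repair margin, see above)
  cannot be recovered; raise `window_size` for coarse structures.
* The rejection rules assume the operator's counts are correct.  If every
  column is rejected the error says so rather than guessing — typically
  the counts are off by one or the ROI clips a lamella.
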