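---
title: "Quantifying macrovesicular steatosis with shape descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying macrovesicular steatosis with shape descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steatr)
```

## The measurement model

Macrovesicular steatosis is graded as the fraction of tissue area occupied
by large lipid vacuoles. On an H&E slide a vacuole is an unstained hole:
bright, roughly disc-shaped, 15–100 µm across. The structures that mimic it
— vessel and duct lumina, tears and folds in the section, coverslip glare —
differ in *geometry* (elongated, ragged, or too large) or in *photometry*
(glare clips at the sensor maximum). `steatr` therefore works entirely on
grayscale intensity and region geometry; it never models stain color, which
makes it robust to staining variation but also means it cannot distinguish
a vacuole from any other bright, round, well-sized hole in tissue.

The estimate is the exact identity

```
steatosis_pct = 100 * sum(accepted vacuole area um^2) / tissue area um^2
```

with the denominator taken from the artifact-suppressed tissue mask
*including* vacuole pixels (a fat-laden hepatocyte is still tissue), which
guarantees the estimate stays in [0, 100].

### Assumptions

* Vacuoles are brighter than their surrounding tissue by more than the
  dynamic-threshold offset (true for unstained fat on eosin; not true for
  faint or washed-out stains).
* Tissue is darker than the slide background, so Otsu's threshold on the
  smoothed luminance separates the two classes.
* The image scale (microns per pixel) is known. Physical thresholds (µm²)
  are converted to pixels with it, so an image can be analyzed at any
  pyramid level; plain PNGs carry no scale metadata, and the fallback
  (0.249 µm/px, a common scanner maximum) must be overridden when it does
  not apply (`default_mpp` / `--mpp`).

## The shape descriptors

For a filled region with pixel count $F$, sub-pixel contour polygon (area
$A$, length $L$, points $p_i$), pixel centroid $c$ and $d_i = \lVert p_i - c
\rVert$:

* roundness $= 1 - \sigma_d/\bar d$ — radial dispersion; 1 for a disc,
  falls for elongated or ragged outlines.
* circularity $= A / (\pi \max_i d_i^2)$ — area relative to the
  circumscribed circle; equals the axis ratio $b/a$ for an ellipse, so it
  is the binding constraint for moderately elongated shapes.
* compactness $= L^2 / (4\pi A)$ — the isoperimetric quotient; 1 for a
  disc, $4/\pi$ for a square, grows with boundary raggedness.
* convexity $= A / A_{hull}$ — 1 for convex regions, low for U-shapes and
  torn outlines.
* anisometry $= R_a/R_b$ — axis ratio of the second-moment equivalent
  ellipse of the pixel set (with the $1/12$ per-pixel variance term, so a
  single pixel is isotropic); the natural vessel detector.

Two deliberate geometry choices keep these ratios honest:

* **Mixed geometries are never divided by one another.** Ratio descriptors
  use the contour polygon area $A$; the physical area report uses the pixel
  count $F$. Dividing a polygon perimeter by a pixel-count area biases
  compactness.
* **The contour is lightly smoothed** (4 iterations of a circular
  ¼–½–¼ kernel) before any contour quantity is computed. The marching-squares
  iso-contour of a binary mask staircases, inflating a disc's perimeter by
  ~6% and its compactness by ~12%; after smoothing a radius-50 disc sits
  within 1% of every unit anchor while a 100-px square still matches its
  closed forms ($4/\pi$, $2/\pi$) within 2%. Stronger smoothing would start
  rounding true corners; 4 iterations is the calibrated compromise between
  those two errors.

Degenerate regions (single pixels, collinear contours) take the neutral
guard values 1 for every ratio descriptor. Interior holes are filled before
labeling — a vacuole with debris in its lumen is one region — using the
digital-topology dual pairing (8-connected objects / 4-connected background,
and vice versa). Labels are assigned in scanline order of each region's
topmost-leftmost pixel, so outputs are deterministic. Coordinates are
1-based (row, col) from the top-left, the R convention, applied uniformly.

## Pipeline parameters

All defaults live in `pipeline_config()` and are echoed into every report.
The geometric filter settings are this package's own calibration against the
synthetic generator; the workflow treats them as tunable by design (edit the
config, re-run, inspect the overlay), and none are claimed to be canonical
for a particular scanner or stain batch.

| parameter | default | unit | role |
|---|---|---|---|
| `mean_filter_size` | 5 | px | smoothing before Otsu |
| `speckle_min_area` | 2000 | µm² | debris removal from the tissue mask |
| `edge_crop` | 100 | px | border band excluded (slide-edge artifacts) |
| `bridge_span` | 11 | px | widest tear the closing bridges |
| `void_max_area` | 1.5×10⁶ | µm² | voids above are folds/tears, not tissue |
| `void_min_convexity` | 0.85 | — | ragged voids carved out of tissue |
| `glare_saturation_max` | 0.10 | — | HSV saturation ceiling for glare |
| `glare_value_min` | 0.995 | — | brightness floor for glare (clipping) |
| `dyn_window` | 31 | px | local-mean window of the dynamic threshold |
| `dyn_offset` | 5 | gray | margin above the local mean |
| `vacuole_min/max_area` | 50 / 12000 | µm² | macrovesicular size band |
| shape bounds | see README | — | acceptance gates |

Notes on the less obvious choices:

* **Glare polarity.** Glare is *excluded* from tissue: a pixel is glare when
  it is nearly colorless (saturation < 0.10) *and* at clipped brightness
  (value ≥ 0.995). Vacuoles are also colorless but render just below sensor
  clipping, so the brightness floor — not saturation — separates them. A
  `glare_remove` flag preserves the alternative (keep low-saturation pixels)
  for slides where that reading is wanted.
* **Edge crop is in pixels, not µm.** That makes the crop
  resolution-dependent; it is intentional, matching how the step is used in
  practice (a fixed scanner-edge band). Consequently the tissue should sit
  comfortably inside the cropped field at every level analyzed.
* **Dynamic threshold and large vacuoles.** A vacuole wider than the local
  window responds only along its rim (its center equals its own local mean),
  so the threshold response inside tissue is hole-filled before labeling. A
  3-px opening first removes single-pixel noise responses.
* **Rejection reasons are deterministic.** A rejected region reports the
  *first* failing criterion in the fixed order border, area, roundness,
  circularity, compactness, convexity, anisometry. Under the default bounds
  an elongated lumen usually falls at *circularity* (for an ellipse,
  circularity = axis ratio⁻¹ binds before the anisometry gate); the
  anisometry gate becomes the binding one when the earlier gates are
  relaxed. The reason is diagnostic, not a classification of the artifact.
* **Border regions** (clipped by the image edge) are excluded from
  classification by default; the edge crop makes this nearly moot.

## The synthetic generator

`synthetic_spec()` + `generate_slide()` render the structures the classifier
must separate, with exact masks: eosin-pink tissue (a disc or a
harmonically-perturbed blob, RGB anchor (230, 160, 180), 3% multiplicative
texture noise) on a white background; non-overlapping, slightly irregular
near-white vacuoles (248 ± 2, clipped below the glare floor) placed by
rejection sampling until the vacuole/tissue pixel ratio is within ±0.3
percentage points of the target; elongated bright vessel lumina (axis ratio
3–6); mounting-medium tears (252, just below clipping) carved across the
tissue; fully clipped glare discs (255). Glare is carved out of the usable
tissue before anything else is placed, since it obscures what lies beneath.
Everything derives from one seed; identical specs render bit-identical
output, and cohort child seeds derive deterministically from a master seed.

Defaults are 1024×1024 px at 1 µm/px with the tissue radius at 0.27 of the
image side, so the specimen sits inside the 100-px crop band both at native
scale and after a 2× downsample — the geometry of a well-centered biopsy
scan. Cohort target fractions default to a 1–35% grid, the clinically
relevant right-skewed range.

What the generator does **not** emulate: nuclei and sinusoidal texture,
microvesicular droplets (< 15 µm), stain spectra (the pipeline is
grayscale-driven, so only luminance contrast matters), confluent high-grade
steatosis (vacuole non-overlap is enforced by default; disabling it would
reproduce the known underestimation regime), and scanner noise models.
Passing the recovery suite therefore shows the geometry and thresholding
logic are correct and well-calibrated *for this contrast model*; it does not
certify performance on clinical material, where stain quality, compression
and section thickness add variation the generator does not contain.

## Agreement statistics

Continuous scores are compared with Pearson r (Fisher-z CI, $R^2 = r^2$),
Spearman rho (Pearson on midranks, t-approximation p), and RMSE. Ordinal
agreement uses quadratically weighted Cohen's κ over the grading bins
{0}, (0,5], (5,10], (10,15], (15,20], (20,30], (30,100] — a score of
exactly 0 is its own category, and boundaries belong to the lower bin.
Bland–Altman analysis reports bias ± 1.96·SD limits of agreement. The
tolerance rate counts cases within ±5 *absolute* percentage points of the
mean over available raters, boundary inclusive; range classification is
inclusive at the extremes. Missing raters are handled by pairwise deletion,
matching how partially overlapping reading sets are analyzed in practice.

The κ confidence interval defaults to the large-sample (Fleiss–Cohen–
Everitt) standard error; a seeded case-resampling bootstrap is available
(`method = "bootstrap"`) and is the better choice for very sparse tables,
but with 7 ordinal bins and typical cohort sizes the asymptotic interval is
the conventional report, so it is the default. κ is undefined when a rater
uses a single category; that is an error, not a silent NA.

Averaging $n$ independent raters shrinks the error SD by $\sqrt{1/n}$
(≈ 0.58 for three raters), which is why correlations against a rater
consensus exceed correlations against individuals; the package exposes this
as `averaging_noise_factor()` so reports can state it rather than imply it.

## Problem sizes and runtime choices

The validation suite runs parameter recovery on 50 seeded slides at
1024×1024 px / 1 µm/px with true fractions spanning 1–35% (observed:
Pearson r > 0.99, mean absolute error < 0.5 percentage points), artifact
immunity on 10 vessel/tear/glare-only slides (all estimates 0 under the
defaults), and unit fixtures at 300–400 px. These sizes exercise every code
path — vacuoles both smaller and larger than the dynamic window, tears
crossing tissue, clipped glare — while keeping a full run in a few minutes
on one CPU; the estimator itself is resolution-consistent (physical
thresholds rescale via mpp), which the suite checks explicitly across a 2×
downsample.

## Known limitations

* Confluent high-grade steatosis (> 30%): merged vacuoles violate the
  disc-likeness gates and the method under-reports; it reports honestly but
  is not corrected for this regime.
* Microvesicular fat is out of scope (below the 15 µm design band; would
  need higher magnification).
* No stain normalization: gross staining failures break the
  brighter-than-tissue assumption rather than degrading gracefully.
* Whole images are processed in memory; there is no tiled/streaming mode
  for slides larger than RAM, and pyramidal reading is limited to
  multi-page TIFF (each page one level).
* The ±0.3-point placement tolerance of the generator is guaranteed only
  when the smallest vacuole is small relative to the tissue (true at the
  default sizes); tiny test tissues carry a correspondingly larger discrete
  placement error.
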