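---
title: "Marker-controlled watershed segmentation of darkfield cell images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-controlled watershed segmentation of darkfield cell images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darkcellseg)
```

## The problem and the model

Darkfield fluorescence micrographs of treated cell cultures show bright
green cells on a near-black background. Cells that internalize the
fluorescent compound are scored as affected by the treatment, so the
covered area and the cell count per field, compared across
concentration stages (control, 12.5, 25, 50 µg/mL), quantify the dose
response. The analytical challenge is that cells touch and cluster, so
a plain threshold undercounts; the package separates clumps with a
marker-controlled watershed on the distance transform, the standard
model-based approach for touching convex objects.

The watershed view treats a 2-D raster as a topographic surface whose
heights are flooded from its regional minima; pixels where floods from
two minima meet are ridges, the segmentation boundaries. Applied
directly to image intensities every spurious minimum becomes a basin
(over-segmentation); applied to the negated Euclidean distance
transform (EDT) of the cleaned binary mask, with minima *imposed* only
at markers deeper than a threshold h, each sufficiently thick blob core
becomes exactly one basin.

## Processing chain and its parameters

`segment_cells()` composes, in order:

| step | operation | default | why |
|---|---|---|---|
| 1 | resize longer side | `max_side = 1024` px | comparable per-image percentages; bilinear |
| 2 | green channel | — | fluorescence lives in the green band |
| 3 | median filter | 3×3 | impulse-noise removal, edge-preserving; smallest window |
| 4 | CLAHE | clip 0.01, 8×8 tiles | local contrast with bounded gain, background noise stays low |
| 5 | Otsu threshold | strict `> k` | between-class-variance maximum over all 256 levels |
| 6 | opening, closing | disk radius 3 | removes spurs/specks, closes rim gaps |
| 7 | area opening | 50 px, 8-connected | bright specks (air bubbles, reflections) are below 50 px |
| 8 | hole filling | 50 px, 4-connected holes | complement → area-open → complement |
| 9 | markers | extended minima, h = 3 | suppresses minima shallower than 3 px of thickness |
| 10 | watershed | 8-connected, in-mask | FIFO priority flood, ridge label 0 |
| 11 | size filter | 500 px | regions below it are not acknowledged complete cells |

The white-point metric counts pixels strictly above 200 (the intensity
range where high-dose and control histograms differ most) on the
*reference* grayscale — the resized, median-filtered green channel
before CLAHE — because contrast equalization rescales intensities and
would detach the threshold from its physical meaning. Histograms are
taken from the same reference image. Whether CLAHE feeds the Otsu stage
is configurable (`use_clahe`); it defaults to `TRUE`, which makes the
threshold adaptive to faded captures, and the equalized image is also
returned for inspection.

## Numerical choices

* **Surface quantization.** All surfaces are quantized to 0.1 height
  units before minima detection, reconstruction or flooding, so the
  ordering of near-equal floating-point heights — and therefore every
  label map — is reproducible across platforms.
* **Flood determinism.** The priority queue orders by height, then by a
  FIFO counter seeded in raster order; ties cannot reorder between
  runs. A pixel whose already-labeled neighbors disagree at pop time
  becomes a ridge and never propagates.
* **Border policy.** Out-of-raster pixels are background for both
  dilation and erosion (darkfield backgrounds dominate borders).
  Closing is computed on a padded canvas so its intermediate dilation
  is not clipped: without padding, `A ⊆ close(A)` fails at the border.
  The erosion–dilation duality `A ⊖ B = (Aᶜ ⊕ B̂)ᶜ` likewise holds in
  the infinite-plane sense, with the complement true outside the
  raster; the test suite checks it through a padded oracle.
* **Otsu ties.** When several levels maximize the between-class
  variance (exactly degenerate histograms), the mean of the maximizing
  set, rounded down, is returned — deterministic and symmetric.
* **Degenerate inputs.** Constant images yield an empty mask with a
  warning, not an error; an all-true mask (no background) is refused by
  the EDT; empty marker sets short-circuit to zero cells.
* **Minima imposition** uses reconstruction by erosion of a marker
  image that is a sentinel minimum on markers and a sentinel maximum
  elsewhere, over `min(surface + 1, marker image)`; the regional minima
  of the result are then provably the marker components, which the
  tests assert by plateau enumeration on every random surface.

## Geometry conventions (they matter for the ratios)

Perimeter is the length of the 8-connected outer boundary chain through
pixel centers with √2-weighted diagonal steps. The convex hull is taken
over pixel corners (so hull area always bounds pixel area, and solidity
is ≤ 1 by construction); Feret diameters are measured on pixel centers
by rotating-calipers over the center hull. Eccentricity comes from the
second-central-moment ellipse with the 1/12 per-pixel variance
correction.

The chain estimator overestimates smooth contour length by roughly 5 %
(a digitized line at 22.5° is the worst case), so a rasterized disk of
radius 50 scores form factor ≈ 0.91 and convexity ≈ 0.96 rather than 1,
while squares and rectangles are exact. This bias is inherent to the
estimator, documented here because form factor is sensitive to it; the
closed-form descriptor values (circle form factor 1, square π/4, square
extent 1, circle roundness/solidity/compactness 1) are exact because
they bypass rasterization. Under the diagonal Feret convention a
square's roundness is 4a²/(π·2a²) = 2/π ≈ 0.637 and its compactness is
√(4/π)·a/(a√2) ≈ 0.798; reference values of π/2 and 2/π sometimes
quoted for these two quantities are mutually inconsistent with the
formulas under any single diameter convention, so only the circle
values are asserted. A square's aspect ratio equals 1 only under
equivalent-ellipse axes; with Feret diameters it is √2, a documented
discrepancy, and the Feret convention is kept because the per-cell
reports expose Feret properties explicitly.

Compactness sometimes circulates written as "4·Area/π / MaxDiameter",
which is dimensionally inconsistent (a length, not a ratio); it is
implemented as √(4A/π)/Dmax, the equivalent-disk diameter over the
maximal Feret diameter, which makes the circle value exactly 1.

## The agreement metric

For ground truth of N annotated cells, ε = (Σⱼ Bⱼ)/N × 100 %. The
indicator Bⱼ is defined by mask overlay; since literal pixel identity
is unattainable for any realistic segmenter, the default criterion is
IoU ≥ 0.5 with greedy one-to-one matching by descending IoU (ties to
the smaller predicted label), and the exact-identity mode is retained
as an option. ε counts successes, so it is reported as *agreement*,
with `error = 100 − ε` derived alongside, and suite summaries give the
sample mean and n−1 standard deviation. Both interpretations of the
overlay criterion ship; neither is asserted as the original study's.

## What the synthetic generator emulates — and what it does not

The generator reproduces the features of the darkfield captures that
drive the pipeline's behavior: Gaussian background noise (mean 8,
sd 4 — a visually plausible darkfield floor), bright green elliptical
cells (peak 200–240, falling to ~65 % at the rim, multiplicative
speckle), eccentricities up to ~0.85 to exercise the descriptor ranges,
sub-50-px white specks as artifacts, and cell counts that grow with the
dose stage (0/12/24/40 per 512×512 canvas for stages A–D; a full-scale
validation suite of 28 images of 42–51 cells each, ~1300 cells total).
Cell axes are sampled so every rasterized cell exceeds the 500-px
completeness filter. A fraction (default 0.15) of cells is placed
overlapping a partner; the generator's contract is that touching pairs
keep distinct thickness maxima, which is enforced at placement time by
checking that the emulated post-closing mask of the candidate pair
yields exactly two extended-minima markers at depths 3 and 4 —
placements that would merge are re-drawn. Chains of three or more
touching cells are not generated.

It does **not** simulate optical point-spread functions, hyperspectral
band structure, uneven illumination, out-of-focus cells, or densely
clustered colonies. Passing the synthetic-analog accuracy runs
therefore shows the pipeline is correct and well-behaved under the
stated imaging model; it does not certify performance on real
microscope captures, whose difficulty (irregular shapes, debris,
illumination gradients) can only be assessed against real annotations.

## Problem sizes and reproducibility

The test suite and the synthetic validation runs use 512×512 canvases
(processed at native resolution, `max_side = 512`), 28-image suites and
10-image count checks; oracle equivalence runs use 100 random images
for thresholding, 50 random 16×16 masks for the EDT, 50 random 8×8
surfaces for the watershed and hundreds of random small masks for the
morphology laws — sizes at which the brute-force oracles are exact and
fast. A single integer seed drives each generator call; identical seeds
and configurations give bit-identical images, label maps and feature
tables, which the suite asserts byte-for-byte on the exported CSVs.

## Known limitations

* The watershed separates touching cells only where each has a
  distinct thickness maximum deeper than h = 3 px; flat, wide-necked
  clumps merge by design (lowering h re-introduces over-segmentation).
* Perimeter-derived ratios carry the ~5 % chain-length bias above.
* Cells touching the image border are kept as long as they pass the
  500-px filter, but their geometry is truncated by the frame.
* The agreement metric is threshold-based; boundary-distance metrics
  (Hausdorff, ASSD) are out of scope.
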