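# darkcellseg

Segmentation and quantification of fluorescent cells in darkfield RGB
micrographs, for dose–response experiments on treated cell cultures.

In darkfield fluorescence imaging of compound-exposed cultures, cells
that internalize the fluorescent compound light up bright green on a
near-black background; the fraction of the field they cover, and their
count, track the treatment effect across concentrations (control, 12.5,
25 and 50 µg/mL). `darkcellseg` turns one such capture into per-cell
geometry and per-image dose-stage summaries, for the biomedical analyst
who needs reproducible numbers rather than visual impressions.

## Method

The pipeline is the classical marker-controlled watershed chain:

1. **Pre-processing** — resize to a standard size, extract the green
   channel, median-filter (3×3), contrast-limited adaptive histogram
   equalization (clip 0.01, 8×8 tiles).
2. **Binarization** — Otsu's threshold, maximizing the between-class
   variance σ²_B(k) = (m_G·P₁(k) − m(k))² / (P₁(k)(1 − P₁(k))) over all
   256 levels; pixels above k* are foreground.
3. **Mask cleanup** — morphological opening and closing with a
   disk-shaped structuring element of radius 3, removal of foreground
   specks under 50 px and filling of holes under 50 px.
4. **Cell separation** — the negated exact Euclidean distance transform
   turns every blob into a catchment basin; extended minima of depth
   h = 3 mark candidate nuclei, minima imposition forces the surface's
   minima onto those markers, and deterministic priority-flood watershed
   (FIFO within each height level) labels one basin per marker, with
   ridge pixels kept at label 0. Labels under 500 px are discarded as
   incomplete cells.
5. **Quantification** — per cell: area, filled area, perimeter
   (√2-weighted boundary chain), convex hull, Feret diameters, and the
   dimensionless descriptors form factor 4πA/P², roundness 4A/(πD²max),
   aspect ratio, solidity A/A_hull, extent A/A_bbox, compactness
   √(4A/π)/Dmax, convexity and eccentricity. Per image: percent cell
   area, cell count, percent of white points (> 200) and the 256-bin
   intensity histogram.

Segmentation accuracy against labeled ground truth is scored per image
as ε = (Σⱼ Bⱼ)/N × 100 %, where Bⱼ indicates whether annotated cell j is
matched by a predicted region (IoU ≥ 0.5 by default, or exact pixel
identity), plus the mean absolute error of cell counts.

Because annotated darkfield captures of this kind are rarely shareable,
the package ships a seeded synthetic generator that emulates them — noisy
near-black background, bright green elliptical cells (some touching,
with guaranteed distinct thickness maxima), sub-50-px bright specks as
artifacts, and dose-dependent cell density — with exact ground-truth
masks, so every stage of the pipeline is testable end to end.

## Worked example

```r
library(darkcellseg)
cfg <- pipeline_config(max_side = 512)
series <- generate_stage_series(seed = 1)   # four-stage synthetic dose series
for (st in names(series)) {
  seg <- segment_cells(series[[st]]$image, cfg)
  print(stage_report(seg$gray, seg$labels, st))
}
```

```
Stage A: 0 cells, 0.00% cell area, 0.03% white points
Stage B: 12 cells, 3.82% cell area, 1.07% white points
Stage C: 24 cells, 7.01% cell area, 1.73% white points
Stage D: 40 cells, 12.50% cell area, 2.93% white points
```

The control stage contains only noise and bright specks, all removed by
the 50-px and 500-px filters; percent cell area then rises strictly with
dose. Checking the stage-D segmentation against the generator's ground
truth, and looking at a few per-cell descriptors:

```r
sample <- series$D
seg <- segment_cells(sample$image, cfg)
print(mask_agreement(seg$labels, sample$truth))
#> agreement 100.0% (40/40 cells matched, criterion iou)

head(shape_descriptors(region_census(seg$labels))[1:3,
  c("label","area","perimeter","form_factor","solidity","eccentricity")])
#>   label area perimeter form_factor solidity eccentricity
#> 1     1  823   105.497       0.929    0.965        0.649
#> 2     2  725   100.912       0.895    0.960        0.759
#> 3     3  691    98.184       0.901    0.963        0.681
```

All 40 cells are recovered; the near-1 solidity and the form factors in
the 0.9 range are what slightly elliptical convex cells should score.

A command-line front end is installed at
`system.file("scripts/cellseg", package = "darkcellseg")` with
`process`, `synth` and `validate` subcommands over the same functions.

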