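---
title: "Scoring micronuclei in acridine-orange micrographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring micronuclei in acridine-orange micrographs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mncount)
```

## The problem

The in vitro micronucleus assay scores the fraction of interphase cells
whose cytoplasm contains, besides the main nucleus, one or more small
chromatin bodies (micronuclei) — a biomarker of chromosomal damage.
Regulatory use requires on the order of a thousand scored cells per
condition, which makes manual scoring the bottleneck. Under acridine orange,
nuclei and micronuclei fluoresce green and the cytoplasm red, so the two
compartments can be separated by channel and the micronucleus/nucleus
distinction reduces to size, while debris rejection reduces to shape.
`mncount` implements that program as a deterministic pipeline with six
auditable parameters per image.

## The pipeline and its assumptions

1. **Channel split.** Red and green planes are kept; blue carries no stain
   information and is discarded.
2. **Green binarization.** Pixel ≥ `binarization_th` is nuclear material.
   The threshold is picked automatically from the green histogram: the modal
   nonzero intensity (ties toward the lower bin; bin 0 is excluded as
   saturated background) is mapped monotonically onto the five
   representative levels 65/75/85/120/165. The mapping bins (peak < 50 → 65,
   50–69 → 75, 70–99 → 85, 100–149 → 120, ≥ 150 → 165) are this package's
   own calibration of that monotone relation and can be overridden.
3. **Cleaning.** Opening then closing with the small square element
   (`kernel_s`, default 3 px) removes speckle and fills pinholes. Windows
   are clipped at image borders, so border objects are not eroded from
   outside the field.
4. **Size discrimination.** The cleaned mask is eroded with the large square
   element (`kernel_l`). Connected components (8-connectivity) with a
   surviving remnant are nuclei; components erased entirely are micronucleus
   candidates. Erosion is the standard realization of the size-selective
   "reduction" idea; survivors are restored to their full original component
   extent rather than re-dilated, so nucleus footprints are exact. A
   consequence, accepted as inherent to the method: a micronucleus touching
   its nucleus merges into the nucleus component and cannot be detected.
5. **Candidate filtering.** Candidates need area ≥ `noise_reduction` and
   chain-code circularity ≥ `micronucleus_th`. Circularity is
   `min(1, 4πA/P²)` with P the 8-connected boundary chain length
   (orthogonal step 1, diagonal √2); single pixels get circularity 1 by
   convention, and the clip at 1 compensates the chain's underestimation of
   digital-disk contours, so round spots genuinely score 1.
6. **Cytoplasm.** The per-pixel max of red and green is passed through a
   sigmoid `s(v) = round(255/(1+exp(-g(v-c))))` centered at the window level
   `c` (default 118, gain `g` = 0.05), thresholded by Otsu's method, cleaned
   and hole-filled. The binarized green mask is folded in first, so nuclei
   always lie inside their cytoplasm. Otsu after the sigmoid is our choice —
   the enhancement makes the composite strongly bimodal, which is exactly
   Otsu's operating regime — and is override-able.
7. **Cell separation.** Nucleus components are markers that grow
   geodesically through the cytoplasm mask (marker propagation with a
   distance-dominated metric), cutting fused cytoplasm near the midpoint
   between adjacent nuclei; the dividing line belongs to no cell. Cytoplasm
   without a marker (ghosts, debris fields) is not a cell; cytoplasm with k
   nuclei becomes k cells.
8. **Classification.** An accepted micronucleus belongs to the cell whose
   label contains its centroid — cheaper than overlap-majority voting and
   unambiguous; centroids on dividing lines or background are discarded. A
   cell is one MN cell whether it carries one micronucleus or several.
   Border-touching cells are counted by default (the goal is every cell in
   the imaging field); an `exclude_border` flag is available.

The sigmoid gain is configuration rather than a tunable threshold: it is
fixed at 0.05 and deliberately kept out of the parameter files, whose
six-line format (binarization TH, kernel S, kernel L, noise reduction,
micronucleus TH, window level — in that order) is shared between the
per-image `Palam` files and `PalamLock.txt`. "Window level" and "gradation
center value" name the same quantity here.

## Automatic kernel sizing

The large kernel follows the cells actually in the image: a coarse pre-pass
(Otsu on green, components with area > 50 px², median equivalent diameter
`2√(A/π)`) estimates the nucleus diameter `d`, and
`kernel_l = nearest odd ≥ max(7, round(0.6 d))`. The noise floor follows the
kernel: 11 px² up to kernel 15, 21 px² beyond. The 0.6 factor places the
kernel safely between the micronucleus scale (radius ≤ ~5 px, which must be
erased) and the nucleus scale (radius ≳ 0.7 × kernel, which must survive);
a square k×k element erases any digital disk whose radius is below about
0.71(k−1), plus up to ~0.7 px when the disk center falls between pixel
centers.

## What the synthetic generator emulates — and what it does not

`synth_spec()` renders: red-dominant cytoplasm ellipses (red 140 ± 15,
green bleed 40 ± 10), one green nucleus disk per cell and green
micronucleus disks (green 200 ± 15, red bleed 30 ± 8), flat background 5,
additive Gaussian sensor noise (sd 5), optional touching-cell clusters
(2 px overlap along the center line) and optional elongated green debris.
These intensities put the histogram peak in the lowest threshold bin and
keep the sigmoid at 118 separating cytoplasm (≈190 after enhancement) from
background (≈1).

Geometry defaults, chosen once for a 20× field: nucleus radii 11–12.5 px,
micronucleus radii 3–4.5 px, cytoplasm semi-axes 28–40 px, micronuclei at
least 3 px clear of the nucleus edge and of each other, non-touching cells
at least 5 px apart (guaranteed between circumscribed circles, hence
analytically verifiable). The nucleus band sits deliberately above the
erosion-survival bound of the automatic kernel (13 or 15 px here): the
method presumes its two size classes are separable, as they are in real
assay images; radii near the bound are exactly the regime the published
workflow resolves by manual reanalysis, which a recovery test should not
conflate with the automatic path. Debris defaults (width 4.8–5.2 px,
elongation 4.2–4.6) were measured to give chain circularities of 0.48–0.61
across orientations — accepted by the 0.5 default, rejected at the
practical 0.65 setting, reproducing the published tuning narrative.
Substantially thinner debris is unusable for that purpose: a ~3 px strip
both scores ≈ 0.85 circularity at modest elongation and fragments under the
3×3 opening into compact round chips that mimic micronuclei.

Passing recovery tests on these scenes shows the operator chain is correct
on its stated model: crisp edges, flat illumination, disk-shaped nuclei,
Gaussian noise. Real micrographs add point-spread blur, uneven staining and
illumination, chromatin texture, overlapping (not merely touching) cells,
and micronuclei in contact with the nucleus — none of which the generator
models, and all of which are the reason the published workflow retains
per-image manual reanalysis.

## Numerical choices and degenerate inputs

- Binarization uses ≥, so a pixel exactly at threshold is foreground.
- 16-bit TIFF input maps to 8-bit by integer division by 257.
- Histogram-peak ties break toward the lower intensity.
- A blank (or unresolvable) image falls back to kernel 13 / noise 11 with a
  warning and reports zero cells; `default_params()` refuses diameter
  estimates below 6 px as below the method's scale.
- Zero pooled variance with equal means reports t = 0, p = 0.5; the t-test
  direction is always an explicit argument (default: first method over
  second), never inferred from the data.
- The label palette is a golden-angle hue sequence keyed by label id, and
  every output is a pure function of (image, parameters), so re-runs are
  byte-identical — the property the workflow tests assert.
- Relative viability uses R's round-half-to-even; no published row sits on
  a .5 boundary, so this choice is inert there.

## Problem sizes in the shipped tests

Unit tests run on 320² scenes with 4–6 cells; the recovery suites use the
default 768² / 30-cell scene over 20 seeds (well-separated: exact total and
MN-cell recovery required on every seed; touching pairs: exact totals on at
least 19 of 20). Oracle suites compare erosion/opening/closing/labeling and
the chain perimeter against brute-force sliding-window, flood-fill and
independent contour tracers on 200 random masks up to 32². The acceptance
script reruns recovery at 10 seeds per condition, which keeps a full run
within a few minutes on one core.

## Known limitations

- Micronuclei touching the nucleus are absorbed by design (step 4).
- No nucleus-morphology classes: binucleated cells (CBMN scoring), nuclear
  buds and bridges are out of scope.
- No stain-quality correction or per-channel white balance; images should be
  grouped by staining quality before batch reanalysis, mirroring the
  published recommendation.
- The circularity statistic is resolution-dependent (chains on digital
  grids), which is why the threshold is a tunable, not a constant.
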