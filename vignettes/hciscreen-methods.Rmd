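---
title: "Methods: image analysis for cell-surface ligand-binding screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image analysis for cell-surface ligand-binding screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hciscreen)
```

## The assay and its readout

The screen images each well of a 384-well plate in two fluorescence
channels: Hoechst-stained nuclei (Ch1) and an Alexa488-labelled antibody
that marks recombinant ligand bound at the cell surface (Ch2). Receptors
are overexpressed by transient transfection, so only a subpopulation of
cells can bind the probe; bound probe appears as a ring of membrane
staining around the cell. Two well-level statistics summarise a well:

* the average number of segmented nuclei per field (a cell-attachment and
  focus proxy), and
* **% Cells High**: the percentage of cells whose *target average
  intensity* is at or above a response limit.

The per-cell measurement chain is:

1. **Background removal** (`preprocess_background()`): both channels are
   background-corrected by subtracting a grayscale opening (erosion then
   dilation) with a large square structuring element, clipping negatives to
   zero. The opening is a pointwise lower envelope, so corrected values
   never exceed the input, and a uniform field maps exactly to zero. The
   structuring half-width must be much larger than a nucleus (default 48 px
   at the default 1104-px field scale) so objects are not absorbed into the
   background estimate.
2. **Primary objects** (`segment_nuclei()`): Gaussian smoothing, a global
   threshold, hole filling, connected components, an optional
   distance-transform watershed to split touching nuclei, and a minimum
   area filter. Objects touching the field border are retained by default;
   exclusion is a flag.
3. **Region of interest** (`build_roi()`): each nucleus mask is dilated by
   a rasterized disk (default radius 10 px) to approximate the whole-cell
   footprint. ROIs of neighbouring cells may overlap; each cell is measured
   independently.
4. **Target measurement** (`measure_target()`): within the ROI, only Ch2
   pixels *at or above* the fixed threshold enter the target mask
   (inclusive comparison). The target average intensity `T` is the mean
   over those pixels and is defined as 0 when no pixel passes — unbound
   cells score exactly 0 rather than a background average.
5. **Classification** (`classify_response()`): a cell responds when
   `T >= L` (the response limit, inclusive); `% Cells High` is the
   responder percentage, 0 for an empty population.
6. **Focus QC** (`assess_focus()`): the sharpness score is the variance of
   the 4-neighbour Laplacian of Ch1. A field is rejected when its score
   falls below a configured fraction (default 0.5) of the reference — the
   median score of the well's fields unless a plate-level reference is
   supplied. Rejected fields contribute nothing to any statistic; a well
   whose every field is rejected is flagged `no_analyzable_fields` with
   null-marked features, never fabricated values.

## Threshold calibration from negative controls

Control transfections occupy two interior columns of each plate (columns 2
and 13 by default; the within-column split between negative and positive
controls is a layout choice, default half/half). Negative-control wells are
first measured with a fixed threshold of 0, which makes each cell's
ROI mean and SD recoverable; `calibrate_from_controls()` then sets

* `fixed_threshold = mean + k * SD` (default `k = 5`) of the pooled
  **per-pixel** ROI intensity distribution of negative-control cells,
  reconstructed exactly from the per-cell summaries by the law of total
  variance, and
* `response_limit = fixed_threshold` by default.

A deliberate reading: the calibration statistic is the *pixel* intensity
distribution, not the distribution of per-cell mean intensities. With the
default rule `response_limit = fixed_threshold`, a single suprathreshold
pixel makes a cell a responder (its target average is then at least the
threshold). Per-cell means concentrate as `noise / sqrt(ROI area)`, so a
threshold five of *those* SDs above the mean would sit far inside the
single-pixel noise tail and negative controls would saturate. Five pixel
SDs put the per-cell false-positive probability around `ROI area x 3e-7`,
which keeps negative-control wells at or below 1% Cells High — the
contract the calibration must satisfy on the wells it was computed from.

Because the response limit only re-thresholds per-cell summaries, but the
fixed threshold changes which pixels are measured, the pipeline runs
calibration in two passes: control wells at threshold 0, then every well
(controls included) under the calibrated configuration. Image generation
and loading are deterministic per well, so both passes see identical data.

## Segmentation threshold: why the default is a noise floor, not Otsu

Otsu's method assumes a usefully bimodal histogram. In these fields the
nuclei are sparse and bright on a flat background, so Otsu lands near half
the bright-nucleus amplitude — and a dimly transfected nucleus (a low draw
from the amplitude distribution) falls below it and disappears. Losing dim
cells biases % Cells High, because dim cells are disproportionately
non-responders. The default threshold is therefore a robust noise floor,
`median + 6 * MAD` of the smoothed background-subtracted channel: blank
fields stay empty (isolated noise excursions are removed by the minimum
area filter), while any nucleus a few hundred counts above background is
kept. Otsu (bounded below by the same floor) and fixed numeric thresholds
remain available in `seg_params()`.

Touching nuclei are split by a marker watershed: markers are the local
maxima of the lightly smoothed interior-distance transform, with a minimum
separation (`split_min_distance`, default 6 px; set near the nucleus
radius), flooded on the negated distance. Heavily overgrown clusters merge
into convex blobs that no shape-based method can split; the synthetic
clumping mode (below) deliberately produces the splittable touching-pair
regime plus a residue of genuine under-segmentation.

## The synthetic world

`generate_field()` draws a Poisson number of cells (capped at a packing
limit — density saturates in a confluent monolayer, and the cap keeps
rejection sampling away from its jamming density), places nucleus centers
by rejection sampling with a minimum spacing, marks each cell transfected
with probability `transfected_fraction` and each transfected cell bound
with probability `bound_fraction`, and renders:

* Ch1: one soft-edged disk per nucleus (flat top, ~1 px Gaussian rim),
  amplitude drawn per cell;
* Ch2: an annular ring of Gaussian radial profile (peak at
  `nucleus_radius + membrane_offset_px`, default offset 3 px; SD
  `ch2_ring_width_px / 2`) around each *bound* cell;
* both: uniform background, per-pixel Gaussian noise, clipping to the bit
  depth; optional Gaussian defocus of the noiseless signal.

`clump_fraction` places that fraction of cells at touching distance
(centers 1.7–2.1 nucleus radii from a regularly placed anchor; clumps do
not chain) to stress the splitter. Defaults describe a 20x field on a
16-bit camera: 1104 x 1104 px, ~200 cells per field, nucleus radius
16 ± 2 px, nucleus amplitude 20000 ± 3000 over background 2000, ring
peak 15000 ± 2000, noise SD 300, four fields per well sampled from a
notional 5 x 5 grid.

What a green test on this world establishes — and what it does not: the
generator reproduces the assay's *signal structure* (two co-registered
channels, a ring-positive subpopulation, background and sensor-like noise,
defocus, touching nuclei), so it validates the measurement chain, the
calibration logic and the plate statistics end to end. It does not emulate
photon (Poisson) noise, point-spread functions, vignetting, uneven
illumination, debris, apoptotic or mitotic morphologies, or biological
variation in expression level; agreement on synthetic plates is necessary,
not sufficient, for agreement with instrument data.

### Geometry of a trustworthy fixture

One subtlety discovered while building the test worlds: ROIs are allowed
to overlap, so a cell's ROI can capture a *neighbour's* membrane ring and
inflate % Cells High. The fixture worlds therefore keep

```
min_center_spacing >= (nucleus radius + ROI dilation)        # ROI reach
                      + (ring radius + suprathreshold tail)  # ring extent
```

so crosstalk is geometrically impossible. On real plates this term is a
genuine assay property (confluent neighbours share signal); the package
measures it faithfully rather than correcting for it.

Scaled-down fields (220–260 px, ~30–50 cells, radius 6 px) are used for
plate-scale tests and the acceptance script; field dimensions are a
fixture convention, and the scaled world keeps a full 384-well simulated
screen within a single-CPU budget of minutes.

## Numerical and design choices

* Inclusive (`>=`) comparisons for both the fixed threshold and the
  response limit.
* `% Cells High` is monotone nonincreasing in the response limit (the
  target averages are fixed), and in the fixed threshold *when the
  response limit is tied to it* (a responder is then a cell with any
  suprathreshold pixel, and raising the threshold shrinks every target
  mask). With the limit held fixed strictly above the threshold,
  raising the threshold alone can raise a cell's target average (the mean
  over a brighter, smaller mask) across the limit, so monotonicity in the
  threshold alone is not guaranteed and is not asserted.
* Coordinates are R-native 1-based (row, column); masks are logical
  matrices; intensities are unitless counts in `[0, 2^bit_depth - 1]`.
* Chamfer (3,4)/3 distance transform; priority-flood watershed with FIFO
  tie-break; 8-connected components; reflective boundaries for
  convolution, replicated edges for running min/max morphology.
* Seeds: every generator takes an explicit seed; per-well and per-field
  seeds are derived by a fixed integer recurrence below 2^31, so plates
  are reproducible well by well in any evaluation order.
* Serialization is JSON (config, calibration, run log, truth sidecars);
  tabular outputs are CSV; images are minimal uncompressed grayscale
  TIFFs (8/16-bit) written and read by the package itself and verified
  against an independent TIFF implementation in the tests.
* Per-well population statistics are persisted by default; per-cell tables
  are behind a flag, mirroring the screen's small-storage design.

## Known limitations

* Segmentation equivalence with any vendor implementation is not claimed;
  only the described workflow (primary objects, circular ROI, fixed
  threshold, response limit, the two well features) is reproduced.
* The hit threshold on % Cells High is a configuration decision (default
  10%); the package reports control separation but does not choose the
  threshold automatically.
* The rate-assay utility fits a single linear window (default: the whole
  series); substrate-depletion plateaus must be excluded by the caller.
* Heavily overgrown clusters remain under-segmented by design; nuclei
  counts are estimates, not absolutes, which is why plate QC compares
  wells against the plate median rather than absolute counts.
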