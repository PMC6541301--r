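---
title: "Counting sympathetic nerve fibers: the fibercount method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting sympathetic nerve fibers: the fibercount method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibercount)
```

## The measurement problem

Sympathetic innervation of a tissue is usually quantified by
immunofluorescence against tyrosine hydroxylase (TH), the rate-limiting
enzyme of catecholamine synthesis. TH alone is ambiguous: it stains
sympathetic fibers *and* catecholamine-producing cells. A second stain
against peripherin — a neurofilament expressed exclusively in peripheral
nerve fibers — disambiguates the two: structures positive for both markers
are fibers, TH-only structures are cells.

`fibercount` implements a semi-automated counting workflow over paired
single-channel images (TH, peripherin), producing per-image counts and
densities in events/mm². Two pipelines share the same primitives:

* **Fibers** (`count_fibers()`): threshold the TH channel (Otsu) to build
  the TH-positive ROI; restrict the peripherin channel to that ROI and
  threshold it again (iterative intermeans on the ROI-restricted
  histogram); extract 8-connected particles of the intersection; keep
  particles of at least `min_fiber_area_px` pixels. Every counted particle
  is TH/peripherin double-positive by construction.
* **Cells** (`count_cells()`): threshold the peripherin channel (triangle)
  to find all fiber area; clear (zero) those pixels in a copy of the TH
  channel; triangle-threshold the cleared image; count particles of at
  least `min_cell_area_px` pixels. Reported cells never overlap the
  peripherin mask.

All thresholds use the bright-object convention: foreground is
`intensity > t` on 8-bit data.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `pixels_per_um` | 2.828 | px/µm | lateral sampling at 400× on the nominal setup; a 1600 × 1200 px field covers 0.24 mm² |
| `min_fiber_area_px` | 23 | px | minimum double-positive particle area, ≈ 8 µm (the average diameter of peripheral nerve fibers) at the nominal scale |
| `min_cell_area_px` | 23 | px | minimum TH-only particle area; the original protocol left this value unstated, so the default mirrors the fiber filter and should be treated as a tunable, not a reproduced constant |
| manual length criterion | 50 | µm | `filter_manual_criterion()` emulates the by-eye protocol that admits only oblong objects ≥ 50 µm (141.4 px); used for method-comparison experiments |
| threshold methods | otsu / intermeans / triangle / triangle | — | per stage, in the order TH-ROI, peripherin-in-ROI, peripherin-ROI, cleared-TH |

The density denominator is always the full image area
(`width × height / (pixels_per_um² · 10⁶)` mm²), not the ROI area, so
densities are comparable across images regardless of how much tissue is
positive.

## The threshold algorithms

The three histogram rules are implemented on 256-bin histograms
(`histogram256()`), with bin *t* always assigned to the lower class:

* **Otsu** maximizes the between-class variance
  $\omega_0\,\omega_1\,(\mu_0-\mu_1)^2$ over all 256 candidate cutoffs;
  ties are broken toward the smallest maximizing *t* for determinism.
* **Triangle** draws the chord from the histogram peak to the farthest
  populated tail bin and returns the bin with the maximum perpendicular
  distance to it; when the peak lies nearer the bright end the histogram
  is mirrored first and the result mapped back through
  $t \mapsto 255 - t$.
* **Intermeans** (the IsoData-family rule behind the ImageJ "Default"
  tool) iterates $t \leftarrow \mathrm{round}\big((\mu_{\le t} +
  \mu_{>t})/2\big)$ from the midpoint of the populated range until a fixed
  point; rounding is half-up, the iterate is clamped so both classes stay
  populated, and the loop is capped at 256 steps (an assertion, not a
  practical limit).

A histogram with a single populated bin has no meaningful cutoff; all
three methods return that bin with a `degenerate` flag, which pipelines
carry in their provenance rather than treating as an error (a blank
channel then simply yields zero counts).

Whether the original "Default" tool differs from plain IsoData in edge-bin
handling is not documented; the two differ only on pathological
histograms, and this package fixes the IsoData behaviour above.

## Particle analysis

`label_components()` extracts 8-connected components (diagonal contact
joins, matching the analyze-particles default). The first labelling pass
uses `EBImage::bwlabel()` (4-connected) and a union–find pass merges
diagonally touching labels; labels are then renumbered in row-major
first-pixel order. Per particle the table reports area, centroid, bounding
box and the maximum caliper (Feret) diameter — the largest pairwise
distance between pixel centres, computed over the convex hull. With
pixel-centre coordinates a straight n-pixel segment measures n−1 px; at
the default scale the 50 µm manual criterion (141.4 px) therefore admits
segments of 142 px and longer.

There is no maximum-size or circularity filter and edge-touching particles
are counted, matching the macro behaviour. Touching structures are not
split: two crossing fibers count as one particle (a limitation shared with
the original workflow).

## Histogram restriction and clearing semantics

Two semantic choices in the pipelines deserve explicit statement:

* The peripherin threshold inside the TH ROI is computed from the
  histogram of ROI pixels **only** (`restrict_histogram = TRUE`),
  mirroring the copy-selection-to-a-new-image step of the macro chain.
  This requires the ROI to contain both modes — peripherin-bright fiber
  pixels and peripherin-dark TH-cell pixels. In fields containing no
  TH-positive cells at all the restricted histogram is nearly unimodal
  and the intermeans cutoff splits the bright mode, fragmenting fibers;
  real tissue always contains TH+ cells, but the whole-image alternative
  is exposed as a switch.
* Cleared pixels are set to 0 and **included** in the cell-stage histogram
  (`exclude_cleared = FALSE`), the literal clear-then-threshold order of
  the macro. The statistically cleaner alternative (excluding them) is a
  switch. A TH particle partially overlapping the peripherin mask
  survives only via its non-cleared remainder, which must itself pass the
  size filter.

## The synthetic-data generator

No raw microscopy from the original study is available, so validation
rests on `generate_pair()`/`generate_benchmark_set()`, which render
two-channel fields with known ground truth:

* geometry: 1600 × 1200 px at 2.828 px/µm by default;
* fibers: random-walk polylines (length 20–120 µm, stroke width 2–6 px,
  heading jitter sd 0.25 rad per 1-px step), bright in both channels;
* cells: disks of 5–15 µm diameter, bright in TH only;
* optional peripherin-only fibers (non-sympathetic — must be counted by
  neither pipeline) and small near-round "laterally sectioned" fiber
  blobs, the class the automated method counts and the 50 µm manual
  criterion misses;
* intensities: background N(20, 8) and foreground N(200, 12) per pixel,
  clipped to [0, 255] — contrast typical of well-exposed 8-bit
  fluorescence, far above the signal-to-noise regime where thresholding
  becomes marginal; 2% spectral bleed-through into the negative channel;
* placement: structures keep a 6 px Chebyshev gap (bounded retries, then
  an error), so planted truth sets are pairwise disjoint;
* determinism: one integer seed drives R's Mersenne–Twister; the caller's
  RNG state is saved and restored.

What the generator does **not** emulate: optics (no point-spread blur,
vignetting or chromatic shift), staining artifacts, autofluorescence
texture, intensity gradients, or touching/crossing structures. Passing
recovery tests therefore demonstrates correctness of the operator chain on
well-separated, well-exposed structures — not robustness to the full
variability of real stainings.

## Validation design and problem sizes

The test suite validates each algorithm against an independent oracle:
Otsu against an exhaustive 256-candidate brute force, triangle against a
pointwise perpendicular-distance search, intermeans against a literal
fixed-point loop (1,000 random histograms in the acceptance suite),
labelling against a queue-based flood fill and calipers against all-pairs
distances on masks up to 32 × 32. End-to-end, both pipelines must recover
planted counts exactly on at least 95% of 100 full-size (1600 × 1200)
seeded replicates, and a two-group benchmark with different planted
densities must yield a detectable group difference downstream.
`scripts/acceptance.R` re-runs this validation from scratch and writes the
measured quantities as JSON.

## Statistics

The agreement layer (`compare_methods()`) reports the two-sided t-test
between methods (Welch by default; the pooled form is a switch), the
least-squares slope of automated on manual counts, the Bland–Altman
summary — bias, 1.96-sd limits of agreement, and the least-squares slope
of differences on pair means, a non-classical but deliberately reported
summary of proportional bias — and per-method CV = sd/mean (n−1
denominator) with SNR = 1/CV. Zero-variance groups are handled as limits
(t = 0, p = 1 for equal means) rather than errors. No multiple-testing
correction is applied, matching the original analysis; none is silently
added. Whether images or animals form the unit of analysis is left to the
caller: both groupings can be expressed through the batch manifest.

## Known limitations

* Auto-thresholding presumes signal: on a signal-free noise field every
  global threshold slices noise, and rare above-threshold noise clusters
  can exceed the size filter. Blank-field behaviour is degenerate by
  construction and flagged, not suppressed.
* Single-plane analysis only; no fiber tracing, branching analysis or 3-D
  reconstruction.
* No pre-smoothing (blur/despeckle) is applied before thresholding — the
  macro chain describes none — so salt-and-pepper noise directly enters
  the mask.
* The cell-stage minimum area has no documented reference value; absolute
  cell densities depend on this tunable.
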