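# fibercount

Semi-automated counting of sympathetic nerve fibers and TH-positive cells
in two-channel immunofluorescence images.

## The problem

Sympathetic innervation is quantified by staining tissue sections for
tyrosine hydroxylase (TH), the rate-limiting enzyme of catecholamine
synthesis. TH alone cannot distinguish sympathetic **fibers** from
catecholamine-producing **cells**, and the classical remedy — counting
oblong, ≥ 50 µm structures by eye in 17 high-power fields — is slow,
observer-dependent, and blind to fibers sectioned perpendicular to the
imaging plane. Adding a peripherin counterstain (a neurofilament expressed
exclusively in peripheral nerve fibers) makes the distinction a pixel
operation: TH ∩ peripherin = fiber, TH \ peripherin = cell.

`fibercount` implements that workflow as composable R functions:

* **Fibers**: Otsu-threshold the TH channel into a region of interest
  (ROI); threshold the peripherin signal *within* that ROI (iterative
  intermeans on the ROI-restricted histogram); count 8-connected particles
  of the intersection with area ≥ 23 px (≈ 8 µm, the average diameter of a
  peripheral nerve fiber, at 2.828 px/µm).
* **Cells**: triangle-threshold the peripherin channel, clear those pixels
  from a copy of the TH channel, triangle-threshold the cleared image and
  count the remaining particles.

Densities are reported per mm² of imaged field
(`width·height / (pixels_per_um²·10⁶)`; 0.24 mm² for the nominal
1600 × 1200 px field). The agreement layer reproduces the
manual-vs-automated comparison statistics: Welch t-tests, the
least-squares slope of automated on manual counts, Bland–Altman bias,
limits of agreement and the slope of differences on pair means, and CV/SNR
summaries. Because no reference microscopy images are publicly available,
the package ships a seeded synthetic two-channel image generator with
known ground truth, used throughout the test suite.

## Worked example

```r
library(fibercount)

spec <- synthetic_spec(n_fibers = 5, n_cells = 10, seed = 42)
pair <- generate_pair(spec)           # TH + peripherin channel_images

count_fibers(pair$th, pair$peripherin)
#> <count_result [fibers]: 5 particles, 20.83 /mm2 over 0.2401 mm2>
#>   threshold th: t=60 [otsu]
#>   threshold peripherin: t=112 [intermeans]

count_cells(pair$th, pair$peripherin)
#> <count_result [cells]: 10 particles, 41.65 /mm2 over 0.2401 mm2>
#>   threshold peripherin: t=43 [triangle]
#>   threshold th_cleared: t=44 [triangle]
```

Both pipelines recover the planted truth exactly: 5 double-positive fibers
(20.83 fibers/mm² over the 0.24 mm² field) and 10 TH-only cells, with the
per-stage thresholds recorded as provenance. `tidy()` on a result returns
the per-particle table (area, centroid, bounding box, Feret diameter),
`glance()` a one-row summary, and `autoplot()` the counting-mask overlay.

Method agreement on paired per-image counts:

```r
counts <- tibble::tibble(mc = c(2, 5, 3, 8, 6, 4),
                         ac = c(4, 9, 5, 13, 11, 6))
compare_methods(counts, mc, ac)
#> <method_comparison: 6 image pairs>
#>   manual    mean 4.67 (sd 2.16)
#>   automated mean 8.00 (sd 3.58)
#>   t = -1.954, p = 0.08554 (Welch)
#>   scatter slope (ac ~ mc): 1.629
#>   Bland-Altman: bias 3.333 [0.382, 6.284], slope 0.498
```

The positive Bland–Altman slope says the automated method picks up
proportionally more events where events are frequent — the expected
signature, since it also counts laterally sectioned fibers that the 50 µm
manual length criterion must discard.

Batch processing reads a manifest CSV (`image_id, th_path,
peripherin_path`, optionally `tissue, genotype, manual_count`) and emits a
tidy per-image results table, group summaries and a machine-readable run
record (`run_batch()`, `batch_summary()`). A thin command-line wrapper
with `count-fibers`, `count-cells`, `batch`, `stats` and `simulate`
subcommands lives in `inst/cli/fibercount.R`.

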