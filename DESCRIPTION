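Package: fibercount
Title: Semi-Automated Counting of Sympathetic Nerve Fibers in Two-Channel
    Immunofluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Counts tyrosine hydroxylase (TH) and peripherin double-positive
    sympathetic nerve fibers and TH-single-positive cells in paired
    two-channel fluorescence microscopy images, reproducing an ImageJ-macro
    workflow: histogram auto-thresholding (Otsu, triangle, iterative
    intermeans), region-of-interest masking, 8-connected particle analysis
    with size filtering, and fiber/cell density in events per square
    millimetre. Includes manual-versus-automated method-comparison
    statistics (two-sided t-tests, scatter regression, Bland-Altman
    analysis with regression on means, coefficient of variation and
    signal-to-noise summaries), a seeded synthetic two-channel image
    generator with known ground truth for validation, and batch processing
    over image manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    patchwork,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
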