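#' Batch run configuration
#'
#' One configuration object covering both pipelines plus the batch-level
#' options (output directory, blinding, seed). Mirrors the per-stage
#' threshold choices of the macro chain.
#'
#' @param pixels_per_um Pixel scale (default 2.828).
#' @param min_fiber_area_px,min_cell_area_px Particle size filters.
#' @param th_fiber_method,peripherin_in_roi_method Threshold methods for
#'   the fiber pipeline stages.
#' @param peripherin_cell_method,th_cell_method Threshold methods for the
#'   cell pipeline stages.
#' @param blind Shuffle-anonymize image ids in outputs (ids are re-mapped
#'   with a seeded permutation and the key stored in the run record)?
#' @param seed Integer seed used for blinding.
#' @return A `run_config`.
#' @export
run_config <- function(pixels_per_um = 2.828,
                       min_fiber_area_px = 23,
                       min_cell_area_px = 23,
                       th_fiber_method = "otsu",
                       peripherin_in_roi_method = "intermeans",
                       peripherin_cell_method = "triangle",
                       th_cell_method = "triangle",
                       blind = FALSE,
                       seed = 1L) {
  scale <- pixel_scale(pixels_per_um)
  structure(list(
    scale = scale,
    fiber = fiber_count_config(min_fiber_area_px, th_fiber_method,
                               peripherin_in_roi_method, scale),
    cell = cell_count_config(min_cell_area_px, peripherin_cell_method,
                             th_cell_method, scale),
    blind = isTRUE(blind),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Run both counting pipelines over a manifest of image pairs
#'
#' For each manifest row the TH/peripherin pair is read, fibers and cells
#' are counted, and densities computed. Returns a tidy per-image results
#' tibble plus a machine-readable run record (configuration and per-stage
#' thresholds) sufficient to reproduce the outputs exactly. Missing image
#' files are reported and skipped; their ids are listed in the result's
#' `failed` attribute (the command-line wrapper exits non-zero when any
#' row fails).
#'
#' @param manifest A data frame (or CSV path) with columns `image_id`,
#'   `th_path`, `peripherin_path`, and optionally `tissue`, `genotype`,
#'   `manual_count`.
#' @param config A [run_config()].
#' @param out_dir Optional directory: writes `results.csv`,
#'   `summary.json` and `run_record.json`.
#' @return A `batch_result`: list with `results` (tibble, one row per
#'   image), `count_results` (list of the full `count_result` pairs) and
#'   `run_record`.
#' @export
run_batch <- function(manifest, config = run_config(), out_dir = NULL) {
  if (is.character(manifest)) manifest <- read.csv(manifest)
  manifest <- tibble::as_tibble(manifest)
  if (nrow(manifest) == 0) abort("Manifest is empty.")
  need <- c("image_id", "th_path", "peripherin_path")
  if (!all(need %in% names(manifest))) {
    abort(paste0("Manifest must contain columns: ",
                 paste(need, collapse = ", ")))
  }
  missing <- !file.exists(manifest$th_path) |
             !file.exists(manifest$peripherin_path)
  if (any(missing)) {
    warn(paste0("Skipping rows with missing files: ",
                paste(manifest$image_id[missing], collapse = ", ")))
  }
  opt_col <- function(col, default) {
    if (col %in% names(manifest)) manifest[[col]] else
      rep(default, nrow(manifest))
  }
  tissue <- opt_col("tissue", NA_character_)
  genotype <- opt_col("genotype", NA_character_)
  manual <- suppressWarnings(as.numeric(opt_col("manual_count", NA_real_)))
  rows <- list(); details <- list()
  for (i in which(!missing)) {
    th <- read_channel(manifest$th_path[i], "TH", config$scale)
    pe <- read_channel(manifest$peripherin_path[i], "peripherin",
                       config$scale)
    fib <- count_fibers(th, pe, config$fiber)
    cel <- count_cells(th, pe, config$cell)
    details[[manifest$image_id[i]]] <- list(fibers = fib, cells = cel)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      image_id = manifest$image_id[i],
      tissue = tissue[i],
      genotype = genotype[i],
      width_px = image_width(th), height_px = image_height(th),
      image_area_mm2 = fib$image_area_mm2,
      fiber_count = fib$count,
      fiber_density_per_mm2 = fib$density_per_mm2,
      cell_count = cel$count,
      cell_density_per_mm2 = cel$density_per_mm2,
      manual_count = manual[i],
      threshold_th = fib$thresholds$th$threshold,
      threshold_peripherin = fib$thresholds$peripherin$threshold,
      threshold_peripherin_roi = cel$thresholds$peripherin$threshold,
      threshold_th_cleared = cel$thresholds$th_cleared$threshold
    )
  }
  if (length(rows) == 0) abort("No manifest row could be processed.")
  results <- dplyr::bind_rows(rows)
  if (config$blind) {
    results <- blind_image_ids(results, config$seed)
  }
  record <- list(
    package_version = as.character(utils::packageVersion("fibercount")),
    config = list(
      pixels_per_um = config$scale$pixels_per_um,
      min_fiber_area_px = config$fiber$min_fiber_area_px,
      min_cell_area_px = config$cell$min_cell_area_px,
      th_fiber_method = config$fiber$th_method,
      peripherin_in_roi_method = config$fiber$peripherin_method,
      peripherin_cell_method = config$cell$peripherin_method,
      th_cell_method = config$cell$th_method,
      blind = config$blind, seed = config$seed
    ),
    n_images = nrow(results),
    failed = manifest$image_id[missing]
  )
  out <- structure(list(results = results, count_results = details,
                        run_record = record),
                   failed = manifest$image_id[missing],
                   class = "batch_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(results, file.path(out_dir, "results.csv"), row.names = FALSE)
    jsonlite::write_json(record, file.path(out_dir, "run_record.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    jsonlite::write_json(batch_summary(out),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

blind_image_ids <- function(results, seed) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  perm <- sample(nrow(results))
  results$blinded_id <- sprintf("blind%03d", order(perm))
  results
}

#' Summarize a batch run
#'
#' Group means/sds of fiber and cell densities (by genotype when present)
#' and, when exactly two genotypes exist, the two-sided t-test between
#' them; when manual counts are present, the full method comparison.
#'
#' @param batch A `batch_result` from [run_batch()].
#' @return A list of tidy summaries.
#' @export
batch_summary <- function(batch) {
  stopifnot(inherits(batch, "batch_result"))
  res <- batch$results
  out <- list(n_images = nrow(res))
  if (!all(is.na(res$genotype))) {
    out$by_genotype <- res |>
      dplyr::group_by(.data$genotype) |>
      dplyr::summarise(
        n = dplyr::n(),
        fiber_density_mean = mean(.data$fiber_density_per_mm2),
        fiber_density_sd = sd(.data$fiber_density_per_mm2),
        cell_density_mean = mean(.data$cell_density_per_mm2),
        cell_density_sd = sd(.data$cell_density_per_mm2),
        .groups = "drop")
    gts <- unique(res$genotype)
    if (length(gts) == 2 && all(table(res$genotype) >= 2)) {
      a <- res$fiber_density_per_mm2[res$genotype == gts[1]]
      b <- res$fiber_density_per_mm2[res$genotype == gts[2]]
      out$fiber_density_t_test <- two_sided_t_test(a, b)
      a <- res$cell_density_per_mm2[res$genotype == gts[1]]
      b <- res$cell_density_per_mm2[res$genotype == gts[2]]
      out$cell_density_t_test <- two_sided_t_test(a, b)
    }
  }
  if (any(!is.na(res$manual_count))) {
    paired <- dplyr::filter(res, !is.na(.data$manual_count))
    if (nrow(paired) >= 3) {
      out$method_comparison <-
        glance(compare_methods(paired, "manual_count", "fiber_count"))
    }
  }
  out
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("<batch_result: %d images processed, %d failed>\n",
              nrow(x$results), length(attr(x, "failed"))))
  invisible(x)
}
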