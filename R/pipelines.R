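#' Configuration for the fiber-counting pipeline
#'
#' Defaults mirror the original ImageJ macro workflow: Otsu threshold on the TH
#' channel to build the TH-positive ROI, intermeans ("default") threshold
#' on the ROI-restricted peripherin histogram, and a 23 px minimum particle
#' area (8 um at 2.828 px/um).
#'
#' @param min_fiber_area_px Minimum double-positive particle area (>= 1).
#' @param th_method Threshold method for the TH ROI stage.
#' @param peripherin_method Threshold method for peripherin within the ROI.
#' @param scale A [pixel_scale()].
#' @param restrict_histogram If `TRUE` (default) the peripherin threshold is
#'   computed on the histogram of ROI pixels only, matching the macro's
#'   copy-selection-to-new-image semantics; `FALSE` uses the whole-image
#'   histogram.
#' @return A `fiber_count_config`.
#' @export
fiber_count_config <- function(min_fiber_area_px = 23,
                               th_method = "otsu",
                               peripherin_method = "intermeans",
                               scale = pixel_scale(),
                               restrict_histogram = TRUE) {
  if (min_fiber_area_px < 1) abort("`min_fiber_area_px` must be >= 1.")
  structure(list(min_fiber_area_px = as.integer(min_fiber_area_px),
                 th_method = th_method,
                 peripherin_method = peripherin_method,
                 scale = as_pixel_scale(scale),
                 restrict_histogram = isTRUE(restrict_histogram)),
            class = "fiber_count_config")
}

#' Configuration for the TH-single-positive cell pipeline
#'
#' Both stages default to the triangle threshold, as in the macros. The
#' minimum cell area has no documented reference value; the default of
#' 23 px keeps symmetry with the fiber filter and must be treated as a
#' tunable, not a reproduced constant.
#'
#' @param min_cell_area_px Minimum cell particle area (>= 1).
#' @param peripherin_method Threshold method for the peripherin ROI.
#' @param th_method Threshold method for the cleared TH image.
#' @param scale A [pixel_scale()].
#' @param exclude_cleared If `FALSE` (default) pixels cleared to 0 stay in
#'   the threshold histogram, faithful to the macro's clear-then-threshold
#'   order; `TRUE` drops them (statistically cleaner alternative).
#' @return A `cell_count_config`.
#' @export
cell_count_config <- function(min_cell_area_px = 23,
                              peripherin_method = "triangle",
                              th_method = "triangle",
                              scale = pixel_scale(),
                              exclude_cleared = FALSE) {
  if (min_cell_area_px < 1) abort("`min_cell_area_px` must be >= 1.")
  structure(list(min_cell_area_px = as.integer(min_cell_area_px),
                 peripherin_method = peripherin_method,
                 th_method = th_method,
                 scale = as_pixel_scale(scale),
                 exclude_cleared = isTRUE(exclude_cleared)),
            class = "cell_count_config")
}

#' TH-positive region of interest
#'
#' First macro stage: auto-threshold the TH channel (Otsu by default) and
#' return the above-threshold selection as a mask. A degenerate histogram
#' (e.g. a blank image) is flagged on the mask, not treated as an error.
#'
#' @param th_image TH-channel [channel_image()].
#' @param method Threshold method name.
#' @return A [binary_mask()].
#' @export
th_positive_roi <- function(th_image, method = "otsu") {
  stopifnot(is_channel_image(th_image))
  apply_threshold(th_image, auto_threshold(histogram256(th_image), method))
}

#' Peripherin-positive region of interest
#'
#' Triangle-threshold the peripherin channel; the resulting selection marks
#' all nerve-fiber area (peripherin is expressed exclusively in peripheral
#' nerve fibers) and is used to clear fibers before cell counting.
#'
#' @param peripherin_image Peripherin-channel [channel_image()].
#' @param method Threshold method name.
#' @return A [binary_mask()].
#' @export
peripherin_positive_roi <- function(peripherin_image, method = "triangle") {
  stopifnot(is_channel_image(peripherin_image))
  apply_threshold(peripherin_image,
                  auto_threshold(histogram256(peripherin_image), method))
}

count_result <- function(kind, particles, thresholds, masks, image, scale) {
  area <- image_area_mm2(image_width(image), image_height(image), scale)
  n <- nrow(particles)
  structure(list(kind = kind,
                 count = n,
                 density_per_mm2 = n / area,
                 image_area_mm2 = area,
                 thresholds = thresholds,
                 particles = particles,
                 masks = masks),
            class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("<count_result [%s]: %d particles, %.2f /mm2 over %.4f mm2>\n",
              x$kind, x$count, x$density_per_mm2, x$image_area_mm2))
  for (nm in names(x$thresholds)) {
    t <- x$thresholds[[nm]]
    cat(sprintf("  threshold %s: t=%d [%s]%s\n", nm, t$threshold, t$method,
                if (t$degenerate) " (degenerate)" else ""))
  }
  invisible(x)
}

#' Count TH/peripherin double-positive fibers
#'
#' The full fiber chain: build the TH-positive ROI, place it on the
#' peripherin channel, auto-threshold the peripherin intensities within the
#' ROI (intermeans by default, on the ROI-restricted histogram), extract
#' 8-connected particles, keep those of at least `min_fiber_area_px`
#' pixels, and report the count and density over the full image area.
#' Every counted particle lies entirely inside the TH ROI by construction,
#' so counted particles are TH/peripherin double-positive.
#'
#' @param th_image,peripherin_image Paired [channel_image()]s of identical
#'   dimensions.
#' @param config A [fiber_count_config()].
#' @return A `count_result`: count, density per mm^2, image area, the two
#'   stage thresholds, the filtered particle table and intermediate masks.
#' @examples
#' spec <- synthetic_spec(width_px = 400, height_px = 300,
#'                        n_fibers = 3, n_cells = 4, seed = 7)
#' pair <- generate_pair(spec)
#' count_fibers(pair$th, pair$peripherin)
#' @export
count_fibers <- function(th_image, peripherin_image,
                         config = fiber_count_config()) {
  stopifnot(is_channel_image(th_image), is_channel_image(peripherin_image),
            inherits(config, "fiber_count_config"))
  if (!identical(dim(th_image), dim(peripherin_image))) {
    abort("TH and peripherin images must have identical dimensions.")
  }
  roi <- th_positive_roi(th_image, config$th_method)
  if (!any(roi)) {
    warn("TH ROI is empty; fiber count is 0.")
    t_na <- threshold_result(attr(roi, "threshold"), attr(roi, "method"),
                             degenerate = TRUE)
    empty <- particle_table(matrix(0L, nrow(roi), ncol(roi)), roi)
    return(count_result("fibers", empty,
                        list(th = t_na, peripherin = t_na),
                        list(th_roi = roi), th_image, config$scale))
  }
  hist_p <- if (config$restrict_histogram) {
    histogram256(peripherin_image, restrict_to = roi)
  } else {
    histogram256(peripherin_image)
  }
  t_p <- auto_threshold(hist_p, config$peripherin_method)
  peri_mask <- apply_threshold(peripherin_image, t_p)
  dp <- binary_mask(unclass(peri_mask) & unclass(roi),
                    threshold = t_p$threshold, method = t_p$method,
                    degenerate = t_p$degenerate)
  particles <- filter_by_size(label_components(dp), config$min_fiber_area_px)
  t_th <- threshold_result(attr(roi, "threshold"), attr(roi, "method"),
                           attr(roi, "degenerate"))
  count_result("fibers", particles,
               list(th = t_th, peripherin = t_p),
               list(th_roi = roi, double_positive = dp),
               th_image, config$scale)
}

#' Count TH-single-positive cells
#'
#' The cell chain: build the peripherin-positive ROI, clear those pixels
#' (set to 0) in a copy of the TH channel, triangle-threshold the cleared
#' image, extract 8-connected particles and keep those of at least
#' `min_cell_area_px` pixels. What remains after clearing is TH signal
#' without peripherin — catecholamine-producing cells rather than fibers —
#' so no reported particle overlaps the peripherin mask.
#'
#' @param th_image,peripherin_image Paired [channel_image()]s of identical
#'   dimensions.
#' @param config A [cell_count_config()].
#' @return A `count_result` (see [count_fibers()]).
#' @export
count_cells <- function(th_image, peripherin_image,
                        config = cell_count_config()) {
  stopifnot(is_channel_image(th_image), is_channel_image(peripherin_image),
            inherits(config, "cell_count_config"))
  if (!identical(dim(th_image), dim(peripherin_image))) {
    abort("TH and peripherin images must have identical dimensions.")
  }
  proi <- peripherin_positive_roi(peripherin_image, config$peripherin_method)
  cleared <- unclass(th_image)
  cleared[unclass(proi)] <- 0L
  attributes(cleared) <- list(dim = dim(th_image))
  cleared_img <- new_channel_image(cleared, attr(th_image, "scale"),
                                   attr(th_image, "channel"))
  hist_c <- if (config$exclude_cleared && any(!proi)) {
    histogram256(cleared_img,
                 restrict_to = binary_mask(!unclass(proi), method = "complement"))
  } else {
    histogram256(cleared_img)
  }
  t_c <- auto_threshold(hist_c, config$th_method)
  cell_mask <- apply_threshold(cleared_img, t_c)
  # cleared pixels are 0 and the threshold is >= 0, so the ROI is excluded;
  # enforce anyway so degenerate thresholds cannot leak fibers back in
  cm <- unclass(cell_mask) & !unclass(proi)
  attributes(cm) <- list(dim = dim(cell_mask))
  cell_mask <- binary_mask(cm, threshold = t_c$threshold,
                           method = t_c$method, degenerate = t_c$degenerate)
  particles <- filter_by_size(label_components(cell_mask),
                              config$min_cell_area_px)
  t_p <- threshold_result(attr(proi, "threshold"), attr(proi, "method"),
                          attr(proi, "degenerate"))
  count_result("cells", particles,
               list(peripherin = t_p, th_cleared = t_c),
               list(peripherin_roi = proi, cells = cell_mask),
               th_image, config$scale)
}
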