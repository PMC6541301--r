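#' Pixel scale metadata
#'
#' Records the lateral sampling of the microscope images in pixels per
#' micrometer. The default of 2.828 px/um corresponds to the 400x
#' magnification setup the counting workflow was designed for, under which a
#' 1600 x 1200 px field covers 0.24 mm^2.
#'
#' @param pixels_per_um Pixels per micrometer; must be strictly positive.
#' @return A `pixel_scale` object.
#' @examples
#' pixel_scale()
#' image_area_mm2(1600, 1200, pixel_scale(2.828))
#' @export
pixel_scale <- function(pixels_per_um = 2.828) {
  if (!is.numeric(pixels_per_um) || length(pixels_per_um) != 1 ||
      !is.finite(pixels_per_um) || pixels_per_um <= 0) {
    abort("`pixels_per_um` must be a single positive number.")
  }
  structure(list(pixels_per_um = as.numeric(pixels_per_um)),
            class = "pixel_scale")
}

#' @export
print.pixel_scale <- function(x, ...) {
  cat(sprintf("<pixel_scale: %.4g px/um (%.4g um/px)>\n",
              x$pixels_per_um, 1 / x$pixels_per_um))
  invisible(x)
}

# Internal fast path: `px` must already be a valid integer matrix in [0,255].
new_channel_image <- function(px, scale, channel) {
  structure(px, scale = scale, channel = channel,
            class = c("channel_image", "matrix", "array"))
}

as_pixel_scale <- function(scale) {
  if (inherits(scale, "pixel_scale")) return(scale)
  pixel_scale(scale)
}

#' Field of view area in square millimetres
#'
#' @param width_px,height_px Image dimensions in pixels.
#' @param scale A [pixel_scale()] (or bare pixels-per-um number).
#' @return Area in mm^2: `width_px * height_px / (pixels_per_um^2 * 1e6)`.
#' @export
image_area_mm2 <- function(width_px, height_px, scale = pixel_scale()) {
  scale <- as_pixel_scale(scale)
  if (width_px < 1 || height_px < 1) {
    abort("Image dimensions must be at least 1 pixel.")
  }
  (width_px * height_px) / (scale$pixels_per_um^2 * 1e6)
}

#' Construct a single fluorescence channel image
#'
#' A `channel_image` is an integer matrix of 8-bit intensities (0-255),
#' stored with rows as image rows (y) and columns as image columns (x),
#' carrying its pixel scale and channel label as attributes.
#'
#' @param pixels Numeric or integer matrix with all values in \[0, 255\].
#' @param scale A [pixel_scale()].
#' @param channel Channel label, one of `"TH"`, `"peripherin"`, `"DAPI"`,
#'   `"other"`.
#' @return A `channel_image`.
#' @export
channel_image <- function(pixels, scale = pixel_scale(), channel = "other") {
  if (!is.matrix(pixels)) abort("`pixels` must be a matrix.")
  if (nrow(pixels) < 1 || ncol(pixels) < 1) {
    abort("Image must be at least 1 x 1.")
  }
  channel <- match.arg(channel, c("TH", "peripherin", "DAPI", "other"))
  px <- as.integer(round(pixels))
  if (anyNA(px) || any(px < 0L) || any(px > 255L)) {
    abort("All intensities must lie in [0, 255].")
  }
  structure(matrix(px, nrow(pixels), ncol(pixels)),
            scale = as_pixel_scale(scale),
            channel = channel,
            class = c("channel_image", "matrix", "array"))
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image [%s]: %d x %d px, %.4g px/um, range %d-%d>\n",
              attr(x, "channel"), ncol(x), nrow(x),
              attr(x, "scale")$pixels_per_um, min(x), max(x)))
  invisible(x)
}

#' @rdname channel_image
#' @param x Object to test.
#' @export
is_channel_image <- function(x) inherits(x, "channel_image")

image_width <- function(image) ncol(image)
image_height <- function(image) nrow(image)

#' Convert an RGB image to an 8-bit grayscale channel
#'
#' Follows the unweighted ImageJ-style conversion: each pixel becomes the
#' plain mean of its R, G and B values, rounded half-up and clipped to
#' \[0, 255\]. Already-gray triples are mapped to themselves.
#'
#' @param rgb A height x width x 3 array of 8-bit values (0-255).
#' @param scale,channel Passed to [channel_image()].
#' @return A `channel_image`.
#' @export
to_grayscale_8bit <- function(rgb, scale = pixel_scale(), channel = "other") {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] < 3) {
    abort("`rgb` must be a height x width x 3 array.")
  }
  m <- (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
  gray <- pmin(pmax(floor(m + 0.5), 0), 255)  # round half-up
  channel_image(matrix(gray, dim(rgb)[1], dim(rgb)[2]),
                scale = scale, channel = channel)
}

#' Read a fluorescence channel from a TIFF or PNG file
#'
#' Accepts 8-bit grayscale or RGB images; RGB inputs are collapsed through
#' [to_grayscale_8bit()]. The pixel scale is attached from the `scale`
#' argument (TIFF resolution tags are deliberately ignored: macro-era
#' exports rarely carry them reliably).
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param channel Channel label (see [channel_image()]).
#' @param scale A [pixel_scale()].
#' @return A `channel_image`.
#' @export
read_channel <- function(path, channel = "other", scale = pixel_scale()) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    abort(paste0("Unsupported image format: .", ext, " (use TIFF or PNG)"))
  )
  vals <- round(raw * 255)
  nd <- length(dim(vals))
  if (nd == 2 || is.null(dim(vals))) {
    channel_image(as.matrix(vals), scale = scale, channel = channel)
  } else if (nd == 3 && dim(vals)[3] >= 3) {
    to_grayscale_8bit(vals[, , 1:3, drop = FALSE],
                      scale = scale, channel = channel)
  } else if (nd == 3 && dim(vals)[3] == 1) {
    channel_image(vals[, , 1], scale = scale, channel = channel)
  } else {
    abort("Unsupported image layout: expected grayscale or RGB.")
  }
}

#' Write a channel image as an 8-bit grayscale TIFF
#'
#' @param image A [channel_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_channel <- function(image, path) {
  stopifnot(is_channel_image(image))
  m <- unclass(image)
  attributes(m) <- list(dim = dim(m))
  tiff::writeTIFF(m / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Binary masks: the package's representation of an ImageJ selection
#'
#' A `binary_mask` is a logical matrix marking above-threshold pixels under
#' the bright-object convention (`intensity > threshold`). It carries the
#' threshold and method that produced it, plus a degenerate flag set when
#' the threshold came from a single-populated-bin histogram.
#'
#' @param pixels Logical matrix.
#' @param threshold Integer threshold in \[0, 255\] that produced the mask
#'   (`NA` for hand-built masks).
#' @param method Threshold method identifier.
#' @param degenerate Logical; was the underlying histogram degenerate?
#' @return A `binary_mask`.
#' @export
binary_mask <- function(pixels, threshold = NA_integer_, method = "manual",
                        degenerate = FALSE) {
  if (!is.matrix(pixels) || !is.logical(pixels)) {
    abort("`pixels` must be a logical matrix.")
  }
  if (!is.na(threshold) && (threshold < 0 || threshold > 255)) {
    abort("`threshold` must lie in [0, 255].")
  }
  structure(pixels,
            threshold = as.integer(threshold), method = method,
            degenerate = isTRUE(degenerate),
            class = c("binary_mask", "matrix", "array"))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask: %d x %d px, %d foreground (%.2f%%), t=%s [%s]%s>\n",
              ncol(x), nrow(x), sum(x), 100 * mean(x),
              attr(x, "threshold"), attr(x, "method"),
              if (isTRUE(attr(x, "degenerate"))) ", degenerate" else ""))
  invisible(x)
}

#' @rdname binary_mask
#' @param x Object to test.
#' @export
is_binary_mask <- function(x) inherits(x, "binary_mask")

#' Write and read binary masks as 8-bit TIFFs
#'
#' Masks are persisted with background 0 and foreground 255 and round-trip
#' losslessly. Threshold provenance is not stored in the file.
#'
#' @param mask A [binary_mask()].
#' @param path File path.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` returns a
#'   `binary_mask` (with `method = "file"`).
#' @export
write_mask <- function(mask, path) {
  stopifnot(is_binary_mask(mask))
  m <- unclass(mask)
  attributes(m) <- list(dim = dim(m))
  tiff::writeTIFF(m * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- tiff::readTIFF(path)
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  binary_mask(round(raw * 255) > 0, method = "file")
}
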