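#' 256-bin intensity histogram
#'
#' Tabulates 8-bit intensities over the whole image or, when `restrict_to`
#' is supplied, over the masked pixels only (the in-ROI histogram used when
#' thresholding a channel inside a previously built selection).
#'
#' @param image A [channel_image()].
#' @param restrict_to Optional [binary_mask()] of matching dimensions with
#'   at least one foreground pixel.
#' @return A `histogram256`: list with `counts` (integer vector of length
#'   256, bin i holds the count of intensity i-1) and `total`.
#' @export
histogram256 <- function(image, restrict_to = NULL) {
  stopifnot(is_channel_image(image))
  px <- as.integer(image)
  if (!is.null(restrict_to)) {
    if (!identical(dim(restrict_to), dim(image))) {
      abort("`restrict_to` dimensions must match the image.")
    }
    keep <- as.logical(restrict_to)
    if (!any(keep)) abort("`restrict_to` selects no pixels (empty ROI).")
    px <- px[keep]
  }
  counts <- tabulate(px + 1L, nbins = 256L)
  structure(list(counts = counts, total = sum(counts)),
            class = "histogram256")
}

#' @export
print.histogram256 <- function(x, ...) {
  nz <- which(x$counts > 0L)
  cat(sprintf("<histogram256: %d pixels, %d populated bins, range %d-%d>\n",
              x$total, length(nz), min(nz) - 1L, max(nz) - 1L))
  invisible(x)
}

threshold_result <- function(threshold, method, degenerate = FALSE) {
  structure(list(threshold = as.integer(threshold), method = method,
                 degenerate = isTRUE(degenerate)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result: t=%d [%s]%s>\n", x$threshold, x$method,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

check_hist <- function(hist) {
  if (!inherits(hist, "histogram256")) abort("Expected a `histogram256`.")
  if (hist$total < 1) abort("Histogram is empty; cannot threshold.")
  which(hist$counts > 0L) - 1L  # populated intensity levels
}

#' Otsu automatic threshold
#'
#' Selects the threshold t maximizing the between-class variance
#' w0(t) w1(t) (mu0(t) - mu1(t))^2, where class 0 collects bins <= t and
#' class 1 the bins > t. Ties are broken by the smallest maximizing t. A
#' histogram with a single populated bin returns that bin with the
#' degenerate flag set.
#'
#' @param hist A [histogram256()].
#' @return A `threshold_result` with `method = "otsu"`.
#' @export
threshold_otsu <- function(hist) {
  pop <- check_hist(hist)
  if (length(pop) == 1L) {
    return(threshold_result(pop, "otsu", degenerate = TRUE))
  }
  counts <- as.numeric(hist$counts)
  lev <- 0:255
  w0 <- cumsum(counts)                       # pixels in class <= t
  s0 <- cumsum(counts * lev)                 # intensity sum in class <= t
  w1 <- hist$total - w0
  s1 <- s0[256] - s0
  valid <- w0 > 0 & w1 > 0                   # both classes populated
  bcv <- rep(-Inf, 256)
  bcv[valid] <- w0[valid] * w1[valid] *
    (s0[valid] / w0[valid] - s1[valid] / w1[valid])^2
  threshold_result(which.max(bcv) - 1L, "otsu")
}

#' Triangle automatic threshold
#'
#' Geometric triangle method: a line is drawn from the histogram peak to
#' the farthest non-empty tail endpoint, and the threshold is the bin with
#' the maximum perpendicular distance to that line. When the peak lies
#' nearer the high-intensity end, the histogram is mirrored first, the
#' threshold computed, and mapped back (t = 255 - t').
#'
#' @param hist A [histogram256()].
#' @return A `threshold_result` with `method = "triangle"`.
#' @export
threshold_triangle <- function(hist) {
  pop <- check_hist(hist)
  if (length(pop) == 1L) {
    return(threshold_result(pop, "triangle", degenerate = TRUE))
  }
  counts <- as.numeric(hist$counts)
  peak <- which.max(counts) - 1L
  lo <- pop[1]; hi <- pop[length(pop)]
  mirrored <- (peak - lo) > (hi - peak)      # peak nearer high end
  if (mirrored) {
    counts <- rev(counts)
    peak <- 255L - peak
    hi <- 255L - lo
  }
  t <- triangle_core(counts, peak, hi)
  if (mirrored) t <- 255L - t
  threshold_result(t, "triangle")
}

# Max perpendicular distance from the chord (peak, h[peak]) -- (end, h[end]),
# searched over the bins between peak and end; peak is left of end here.
triangle_core <- function(counts, peak, end) {
  if (end <= peak) return(peak)
  x1 <- peak; y1 <- counts[peak + 1L]
  x2 <- end;  y2 <- counts[end + 1L]
  xs <- peak:end
  ys <- counts[xs + 1L]
  # |cross product| / chord length; chord length constant, omit it
  d <- abs((y2 - y1) * xs - (x2 - x1) * ys + x2 * y1 - y2 * x1)
  xs[which.max(d)]
}

#' Iterative intermeans ("default") automatic threshold
#'
#' The IsoData-family rule behind the ImageJ "Default" auto-threshold tool:
#' starting from the midpoint of the populated intensity range, iterate
#' t <- round((mean of bins <= t + mean of bins > t) / 2) until a fixed
#' point is reached. Rounding is half-up; the iteration is capped at 256
#' steps (it terminates long before in practice).
#'
#' @param hist A [histogram256()].
#' @return A `threshold_result` with `method = "intermeans"`.
#' @export
threshold_intermeans <- function(hist) {
  pop <- check_hist(hist)
  if (length(pop) == 1L) {
    return(threshold_result(pop, "intermeans", degenerate = TRUE))
  }
  counts <- as.numeric(hist$counts)
  lev <- 0:255
  cw <- cumsum(counts)
  cs <- cumsum(counts * lev)
  lo <- pop[1]; hi <- pop[length(pop)]
  t <- (lo + hi) %/% 2L                      # midpoint start, both classes live
  for (iter in 1:256) {
    i <- t + 1L
    mu_lo <- cs[i] / cw[i]
    mu_hi <- (cs[256] - cs[i]) / (cw[256] - cw[i])
    t_new <- floor((mu_lo + mu_hi) / 2 + 0.5)
    t_new <- min(max(t_new, lo), hi - 1L)    # keep both classes populated
    if (t_new == t) return(threshold_result(t, "intermeans"))
    t <- t_new
  }
  abort("Intermeans iteration failed to converge within 256 steps.")
}

#' Select an auto-threshold method by name
#'
#' Dispatches to [threshold_otsu()], [threshold_triangle()] or
#' [threshold_intermeans()]; `"default"` is accepted as an alias for the
#' intermeans method, matching the ImageJ tool name.
#'
#' @param hist A [histogram256()].
#' @param method One of `"otsu"`, `"triangle"`, `"intermeans"`, `"default"`.
#' @return A `threshold_result`.
#' @export
auto_threshold <- function(hist, method = c("otsu", "triangle",
                                            "intermeans", "default")) {
  method <- match.arg(method)
  switch(method,
    otsu = threshold_otsu(hist),
    triangle = threshold_triangle(hist),
    intermeans = , default = threshold_intermeans(hist)
  )
}

#' Apply a threshold to an image
#'
#' Produces the selection of bright objects: pixels strictly above the
#' threshold are foreground.
#'
#' @param image A [channel_image()].
#' @param t A `threshold_result` (or a bare integer in \[0, 255\]).
#' @return A [binary_mask()].
#' @export
apply_threshold <- function(image, t) {
  stopifnot(is_channel_image(image))
  if (is.numeric(t)) t <- threshold_result(t, "manual")
  m <- unclass(image) > t$threshold
  attributes(m) <- list(dim = dim(image))
  binary_mask(m, threshold = t$threshold, method = t$method,
              degenerate = t$degenerate)
}
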