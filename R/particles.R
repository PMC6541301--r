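#' Label 8-connected components of a binary mask
#'
#' The analyze-particles stage: connected components are extracted under
#' 8-connectivity (diagonally touching pixels join), labelled in row-major
#' first-pixel order, and measured. Coordinates are pixel-centre based with
#' x along image columns and y along rows, both 1-based.
#'
#' The maximum caliper (Feret) diameter is the largest pairwise distance
#' between pixel centres of a particle, computed over the convex hull.
#'
#' @param mask A [binary_mask()].
#' @return A `particle_table`: a tibble with one row per particle
#'   (`particle`, `area_px`, `centroid_x`, `centroid_y`, `min_x`, `min_y`,
#'   `max_x`, `max_y`, `caliper_px`), carrying the label matrix as
#'   attribute `"labels"` and the mask dimensions as `"mask_dim"`.
#' @export
label_components <- function(mask) {
  stopifnot(is_binary_mask(mask))
  m <- unclass(mask)
  attributes(m) <- list(dim = dim(m))
  lab <- EBImage::bwlabel(m * 1)
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  lab <- merge_diagonal_labels(lab)
  lab <- relabel_row_major(lab)
  particle_table(lab, mask)
}

# bwlabel is 4-connected; union labels that touch only diagonally.
merge_diagonal_labels <- function(lab) {
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- as.vector(lab[-nr, -nc]); b <- as.vector(lab[-1, -1])   # down-right
  c_ <- as.vector(lab[-1, -nc]); d <- as.vector(lab[-nr, -1])   # up-right
  k1 <- a > 0L & b > 0L & a != b
  k2 <- c_ > 0L & d > 0L & c_ != d
  pairs <- rbind(cbind(a[k1], b[k1]), cbind(c_[k2], d[k2]))
  if (nrow(pairs) == 0L) return(lab)
  pairs <- unique(pairs)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  lab[lab > 0L] <- root[lab[lab > 0L]]
  lab
}

# Renumber labels 1..k by first occurrence scanning rows top-to-bottom,
# then columns left-to-right (ImageJ raster order).
relabel_row_major <- function(lab) {
  if (max(lab) == 0L) return(lab)
  rm_order <- as.vector(t(lab))            # row-major traversal
  firsts <- rm_order[rm_order > 0L]
  old <- unique(firsts)
  new <- integer(max(lab))
  new[old] <- seq_along(old)
  lab[lab > 0L] <- new[lab[lab > 0L]]
  lab
}

particle_table <- function(lab, mask) {
  k <- max(lab)
  if (k == 0L) {
    tbl <- tibble::tibble(
      particle = integer(), area_px = integer(),
      centroid_x = numeric(), centroid_y = numeric(),
      min_x = integer(), min_y = integer(),
      max_x = integer(), max_y = integer(),
      caliper_px = numeric()
    )
  } else {
    idx <- which(lab > 0L)
    lv <- lab[idx]
    ys <- ((idx - 1L) %% nrow(lab)) + 1L
    xs <- ((idx - 1L) %/% nrow(lab)) + 1L
    ord <- order(lv)
    lv <- lv[ord]; xs <- xs[ord]; ys <- ys[ord]
    grp <- split(seq_along(lv), lv)
    tbl <- tibble::tibble(
      particle = seq_len(k),
      area_px = vapply(grp, length, integer(1), USE.NAMES = FALSE),
      centroid_x = vapply(grp, function(i) mean(xs[i]), numeric(1), USE.NAMES = FALSE),
      centroid_y = vapply(grp, function(i) mean(ys[i]), numeric(1), USE.NAMES = FALSE),
      min_x = vapply(grp, function(i) min(xs[i]), integer(1), USE.NAMES = FALSE),
      min_y = vapply(grp, function(i) min(ys[i]), integer(1), USE.NAMES = FALSE),
      max_x = vapply(grp, function(i) max(xs[i]), integer(1), USE.NAMES = FALSE),
      max_y = vapply(grp, function(i) max(ys[i]), integer(1), USE.NAMES = FALSE),
      caliper_px = vapply(grp, function(i) max_caliper(xs[i], ys[i]),
                          numeric(1), USE.NAMES = FALSE)
    )
  }
  structure(tbl,
            labels = lab, mask_dim = dim(lab),
            threshold = attr(mask, "threshold"),
            method = attr(mask, "method"),
            class = c("particle_table", class(tbl)))
}

# Largest pairwise pixel-centre distance, convex-hull accelerated.
max_caliper <- function(xs, ys) {
  n <- length(xs)
  if (n == 1L) return(0)
  pts <- cbind(xs, ys)
  if (n > 3L) {
    h <- tryCatch(chull(pts), error = function(e) seq_len(n))
    pts <- pts[h, , drop = FALSE]
  }
  sqrt(max(dist(pts)^2))
}

#' @export
print.particle_table <- function(x, ...) {
  cat(sprintf("<particle_table: %d particles, %d foreground px>\n",
              nrow(x), sum(x$area_px)))
  NextMethod()
}

keep_particles <- function(table, keep) {
  lab <- attr(table, "labels")
  kept_ids <- table$particle[keep]
  if (length(kept_ids) < nrow(table)) {
    fg <- lab > 0L
    map <- integer(max(lab, 1L))
    map[kept_ids] <- kept_ids
    lab[fg] <- map[lab[fg]]
  }
  out <- table[keep, , drop = FALSE]
  attr(out, "labels") <- lab
  attr(out, "mask_dim") <- attr(table, "mask_dim")
  attr(out, "threshold") <- attr(table, "threshold")
  attr(out, "method") <- attr(table, "method")
  class(out) <- class(table)
  out
}

#' Filter particles by minimum area
#'
#' The analyze-particles "Size" filter: particles with `area_px >=
#' min_area_px` are kept. The default fiber criterion is 23 px (8 um, the
#' average diameter of peripheral nerve fibers, at 2.828 px/um).
#'
#' @param table A `particle_table` from [label_components()].
#' @param min_area_px Minimum pixel area; must be >= 0.
#' @return The filtered `particle_table` (label matrix updated to match).
#' @export
filter_by_size <- function(table, min_area_px = 23) {
  stopifnot(inherits(table, "particle_table"))
  if (!is.numeric(min_area_px) || length(min_area_px) != 1 ||
      is.na(min_area_px) || min_area_px < 0) {
    abort("`min_area_px` must be a single non-negative number.")
  }
  keep_particles(table, table$area_px >= min_area_px)
}

#' Emulate the manual length criterion
#'
#' The manual counting protocol only admits oblong objects at least 50 um
#' long. For method-comparison experiments this is emulated in software by
#' keeping particles whose maximum caliper reaches `min_length_um`
#' micrometers (141.4 px at the default 50 um and 2.828 px/um).
#'
#' @param table A `particle_table`.
#' @param min_length_um Minimum length in micrometers (> 0).
#' @param scale A [pixel_scale()].
#' @return The filtered `particle_table`.
#' @export
filter_manual_criterion <- function(table, min_length_um = 50,
                                    scale = pixel_scale()) {
  stopifnot(inherits(table, "particle_table"))
  if (min_length_um <= 0) abort("`min_length_um` must be positive.")
  scale <- as_pixel_scale(scale)
  keep_particles(table, table$caliper_px >= min_length_um * scale$pixels_per_um)
}

#' Export a particle table as CSV with micrometer-scaled measurements
#'
#' @param table A `particle_table`.
#' @param path Output CSV path.
#' @param scale A [pixel_scale()] used to add `area_um2` and `caliper_um`.
#' @return The exported tibble, invisibly.
#' @export
write_particles <- function(table, path, scale = pixel_scale()) {
  stopifnot(inherits(table, "particle_table"))
  scale <- as_pixel_scale(scale)
  ppu <- scale$pixels_per_um
  out <- dplyr::mutate(tibble::as_tibble(table),
                       area_um2 = .data$area_px / ppu^2,
                       caliper_um = .data$caliper_px / ppu)
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}
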