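#' Specification for synthetic two-channel fluorescence images
#'
#' Describes a simulated microscope field with planted structures and known
#' ground truth: curvilinear double-positive fibers (bright in both the TH
#' and peripherin channels), round TH-only cells, and Gaussian background
#' noise. Defaults emulate the nominal acquisition geometry (1600 x 1200 px
#' at 2.828 px/um) with 8-bit contrast typical of well-exposed
#' immunofluorescence: background ~N(20, 8), foreground ~N(200, 12).
#'
#' @param width_px,height_px Image dimensions in pixels.
#' @param n_fibers,n_cells Number of planted fibers (double-positive) and
#'   cells (TH-only).
#' @param fiber_length_um Length range of fiber centrelines, micrometers.
#' @param fiber_width_px Stroke width range of fibers, pixels.
#' @param fiber_tortuosity Standard deviation (radians) of the per-step
#'   heading jitter of the fiber random walk; 0 gives straight fibers.
#' @param cell_diameter_um Diameter range of cell disks, micrometers.
#' @param fg_mean,fg_sd Foreground intensity model (per structure pixel).
#' @param bg_mean,bg_sd Background intensity model.
#' @param bleedthrough Fraction of a structure's signal leaking into the
#'   channel it is negative in (spectral bleed-through).
#' @param separation_px Minimum Chebyshev gap enforced between planted
#'   structures; 0 disables separation.
#' @param lateral_fibers Number of additional small, near-round
#'   double-positive blobs emulating laterally sectioned fibers (counted in
#'   `n_fibers`' truth set when > 0 they are appended as extra fibers).
#' @param peripherin_only_fibers Number of planted peripherin-only fibers
#'   (non-sympathetic); these must NOT be counted by either pipeline.
#' @param scale A [pixel_scale()].
#' @param seed Integer RNG seed; the same spec always renders identical
#'   images.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(width_px = 1600, height_px = 1200,
                           n_fibers = 5, n_cells = 10,
                           fiber_length_um = c(20, 120),
                           fiber_width_px = c(2, 6),
                           fiber_tortuosity = 0.25,
                           cell_diameter_um = c(5, 15),
                           fg_mean = 200, fg_sd = 12,
                           bg_mean = 20, bg_sd = 8,
                           bleedthrough = 0.02,
                           separation_px = 6,
                           lateral_fibers = 0,
                           peripherin_only_fibers = 0,
                           scale = pixel_scale(),
                           seed = 1L) {
  stopifnot(width_px >= 16, height_px >= 16,
            n_fibers >= 0, n_cells >= 0,
            lateral_fibers >= 0, peripherin_only_fibers >= 0,
            fg_mean >= 0, fg_mean <= 255, bg_mean >= 0, bg_mean <= 255,
            fg_sd >= 0, bg_sd >= 0, bleedthrough >= 0, bleedthrough <= 1)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 n_fibers = as.integer(n_fibers),
                 n_cells = as.integer(n_cells),
                 fiber_length_um = fiber_length_um,
                 fiber_width_px = fiber_width_px,
                 fiber_tortuosity = fiber_tortuosity,
                 cell_diameter_um = cell_diameter_um,
                 fg_mean = fg_mean, fg_sd = fg_sd,
                 bg_mean = bg_mean, bg_sd = bg_sd,
                 bleedthrough = bleedthrough,
                 separation_px = as.integer(separation_px),
                 lateral_fibers = as.integer(lateral_fibers),
                 peripherin_only_fibers = as.integer(peripherin_only_fibers),
                 scale = as_pixel_scale(scale),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec: %d x %d px, %d fibers + %d lateral, %d cells, %d peripherin-only, seed %d>\n",
    x$width_px, x$height_px, x$n_fibers, x$lateral_fibers, x$n_cells,
    x$peripherin_only_fibers, x$seed))
  invisible(x)
}

# Rasterize a polyline by stamping a disk of the given radius at each
# (densely sampled) point; returns linear pixel indices into an h x w grid.
stamp_polyline <- function(xs, ys, radius, w, h) {
  r <- max(radius, 0.5)
  off <- expand.grid(dx = -ceiling(r):ceiling(r), dy = -ceiling(r):ceiling(r))
  off <- off[off$dx^2 + off$dy^2 <= r^2 + 1e-9, ]
  px <- rep(round(xs), each = nrow(off)) + off$dx
  py <- rep(round(ys), each = nrow(off)) + off$dy
  keep <- px >= 1 & px <= w & py >= 1 & py <= h
  unique((px[keep] - 1L) * h + py[keep])
}

# Random-walk fiber centreline of given pixel length starting inside margins.
fiber_pixels <- function(length_px, width_px_stroke, tortuosity, w, h) {
  margin <- 8
  x <- runif(1, margin, w - margin)
  y <- runif(1, margin, h - margin)
  theta <- runif(1, 0, 2 * pi)
  n_steps <- max(2L, ceiling(length_px))
  xs <- numeric(n_steps); ys <- numeric(n_steps)
  for (i in seq_len(n_steps)) {
    xs[i] <- x; ys[i] <- y
    theta <- theta + rnorm(1, 0, tortuosity)
    x <- min(max(x + cos(theta), 2), w - 1)
    y <- min(max(y + sin(theta), 2), h - 1)
  }
  stamp_polyline(xs, ys, width_px_stroke / 2, w, h)
}

disk_pixels <- function(cx, cy, radius, w, h) {
  stamp_polyline(cx, cy, radius, w, h)
}

# Chebyshev-dilate a pixel set by s (for separation testing).
dilate_pixels <- function(idx, s, w, h) {
  if (s <= 0 || length(idx) == 0) return(idx)
  py <- ((idx - 1L) %% h) + 1L
  px <- ((idx - 1L) %/% h) + 1L
  off <- expand.grid(dx = -s:s, dy = -s:s)
  qx <- rep(px, each = nrow(off)) + off$dx
  qy <- rep(py, each = nrow(off)) + off$dy
  keep <- qx >= 1 & qx <= w & qy >= 1 & qy <= h
  (qx[keep] - 1L) * h + qy[keep]          # duplicates harmless for probing
}

place_structure <- function(gen, occupied, sep, w, h, max_tries = 100) {
  for (try in seq_len(max_tries)) {
    idx <- gen()
    if (length(idx) == 0) next
    probe <- dilate_pixels(idx, sep, w, h)
    if (!any(occupied[probe])) return(idx)
  }
  abort("Could not place structure without overlap after bounded retries; reduce counts or separation.")
}

clamp8 <- function(x) {
  x <- as.integer(round(x))
  x[x < 0L] <- 0L; x[x > 255L] <- 255L
  x
}

#' Generate a synthetic TH/peripherin image pair with ground truth
#'
#' Renders the field described by a [synthetic_spec()]: fibers as
#' rasterized random-walk polylines bright in both channels, cells as disks
#' bright in TH only, optional peripherin-only fibers and laterally
#' sectioned fiber blobs, over Gaussian background noise clipped to
#' \[0, 255\]. Deterministic given the spec's seed (the caller's RNG state
#' is left untouched).
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `th` and `peripherin` ([channel_image()]s) and
#'   `truth`: a list of per-structure pixel-index sets (`fiber_pixels`,
#'   `cell_pixels`, `peripherin_only_pixels`) plus planted counts.
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  w <- spec$width_px; h <- spec$height_px
  ppu <- spec$scale$pixels_per_um
  n_px <- w * h
  occupied <- matrix(FALSE, h, w)

  draw_fiber <- function() {
    len_px <- runif(1, spec$fiber_length_um[1], spec$fiber_length_um[2]) * ppu
    wd <- runif(1, spec$fiber_width_px[1], spec$fiber_width_px[2])
    fiber_pixels(len_px, wd, spec$fiber_tortuosity, w, h)
  }
  draw_cell <- function() {
    r <- runif(1, spec$cell_diameter_um[1], spec$cell_diameter_um[2]) * ppu / 2
    disk_pixels(runif(1, 8, w - 8), runif(1, 8, h - 8), r, w, h)
  }
  draw_lateral <- function() {
    # small near-round blob just above the size filter (~fiber cross-section)
    r <- runif(1, 3, 4.5)
    disk_pixels(runif(1, 8, w - 8), runif(1, 8, h - 8), r, w, h)
  }

  plant <- function(n, gen) {
    purrr::map(seq_len(n), function(i) {
      idx <- place_structure(gen, occupied, spec$separation_px, w, h)
      occupied[idx] <<- TRUE
      idx
    })
  }

  fibers <- plant(spec$n_fibers, draw_fiber)
  laterals <- plant(spec$lateral_fibers, draw_lateral)
  cells <- plant(spec$n_cells, draw_cell)
  peri_only <- plant(spec$peripherin_only_fibers, draw_fiber)

  th <- matrix(clamp8(rnorm(n_px, spec$bg_mean, spec$bg_sd)), h, w)
  pe <- matrix(clamp8(rnorm(n_px, spec$bg_mean, spec$bg_sd)), h, w)

  emit <- function(img, idx) {
    img[idx] <- clamp8(rnorm(length(idx), spec$fg_mean, spec$fg_sd))
    img
  }
  bleed <- function(img, idx) {
    img[idx] <- clamp8(img[idx] + spec$bleedthrough * spec$fg_mean)
    img
  }

  for (idx in c(fibers, laterals)) {
    th <- emit(th, idx); pe <- emit(pe, idx)
  }
  for (idx in cells) {
    th <- emit(th, idx); pe <- bleed(pe, idx)
  }
  for (idx in peri_only) {
    pe <- emit(pe, idx); th <- bleed(th, idx)
  }

  list(
    th = new_channel_image(th, spec$scale, "TH"),
    peripherin = new_channel_image(pe, spec$scale, "peripherin"),
    truth = list(
      fiber_pixels = c(fibers, laterals),
      cell_pixels = cells,
      peripherin_only_pixels = peri_only,
      n_fibers = spec$n_fibers + spec$lateral_fibers,
      n_cells = spec$n_cells
    )
  )
}

#' Generate a benchmark set of synthetic image pairs with a manifest
#'
#' Writes `n_images` image pairs per grid row to `dir` as 8-bit TIFFs,
#' together with a ground-truth CSV and a batch manifest consumable by
#' [run_batch()]. Each grid row defines a group (e.g. genotype) with its
#' own planted fiber/cell counts; with `density_grid = NULL` a single
#' group using the base spec's counts is produced. Per-image seeds are
#' derived deterministically from the base spec's seed.
#'
#' @param base A [synthetic_spec()] providing geometry, intensity model and
#'   base seed.
#' @param n_images Images per group (>= 1).
#' @param density_grid Optional data frame with columns `group`,
#'   `n_fibers`, `n_cells`.
#' @param dir Output directory (created if missing).
#' @return The manifest tibble (columns `image_id`, `tissue`, `genotype`,
#'   `th_path`, `peripherin_path`, `width_px`, `height_px`,
#'   `n_fibers_true`, `n_cells_true`), invisibly written to
#'   `manifest.csv` alongside `truth.csv` in `dir`.
#' @export
generate_benchmark_set <- function(base, n_images, density_grid = NULL,
                                   dir = tempfile("benchmark")) {
  stopifnot(inherits(base, "synthetic_spec"), n_images >= 1)
  if (is.null(density_grid)) {
    density_grid <- data.frame(group = "synthetic",
                               n_fibers = base$n_fibers,
                               n_cells = base$n_cells)
  }
  stopifnot(all(c("group", "n_fibers", "n_cells") %in% names(density_grid)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); img_i <- 0L
  for (g in seq_len(nrow(density_grid))) {
    for (i in seq_len(n_images)) {
      img_i <- img_i + 1L
      spec_i <- base
      spec_i$n_fibers <- as.integer(density_grid$n_fibers[g])
      spec_i$n_cells <- as.integer(density_grid$n_cells[g])
      spec_i$seed <- (base$seed + 7919L * img_i) %% .Machine$integer.max
      pair <- generate_pair(spec_i)
      id <- sprintf("img%03d", img_i)
      th_path <- file.path(dir, paste0(id, "_th.tif"))
      pe_path <- file.path(dir, paste0(id, "_peripherin.tif"))
      write_channel(pair$th, th_path)
      write_channel(pair$peripherin, pe_path)
      rows[[img_i]] <- tibble::tibble(
        image_id = id, tissue = "synthetic",
        genotype = density_grid$group[g],
        th_path = th_path, peripherin_path = pe_path,
        width_px = spec_i$width_px, height_px = spec_i$height_px,
        n_fibers_true = pair$truth$n_fibers,
        n_cells_true = pair$truth$n_cells
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(dplyr::select(manifest, "image_id", "genotype",
                          "n_fibers_true", "n_cells_true"),
            file.path(dir, "truth.csv"), row.names = FALSE)
  manifest
}
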