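# Independent reference implementations used to validate the package's
# algorithms. Deliberately written as literal, loop-based transcriptions of
# the definitions, sharing no code with the implementation under test.

make_hist <- function(counts) {
  stopifnot(length(counts) == 256)
  structure(list(counts = as.integer(counts), total = sum(counts)),
            class = "histogram256")
}

# Image from an intensity matrix laid out as the printed image (rows = y).
img <- function(m, channel = "other", scale = pixel_scale()) {
  channel_image(m, scale = scale, channel = channel)
}

mask_of <- function(m) binary_mask(m > 0)

random_hist <- function() {
  counts <- integer(256)
  k <- sample(1:8, 1)
  for (j in seq_len(k)) {
    centre <- sample(0:255, 1)
    width <- sample(1:40, 1)
    lev <- pmax(0, pmin(255, round(rnorm(sample(50:500, 1), centre, width))))
    counts <- counts + tabulate(lev + 1L, 256L)
  }
  if (sum(counts) == 0) counts[sample(0:255, 1) + 1L] <- 10L
  counts
}

# -- Otsu: exhaustive 256-candidate brute force ------------------------------
oracle_otsu <- function(counts) {
  total <- sum(counts)
  lev <- 0:255
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:255) {
    low <- lev <= t
    n0 <- sum(counts[low]); n1 <- sum(counts[!low])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(lev[low] * counts[low]) / n0
    mu1 <- sum(lev[!low] * counts[!low]) / n1
    v <- (n0 / total) * (n1 / total) * (mu0 - mu1)^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# -- Triangle: pointwise perpendicular distance geometry ---------------------
oracle_triangle <- function(counts) {
  pop <- which(counts > 0) - 1L
  if (length(pop) == 1) return(pop)
  peak <- which.max(counts) - 1L
  lo <- pop[1]; hi <- pop[length(pop)]
  flip <- (peak - lo) > (hi - peak)
  if (flip) {
    counts <- rev(counts)
    peak <- 255L - peak
    hi <- 255L - lo
  }
  x1 <- peak; y1 <- counts[peak + 1]
  x2 <- hi; y2 <- counts[hi + 1]
  vlen <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  best_t <- peak; best_d <- -Inf
  for (x in peak:hi) {
    # |v x p| / |v|: area of the parallelogram over the base length
    d <- abs((x2 - x1) * (counts[x + 1] - y1) - (y2 - y1) * (x - x1)) / vlen
    if (d > best_d + 1e-9) { best_d <- d; best_t <- x }
  }
  if (flip) 255L - best_t else best_t
}

# -- Intermeans: literal fixed-point loop ------------------------------------
oracle_intermeans <- function(counts) {
  pop <- which(counts > 0) - 1L
  if (length(pop) == 1) return(pop)
  lo <- pop[1]; hi <- pop[length(pop)]
  lev <- 0:255
  t <- (lo + hi) %/% 2
  repeat {
    low <- lev <= t
    mu_low <- sum(lev[low] * counts[low]) / sum(counts[low])
    mu_high <- sum(lev[!low] * counts[!low]) / sum(counts[!low])
    t_new <- floor((mu_low + mu_high) / 2 + 0.5)
    t_new <- min(max(t_new, lo), hi - 1)
    if (t_new == t) return(t)
    t <- t_new
  }
}

# -- Connected components: queue-based 8-neighbour flood fill ----------------
oracle_flood_fill <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  next_lab <- 0L
  for (y in 1:h) for (x in 1:w) {
    if (mask[y, x] && lab[y, x] == 0L) {
      next_lab <- next_lab + 1L
      queue <- list(c(y, x))
      lab[y, x] <- next_lab
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (dy in -1:1) for (dx in -1:1) {
          ny <- p[1] + dy; nx <- p[2] + dx
          if (ny >= 1 && ny <= h && nx >= 1 && nx <= w &&
              mask[ny, nx] && lab[ny, nx] == 0L) {
            lab[ny, nx] <- next_lab
            queue[[length(queue) + 1]] <- c(ny, nx)
          }
        }
      }
    }
  }
  lab
}

# -- Feret diameter: all-pairs brute force -----------------------------------
oracle_caliper <- function(xs, ys) {
  n <- length(xs)
  if (n == 1) return(0)
  best <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((xs[i] - xs[j])^2 + (ys[i] - ys[j])^2)
    if (d > best) best <- d
  }
  best
}

# -- Textbook statistics -----------------------------------------------------
oracle_welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se <- sqrt(va / na + vb / nb)
  t <- (mean(a) - mean(b)) / se
  df <- (va / na + vb / nb)^2 /
    ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, p = p)
}

oracle_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

small_spec <- function(seed, ...) {
  synthetic_spec(width_px = 400, height_px = 300, n_fibers = 3, n_cells = 4,
                 fiber_length_um = c(20, 60), seed = seed, ...)
}
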