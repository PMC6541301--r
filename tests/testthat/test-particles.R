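test_that("a solid square is one particle with the right measurements", {
  m <- matrix(0L, 9, 9); m[3:7, 3:7] <- 1L
  tbl <- label_components(mask_of(m))
  expect_equal(nrow(tbl), 1)
  expect_equal(tbl$area_px, 25L)
  expect_equal(tbl$centroid_x, 5); expect_equal(tbl$centroid_y, 5)
  expect_equal(c(tbl$min_x, tbl$min_y, tbl$max_x, tbl$max_y), c(3, 3, 7, 7))
  expect_equal(tbl$caliper_px, 4 * sqrt(2))
})

test_that("diagonally touching pixels form one 8-connected particle", {
  m <- matrix(0L, 4, 4); m[1, 1] <- 1L; m[2, 2] <- 1L
  expect_equal(nrow(label_components(mask_of(m))), 1)
  # anti-diagonal too
  m <- matrix(0L, 4, 4); m[2, 1] <- 1L; m[1, 2] <- 1L
  expect_equal(nrow(label_components(mask_of(m))), 1)
})

test_that("an empty mask yields an empty particle table", {
  tbl <- label_components(binary_mask(matrix(FALSE, 5, 5)))
  expect_equal(nrow(tbl), 0)
  expect_equal(nrow(filter_by_size(tbl, 23)), 0)
  expect_equal(nrow(filter_manual_criterion(tbl, 50)), 0)
})

test_that("labeling matches a flood-fill oracle on random masks", {
  set.seed(77)
  for (i in 1:12) {
    m <- matrix(runif(32 * 32) < 0.35, 32, 32)
    tbl <- label_components(binary_mask(m))
    oracle <- oracle_flood_fill(m)
    expect_equal(nrow(tbl), max(oracle), info = paste("replicate", i))
    # same partition: each oracle component maps to exactly one label
    lab <- attr(tbl, "labels")
    expect_true(all((lab > 0) == m))
    for (k in seq_len(max(oracle))) {
      expect_length(unique(lab[oracle == k]), 1)
    }
  }
})

test_that("particle labels are disjoint and cover the mask exactly", {
  set.seed(78)
  m <- matrix(runif(64 * 64) < 0.3, 64, 64)
  tbl <- label_components(binary_mask(m))
  lab <- attr(tbl, "labels")
  expect_equal(sum(tbl$area_px), sum(m))
  expect_equal(sort(unique(as.vector(lab[lab > 0]))), seq_len(nrow(tbl)))
  expect_equal(as.vector(tabulate(lab[lab > 0], nrow(tbl))),
               as.vector(tbl$area_px))
})

test_that("labels are assigned in row-major first-pixel order", {
  m <- matrix(0L, 5, 10)
  m[4, 2] <- 1L          # later row: should get the higher label
  m[1, 9] <- 1L          # first row, right side: seen first in raster order
  tbl <- label_components(mask_of(m))
  expect_equal(nrow(tbl), 2)
  expect_equal(tbl$centroid_y[1], 1)   # particle 1 is the first-row pixel
  expect_equal(tbl$centroid_y[2], 4)
})

test_that("max caliper equals the all-pairs brute force on random particles", {
  set.seed(79)
  for (i in 1:10) {
    m <- matrix(runif(20 * 20) < 0.4, 20, 20)
    tbl <- label_components(binary_mask(m))
    lab <- attr(tbl, "labels")
    for (k in tbl$particle) {
      idx <- which(lab == k)
      ys <- ((idx - 1) %% nrow(lab)) + 1
      xs <- ((idx - 1) %/% nrow(lab)) + 1
      expect_equal(tbl$caliper_px[tbl$particle == k], oracle_caliper(xs, ys))
    }
  }
})

test_that("translation preserves areas, calipers and counts", {
  set.seed(80)
  m <- matrix(FALSE, 40, 40)
  m[5:12, 6:10] <- matrix(runif(40) < 0.7, 8, 5)
  m[20:24, 25:33] <- matrix(runif(45) < 0.7, 5, 9)
  shifted <- matrix(FALSE, 40, 40)
  shifted[(5:33) + 4, (5:33) + 3] <- m[5:33, 5:33]
  t1 <- label_components(binary_mask(m))
  t2 <- label_components(binary_mask(shifted))
  expect_equal(nrow(t1), nrow(t2))
  expect_equal(sort(t1$area_px), sort(t2$area_px))
  expect_equal(sort(t1$caliper_px), sort(t2$caliper_px))
  expect_equal(sort(t2$centroid_x), sort(t1$centroid_x + 3))
  expect_equal(sort(t2$centroid_y), sort(t1$centroid_y + 4))
})

test_that("the size filter keeps particles at or above the minimum area", {
  # three blobs of areas 25, 22, 23: the fiber criterion keeps two
  m <- matrix(0L, 30, 30)
  m[2:6, 2:6] <- 1L                       # 25 px
  m[10:20, 10] <- 1L; m[10:20, 11] <- 1L  # 22 px
  m[25:29, 20:24] <- 1L; m[25, 20] <- 0L; m[25, 21] <- 0L  # 23 px
  tbl <- label_components(mask_of(m))
  expect_equal(sort(tbl$area_px), c(22L, 23L, 25L))
  expect_equal(nrow(filter_by_size(tbl, 23)), 2)
  expect_equal(nrow(filter_by_size(tbl, 0)), 3)
  expect_equal(nrow(filter_by_size(tbl, 26)), 0)
  expect_error(filter_by_size(tbl, -1), "non-negative")
})

test_that("raising the minimum area never increases the count", {
  set.seed(81)
  m <- matrix(runif(50 * 50) < 0.45, 50, 50)
  tbl <- label_components(binary_mask(m))
  counts <- vapply(c(0, 1, 2, 4, 8, 16, 32),
                   function(a) nrow(filter_by_size(tbl, a)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the manual length criterion keeps only long particles", {
  m <- matrix(0L, 5, 200)
  m[2, 1:150] <- 1L       # 150 px straight segment: caliper 149 px >= 141.4
  m[4, 1:100] <- 1L       # 100 px segment: caliper 99 px, removed
  tbl <- label_components(mask_of(m))
  kept <- filter_manual_criterion(tbl, 50, pixel_scale(2.828))
  expect_equal(nrow(kept), 1)
  expect_equal(kept$max_x, 150)
})

test_that("particle CSV export adds micrometer measurements", {
  m <- matrix(0L, 10, 10); m[2:4, 2:4] <- 1L
  tbl <- label_components(mask_of(m))
  path <- withr::local_tempfile(fileext = ".csv")
  out <- write_particles(tbl, path, pixel_scale(2))
  expect_true(file.exists(path))
  expect_equal(out$area_um2, 9 / 4)
  expect_equal(out$caliper_um, tbl$caliper_px / 2)
})
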