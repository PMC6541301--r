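test_that("blank channels give zero counts with flagged thresholds", {
  blank <- img(matrix(0L, 60, 80), channel = "TH")
  roi <- th_positive_roi(blank)
  expect_equal(sum(roi), 0)
  expect_true(attr(roi, "degenerate"))

  expect_warning(res <- count_fibers(blank, img(matrix(0L, 60, 80))), "empty")
  expect_equal(res$count, 0)
  expect_equal(res$density_per_mm2, 0)

  res_c <- count_cells(blank, img(matrix(0L, 60, 80)))
  expect_equal(res_c$count, 0)
})

test_that("a bright blob is covered by the TH ROI", {
  set.seed(12)
  m <- matrix(pmax(0, round(rnorm(80 * 80, 10, 3))), 80, 80)
  m[30:35, 40:44] <- 220L
  roi <- th_positive_roi(img(m, channel = "TH"))
  expect_true(all(roi[30:35, 40:44]))
  expect_false(attr(roi, "degenerate"))
})

test_that("peripherin ROI covers a bright curvilinear structure", {
  set.seed(13)
  m <- matrix(pmax(0, round(rnorm(100 * 100, 15, 5))), 100, 100)
  path_cols <- 10:90
  path_rows <- round(50 + 15 * sin(seq(0, 3 * pi, length.out = 81)))
  for (i in seq_along(path_cols)) {
    m[path_rows[i] + (-1:1), path_cols[i]] <- 210L
  }
  roi <- peripherin_positive_roi(img(m, channel = "peripherin"))
  expect_true(all(roi[cbind(path_rows, path_cols)]))
  # a fully saturated image is degenerate, flagged not fatal
  sat <- peripherin_positive_roi(img(matrix(255L, 20, 20)))
  expect_true(attr(sat, "degenerate"))
})

test_that("planted fibers and cells are recovered at their planted counts", {
  pair <- generate_pair(small_spec(seed = 21))
  fib <- count_fibers(pair$th, pair$peripherin)
  cel <- count_cells(pair$th, pair$peripherin)
  expect_equal(fib$count, pair$truth$n_fibers)
  expect_equal(cel$count, pair$truth$n_cells)
  expect_equal(fib$density_per_mm2, fib$count / fib$image_area_mm2)
})

test_that("counted fibers are double-positive: inside TH ROI and peripherin mask", {
  pair <- generate_pair(small_spec(seed = 22))
  fib <- count_fibers(pair$th, pair$peripherin)
  lab <- attr(fib$particles, "labels")
  counted <- lab > 0
  expect_true(all(fib$masks$th_roi[counted]))
  expect_true(all(fib$masks$double_positive[counted]))
})

test_that("reported cells never overlap the peripherin mask", {
  pair <- generate_pair(small_spec(seed = 23))
  cel <- count_cells(pair$th, pair$peripherin)
  lab <- attr(cel$particles, "labels")
  expect_equal(sum(lab > 0 & cel$masks$peripherin_roi), 0)
})

test_that("fiber and cell pixel sets are disjoint on the same image pair", {
  pair <- generate_pair(small_spec(seed = 24))
  fib <- count_fibers(pair$th, pair$peripherin)
  cel <- count_cells(pair$th, pair$peripherin)
  fib_px <- attr(fib$particles, "labels") > 0
  cel_px <- attr(cel$particles, "labels") > 0
  expect_equal(sum(fib_px & cel_px), 0)
})

test_that("raising the fiber size filter never increases the count", {
  pair <- generate_pair(small_spec(seed = 25))
  counts <- vapply(c(1, 23, 100, 400, 2000), function(a) {
    count_fibers(pair$th, pair$peripherin,
                 fiber_count_config(min_fiber_area_px = a))$count
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a TH disk fully inside the peripherin mask is cleared, not counted", {
  set.seed(26)
  th <- matrix(pmax(0, round(rnorm(100 * 100, 15, 5))), 100, 100)
  pe <- matrix(pmax(0, round(rnorm(100 * 100, 15, 5))), 100, 100)
  th[40:52, 40:52] <- 210L   # TH blob
  pe[38:54, 38:54] <- 200L   # peripherin region swallowing it
  res <- count_cells(img(th, channel = "TH"), img(pe, channel = "peripherin"))
  expect_equal(res$count, 0)
})

test_that("pipelines are deterministic: identical inputs give identical results", {
  pair <- generate_pair(small_spec(seed = 27))
  a <- count_fibers(pair$th, pair$peripherin)
  b <- count_fibers(pair$th, pair$peripherin)
  expect_identical(glance(a), glance(b))
  expect_identical(tidy(a), tidy(b))
  expect_identical(as.vector(attr(a$particles, "labels")),
                   as.vector(attr(b$particles, "labels")))
})

test_that("dimension mismatches are rejected", {
  a <- img(matrix(0L, 10, 10)); b <- img(matrix(0L, 10, 12))
  expect_error(count_fibers(a, b), "dimensions")
  expect_error(count_cells(a, b), "dimensions")
})

test_that("count results expose tidy particle tables and one-row summaries", {
  pair <- generate_pair(small_spec(seed = 28))
  fib <- count_fibers(pair$th, pair$peripherin)
  td <- tidy(fib)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), fib$count)
  gl <- glance(fib)
  expect_equal(gl$count, fib$count)
  expect_equal(gl$threshold_th_method, "otsu")
  expect_equal(gl$threshold_peripherin_method, "intermeans")
})
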