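test_that("a zero-structure spec yields pure noise with empty truth", {
  spec <- synthetic_spec(width_px = 120, height_px = 90,
                         n_fibers = 0, n_cells = 0, seed = 41)
  pair <- generate_pair(spec)
  expect_length(pair$truth$fiber_pixels, 0)
  expect_length(pair$truth$cell_pixels, 0)
  expect_lt(mean(pair$th), 60)   # background-level intensities only
  expect_lt(mean(pair$peripherin), 60)
})

test_that("generation is deterministic given the seed and leaves the RNG alone", {
  spec <- small_spec(seed = 42)
  set.seed(999); before <- runif(1)
  set.seed(999)
  a <- generate_pair(spec)
  after <- runif(1)
  b <- generate_pair(spec)
  expect_identical(as.vector(a$th), as.vector(b$th))
  expect_identical(as.vector(a$peripherin), as.vector(b$peripherin))
  expect_identical(a$truth$fiber_pixels, b$truth$fiber_pixels)
  expect_identical(before, after)  # caller RNG stream undisturbed

  c_ <- generate_pair(small_spec(seed = 43))
  expect_false(identical(as.vector(a$th), as.vector(c_$th)))
})

test_that("planted structures are bright in the right channels", {
  spec <- small_spec(seed = 44)
  pair <- generate_pair(spec)
  lim <- spec$fg_mean - 3 * spec$fg_sd
  for (px in pair$truth$fiber_pixels) {
    expect_gte(mean(pair$th[px]), lim)
    expect_gte(mean(pair$peripherin[px]), lim)
  }
  for (px in pair$truth$cell_pixels) {
    expect_gte(mean(pair$th[px]), lim)
    expect_lt(mean(pair$peripherin[px]), 100)  # only bleed-through
  }
})

test_that("planted structures never overlap and fibers exceed the size filter", {
  spec <- small_spec(seed = 45)
  pair <- generate_pair(spec)
  all_sets <- c(pair$truth$fiber_pixels, pair$truth$cell_pixels)
  all_px <- unlist(all_sets)
  expect_equal(length(all_px), length(unique(all_px)))
  for (px in pair$truth$fiber_pixels) expect_gte(length(px), 23)
})

test_that("peripherin-only fibers are counted by neither pipeline", {
  spec <- synthetic_spec(width_px = 500, height_px = 400,
                         n_fibers = 3, n_cells = 3,
                         peripherin_only_fibers = 3, seed = 46)
  pair <- generate_pair(spec)
  fib <- count_fibers(pair$th, pair$peripherin)
  cel <- count_cells(pair$th, pair$peripherin)
  expect_equal(fib$count, 3)   # sympathetic fibers only
  expect_equal(cel$count, 3)   # cells only; peripherin-only fibers cleared
})

test_that("laterally sectioned fiber blobs are counted by the automated method only", {
  spec <- synthetic_spec(width_px = 500, height_px = 400,
                         n_fibers = 2, n_cells = 3,
                         fiber_length_um = c(60, 110),
                         lateral_fibers = 3, seed = 47)
  pair <- generate_pair(spec)
  fib <- count_fibers(pair$th, pair$peripherin)
  expect_equal(fib$count, 5)   # automated counts laterals too
  manual <- filter_manual_criterion(fib$particles, 50, spec$scale)
  expect_lte(nrow(manual), 2)  # the 50 um criterion drops the small blobs
})

test_that("benchmark sets write images, truth and a consumable manifest", {
  dir <- withr::local_tempdir()
  base <- synthetic_spec(width_px = 160, height_px = 120,
                         n_fibers = 1, n_cells = 1,
                         fiber_length_um = c(15, 25), seed = 48)
  manifest <- generate_benchmark_set(base, n_images = 4, dir = dir)
  expect_equal(nrow(manifest), 4)
  expect_true(all(file.exists(manifest$th_path)))
  expect_true(all(file.exists(manifest$peripherin_path)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  # images round-trip identically through the TIFFs
  back <- read_channel(manifest$th_path[1], "TH", base$scale)
  expect_equal(dim(back), c(120L, 160L))
})

test_that("a zero-density grid produces empty-truth images", {
  dir <- withr::local_tempdir()
  base <- synthetic_spec(width_px = 120, height_px = 90, seed = 49)
  grid <- data.frame(group = "empty", n_fibers = 0, n_cells = 0)
  manifest <- generate_benchmark_set(base, 3, grid, dir)
  expect_equal(manifest$n_fibers_true, rep(0L, 3))
  expect_equal(manifest$n_cells_true, rep(0L, 3))
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(truth$n_fibers_true, rep(0L, 3))
})

test_that("a two-genotype grid yields a detectable density difference", {
  dir <- withr::local_tempdir()
  base <- synthetic_spec(width_px = 640, height_px = 480,
                         fiber_length_um = c(20, 60), seed = 50)
  grid <- data.frame(group = c("wildtype", "ko"),
                     n_fibers = c(2, 8), n_cells = c(2, 2))
  manifest <- generate_benchmark_set(base, 6, grid, dir)
  res <- run_batch(manifest, run_config())
  summ <- batch_summary(res)
  expect_lt(summ$fiber_density_t_test$p_value, 0.05)
  means <- summ$by_genotype$fiber_density_mean
  expect_gt(max(means), min(means))
})
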