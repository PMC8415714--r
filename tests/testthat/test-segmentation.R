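test_that("fruit masking recovers a bright ellipsoid in dark air", {
  dims <- c(60, 60, 70)
  ell <- fixture_ellipsoid(dims, center = c(30, 30, 35), semi = c(22, 22, 28))
  arr <- array(25L, dims)
  arr[ell] <- 170L
  # dark internal spheres must be filled back into the mask
  holes <- fixture_ellipsoid(dims, center = c(30, 30, 35), semi = c(4, 4, 4)) |
    fixture_ellipsoid(dims, center = c(24, 32, 28), semi = c(3, 3, 3))
  arr[holes] <- 25L
  vol <- fixture_volume(arr)
  mask <- compute_fruit_mask(vol)
  expect_true(all(mask[holes]))
  analytic <- 4 / 3 * pi * 22 * 22 * 28
  expect_lt(abs(sum(mask) - analytic) / analytic, 0.02)

  expect_error(compute_fruit_mask(fixture_volume(array(12L, c(20, 20, 20)))),
               "no object found")
})

test_that("histograms count masked voxels exactly", {
  vol <- fixture_volume(array(77L, c(10, 10, 10)))
  h <- compute_histogram(vol)
  expect_equal(sum(h$counts), 1000L)
  expect_equal(sum(h$counts > 0L), 1L)
  expect_equal(h$mids[which(h$counts > 0L)], 77.5)

  # noise-free two-phase phantom: exactly two nonzero bins
  pore <- array(FALSE, c(12, 12, 12)); pore[3:5, 3:5, 3:5] <- TRUE
  h2 <- compute_histogram(fixture_two_phase(pore))
  expect_equal(sum(h2$counts > 0L), 2L)

  set.seed(3)
  arr <- array(sample(0:255, 17^3, TRUE), c(17, 17, 17))
  mask <- array(runif(17^3) < 0.4, c(17, 17, 17))
  h3 <- compute_histogram(fixture_volume(arr), mask)
  expect_equal(sum(h3$counts), sum(mask))
  expect_equal(h3$mask_voxel_count, sum(mask))
  expect_error(compute_histogram(fixture_volume(arr), mask & FALSE), "empty mask")
})

test_that("the valley threshold separates well-split modes", {
  # two delta peaks with an empty gap: T strictly inside the gap
  arr <- array(30L, c(20, 20, 20)); arr[1:10, , ] <- 160L
  h <- compute_histogram(fixture_volume(arr))
  par <- find_valley_threshold(h)
  expect_identical(par$source, "valley")
  expect_gt(par$threshold, 30); expect_lt(par$threshold, 160)

  # Gaussian mixture: T in [60, 130], misclassification < 0.1 %
  set.seed(1)
  n <- 1e6
  comp <- runif(n) < 0.5
  draws <- pmin(pmax(round(rnorm(n, ifelse(comp, 30, 160), 8)), 0), 255)
  vol <- fixture_volume(array(as.integer(draws), c(100, 100, 100)))
  par2 <- find_valley_threshold(compute_histogram(vol))
  expect_gte(par2$threshold, 60); expect_lte(par2$threshold, 130)
  wrong <- sum(comp & draws >= par2$threshold) +
    sum(!comp & draws < par2$threshold)
  expect_lt(wrong / n, 0.001)

  # unimodal histogram (deterministic triangular mode) falls back to Otsu
  vals <- rep(100:140, times = c(1:21, 20:1))
  uni <- fixture_volume(array(as.integer(vals), c(length(vals), 1, 1)))
  par3 <- find_valley_threshold(compute_histogram(uni))
  expect_identical(par3$source, "otsu")
  expect_error(find_valley_threshold(
    structure(list(bin_edges = 0:256, mids = 0:255 + 0.5,
                   counts = rep(0L, 256), mask_voxel_count = 0L,
                   bit_depth = 8L), class = "gray_histogram")), "empty")
})

test_that("phase segmentation is strict, monotone in T, and exact when separable", {
  pore <- array(FALSE, c(16, 16, 16)); pore[4:8, 4:8, 4:8] <- TRUE
  vol <- fixture_two_phase(pore)
  mask <- array(TRUE, dim(pore))

  # T below the volume minimum: no pore voxels
  expect_equal(sum(segment_phases(vol, 10, mask)$phase == 2L), 0)
  # noise-free phases split exactly at T = 95
  ph <- segment_phases(vol, 95, mask)
  expect_identical(ph$phase == 2L, pore)
  # monotone: raising T never shrinks the pore set
  set.seed(5)
  noisy <- fixture_volume(array(as.integer(sample(0:255, 16^3, TRUE)),
                                c(16, 16, 16)))
  p1 <- segment_phases(noisy, 80, mask)$phase == 2L
  p2 <- segment_phases(noisy, 140.5, mask)$phase == 2L
  expect_true(all(p2[p1]))
  # strict comparison admits fractional thresholds: v = 69 is pore at 69.7
  frac <- fixture_volume(array(c(69L, 70L), c(2, 1, 1)))
  phf <- segment_phases(frac, 69.7, array(TRUE, c(2, 1, 1)))
  expect_equal(as.vector(phf$phase), c(2L, 1L))
})

test_that("segmenting a noisy phantom agrees voxelwise with the ground truth", {
  spec <- phantom_spec(c(64, 64, 64), 1,
                       pore_model = list(target_porosity_percent = 8,
                                         diameter = list(kind = "fixed",
                                                         d_um = 7)),
                       intensity_model = list(tissue_mean = 160, pore_mean = 30,
                                              sd = 8),
                       allow_overlap = TRUE, seed = 12)
  g <- generate_phantom(spec)
  mask <- compute_fruit_mask(g$volume)
  par <- find_valley_threshold(compute_histogram(g$volume, mask))
  ph <- segment_phases(g$volume, par, mask)
  agreement <- mean((ph$phase == 2L) == (g$truth$phase_map$phase == 2L))
  expect_gte(agreement, 0.99)

  # porosity converges to truth as the noise vanishes
  err <- vapply(c(16, 8, 2), function(s) {
    sp <- spec; sp$intensity_model$sd <- s
    gs <- generate_phantom(sp)
    m <- compute_fruit_mask(gs$volume)
    pp <- segment_phases(gs$volume,
                         find_valley_threshold(compute_histogram(gs$volume, m)), m)
    abs(porosity(pp, m) - gs$truth$true_porosity_percent)
  }, numeric(1))
  expect_true(err[3] <= err[1] + 1e-9)
  expect_lt(err[3], 0.05)
})
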