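test_that("volumes round-trip bit-identically through every format", {
  set.seed(1)
  td <- withr::local_tempdir()
  v8 <- fixture_volume(array(sample(0:255, 10 * 10 * 4, TRUE), c(10, 10, 4)),
                       voxel_size_um = 79.4)
  v16 <- voxel_volume(array(sample(0:65535, 8^3, TRUE), c(8, 8, 8)),
                      79.4, bit_depth = 16L)

  for (fmt in c("tiff", "tiff_dir", "mhd")) {
    p8 <- file.path(td, paste0("v8_", fmt,
                               switch(fmt, tiff = ".tif", mhd = ".mhd", "")))
    write_volume(v8, p8, format = fmt)
    r8 <- read_volume(p8, format = fmt)
    expect_identical(r8$intensities, v8$intensities)
    expect_equal(r8$voxel_size_um, 79.4)

    p16 <- file.path(td, paste0("v16_", fmt,
                                switch(fmt, tiff = ".tif", mhd = ".mhd", "")))
    write_volume(v16, p16, format = fmt)
    r16 <- read_volume(p16, format = fmt)
    expect_identical(r16$intensities, v16$intensities)
    expect_identical(r16$bit_depth, 16L)
  }

  # MHD stores the element spacing itself
  hdr <- readLines(file.path(td, "v16_mhd.mhd"))
  expect_true(any(grepl("ElementSpacing = 79.4", hdr, fixed = TRUE)))

  # constant-zero volume round-trips exactly
  z <- fixture_volume(array(0L, c(8, 8, 8)))
  write_volume(z, file.path(td, "zero.mhd"))
  expect_identical(read_volume(file.path(td, "zero.mhd"))$intensities,
                   z$intensities)
})

test_that("slice stacks honor numeric filename order and reject ragged slices", {
  td <- withr::local_tempdir()
  dir.create(file.path(td, "stack"))
  # write slices deliberately out of lexicographic order: 2, 10, 1
  for (k in c(2, 10, 1))
    tiff::writeTIFF(matrix(k / 255, 5, 5),
                    file.path(td, "stack", sprintf("img%d.tif", k)))
  vol <- read_volume(file.path(td, "stack"), voxel_size_um = 1)
  expect_equal(dim(vol$intensities)[3], 3L)
  expect_equal(as.vector(vol$intensities[1, 1, ]), c(1L, 2L, 10L))

  # one ragged slice is a format error
  tiff::writeTIFF(matrix(0, 4, 5), file.path(td, "stack", "img3.tif"))
  expect_error(read_volume(file.path(td, "stack"), voxel_size_um = 1),
               "inconsistent slice dimensions")

  # missing voxel size with no sidecar and no override
  dir.create(file.path(td, "stack2"))
  tiff::writeTIFF(matrix(0, 5, 5), file.path(td, "stack2", "img1.tif"))
  expect_error(read_volume(file.path(td, "stack2")), "voxel size")
  expect_error(read_volume(file.path(td, "missing.tif")), "not found")
})

test_that("8-bit conversion maps the window linearly with half-away rounding", {
  v <- voxel_volume(array(c(100L, 300L, 200L, 500L, 0L, 150L), c(6, 1, 1)),
                    1, bit_depth = 16L)
  c8 <- convert_to_8bit(v, 100, 300)
  expect_equal(as.vector(c8$intensities),
               c(0L, 255L, 128L, 255L, 0L, floor(255 * 50 / 200 + 0.5)))
  expect_identical(c8$bit_depth, 8L)
  expect_equal(c8$voxel_size_um, v$voxel_size_um)
  expect_error(convert_to_8bit(v, 10, 10), "degenerate")

  # elementwise oracle on a random 16-bit volume
  set.seed(7)
  arr <- array(sample(0:65535, 4^3, TRUE), c(4, 4, 4))
  v16 <- voxel_volume(arr, 1, bit_depth = 16L)
  wmin <- 1000; wmax <- 60000
  got <- convert_to_8bit(v16, wmin, wmax)$intensities
  oracle <- vapply(as.vector(arr), function(x) {
    x <- min(max(x, wmin), wmax)
    y <- 255 * (x - wmin) / (wmax - wmin)
    as.integer(floor(y + 0.5))  # half away from zero (y >= 0)
  }, integer(1))
  expect_equal(as.vector(got), oracle)

  # monotone non-decreasing in the input intensity
  xs <- seq(0, 65535, by = 257)
  v_line <- voxel_volume(array(as.integer(xs), c(length(xs), 1, 1)),
                         1, bit_depth = 16L)
  y <- as.vector(convert_to_8bit(v_line, 5000, 52000)$intensities)
  expect_true(all(diff(y) >= 0))
})

test_that("porosity is invariant under 16-to-8-bit conversion with a mapped threshold", {
  set.seed(11)
  # 16-bit two-phase slab with noise; the window (observed range, well
  # under 256 gray levels wide) expands, so the conversion is invertible
  arr <- array(0L, c(24, 24, 24))
  pore <- array(runif(length(arr)) < 0.1, dim(arr))
  arr[] <- as.integer(round(rnorm(length(arr), 3000, 10)))
  arr[pore] <- as.integer(round(rnorm(sum(pore), 2900, 10)))
  v16 <- voxel_volume(arr, 1, bit_depth = 16L)
  mask <- array(TRUE, dim(arr))

  T16 <- 2950
  p16 <- porosity(segment_phases(v16, T16, mask), mask)
  wmin <- min(arr); wmax <- max(arr)
  v8 <- convert_to_8bit(v16, wmin, wmax)
  T8 <- map_threshold_to_8bit(T16, wmin, wmax)
  p8 <- porosity(segment_phases(v8, T8, mask), mask)
  expect_equal(p8, p16)
})
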