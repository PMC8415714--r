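# Small grids keep these generator-contract checks fast; the full-size
# preset recovery runs live in test-acceptance.R.

small_slab_spec <- function(seed, porosity = 5, d_um = 8, sd = 0,
                            allow_overlap = FALSE, grid = c(48, 48, 48)) {
  phantom_spec(grid, 1,
               pore_model = list(target_porosity_percent = porosity,
                                 diameter = list(kind = "fixed", d_um = d_um)),
               intensity_model = list(tissue_mean = 160, pore_mean = 30, sd = sd),
               allow_overlap = allow_overlap, seed = seed)
}

test_that("identical spec and seed give bit-identical phantoms", {
  g1 <- generate_phantom(small_slab_spec(3, sd = 8))
  g2 <- generate_phantom(small_slab_spec(3, sd = 8))
  expect_identical(g1$volume$intensities, g2$volume$intensities)
  expect_identical(g1$truth$phase_map$phase, g2$truth$phase_map$phase)
  expect_identical(g1$truth$pore_table, g2$truth$pore_table)
})

test_that("zero porosity target gives a uniform tissue volume", {
  g <- generate_phantom(small_slab_spec(1, porosity = 0))
  expect_equal(g$truth$true_porosity_percent, 0)
  expect_equal(sum(g$truth$phase_map$phase == 2L), 0)
  expect_equal(length(unique(as.vector(g$volume$intensities))), 1L)
})

test_that("noise-free rendering has exactly the phase mean intensities", {
  g <- generate_phantom(small_slab_spec(2, sd = 0))
  vals <- sort(unique(as.vector(g$volume$intensities)))
  expect_equal(vals, c(30L, 160L))

  # ellipsoid fruit with a core: three intensities inside the fruit
  spec <- phantom_spec(c(48, 48, 48), 1,
                       fruit_shape = list(type = "ellipsoid",
                                          semi_axes_um = c(20, 20, 22)),
                       core = list(semi_axes_um = c(6, 6, 7),
                                   center_offset_um = c(0, 0, 0),
                                   intensity_offset = 40),
                       pore_model = list(target_porosity_percent = 4,
                                         diameter = list(kind = "fixed", d_um = 5)),
                       intensity_model = list(tissue_mean = 160, pore_mean = 30,
                                              sd = 0),
                       seed = 4)
  g2 <- generate_phantom(spec)
  inside <- g2$truth$fruit_mask
  expect_setequal(unique(as.vector(g2$volume$intensities[inside])),
                  c(30L, 160L, 200L))
})

test_that("placement stops at the porosity target within half an object", {
  g <- generate_phantom(small_slab_spec(5, porosity = 6, d_um = 8))
  obj_frac <- 100 * max(g$truth$placed$voxel_count) / g$truth$fruit_voxels
  expect_lt(abs(g$truth$true_porosity_percent - 6), obj_frac / 2 + 1e-9)
})

test_that("non-overlapping placement keeps pores one-to-one with components", {
  # density chosen below the random-sequential-adsorption jamming limit of
  # the clearance-inflated exclusion spheres
  g <- generate_phantom(small_slab_spec(6, porosity = 3, d_um = 8,
                                        grid = c(64, 64, 64)))
  expect_equal(nrow(g$truth$pore_table), nrow(g$truth$placed))
  # analytic volume vs voxelized truth porosity, within voxelization error
  analytic <- sum(4 / 3 * pi * (g$truth$placed$radius_um)^3)
  vox <- g$truth$true_porosity_percent / 100 * g$truth$fruit_voxels
  expect_lt(abs(analytic - vox) / vox, 0.15)
})

test_that("an unreachable non-overlap target fails with a clear error", {
  expect_error(generate_phantom(small_slab_spec(7, porosity = 45, d_um = 20,
                                                grid = c(32, 32, 32))),
               "generation failure")
})

test_that("U-shaped axial weighting concentrates pores at both fruit ends", {
  spec <- phantom_spec(c(40, 40, 96), 1,
                       pore_model = list(target_porosity_percent = 8,
                                         diameter = list(kind = "fixed", d_um = 5)),
                       axial_profile = "u_shaped",
                       intensity_model = list(tissue_mean = 160, pore_mean = 30,
                                              sd = 0),
                       allow_overlap = TRUE, seed = 8)
  g <- generate_phantom(spec)
  prof <- porosity_profile(g$truth$phase_map)
  q <- floor(nrow(prof) / 4)
  ends <- mean(prof$porosity_percent[c(seq_len(q), nrow(prof) - seq_len(q) + 1)])
  middle <- mean(prof$porosity_percent[(q + 1):(nrow(prof) - q)])
  expect_gt(ends, middle)
})

test_that("count-density targets place the requested number of objects", {
  spec <- phantom_spec(c(50, 50, 50), 100,  # 5 mm cube => 125 mm^3
                       pore_model = list(count_density_per_mm3 = 0.58,
                                         diameter = list(kind = "fixed",
                                                         d_um = 300)),
                       intensity_model = list(tissue_mean = 160, pore_mean = 30,
                                              sd = 0),
                       allow_overlap = FALSE, seed = 9)
  g <- generate_phantom(spec)
  region_mm3 <- g$truth$fruit_voxels * (100 / 1000)^3
  dens <- pore_number_density(g$truth$pore_table, region_mm3)
  expect_lt(abs(dens - 0.58) / 0.58, 0.10)
})

test_that("tube phantoms carry exact centerline ground truth", {
  one <- generate_tube_phantom(list(list(start = c(7, 15, 15),
                                         end = c(57, 15, 15), radius = 5)),
                               grid_shape = c(64, 30, 30))
  expect_equal(one$truth$total_length_vox, 50)
  expect_equal(one$truth$n_components, 1L)
  expect_equal(nrow(one$truth$endpoints), 2L)
  expect_equal(nrow(one$truth$junctions), 0L)

  y <- generate_tube_phantom(list(
    list(start = c(30, 30, 10), end = c(30, 30, 40), radius = 4),
    list(start = c(30, 30, 40), end = c(12, 30, 60), radius = 4),
    list(start = c(30, 30, 40), end = c(48, 30, 60), radius = 4)),
    grid_shape = c(60, 60, 70))
  expect_equal(nrow(y$truth$junctions), 1L)
  expect_equal(nrow(y$truth$endpoints), 3L)
  expect_equal(y$truth$n_components, 1L)

  two <- generate_tube_phantom(list(
    list(start = c(5, 8, 8), end = c(35, 8, 8), radius = 3),
    list(start = c(5, 22, 22), end = c(35, 22, 22), radius = 3)),
    grid_shape = c(40, 30, 30))
  expect_equal(two$truth$n_components, 2L)
  expect_equal(oracle_component_count(two$truth$phase_map$phase == 2L), 2L)

  expect_error(generate_tube_phantom(list(list(start = c(5, 5, 5),
                                               end = c(5, 5, 5), radius = 2)),
                                     grid_shape = c(20, 20, 20)),
               "zero-length")
})

test_that("phantom specs validate their invariants", {
  expect_error(small_slab_spec(1, porosity = 60), "\\[0, 50\\)")
  expect_error(phantom_spec(c(10, 10, 10), 1,
                            pore_model = list(diameter = list(kind = "fixed",
                                                              d_um = 4)),
                            seed = 1),
               "exactly one")
  expect_error(phantom_spec(c(10, 10, 10), 1,
                            pore_model = list(target_porosity_percent = 5,
                                              diameter = list(kind = "fixed",
                                                              d_um = 4)),
                            intensity_model = list(tissue_mean = 30,
                                                   pore_mean = 160, sd = 0),
                            seed = 1),
               "pores are dark")
  expect_error(phantom_spec(c(10, 10, 10), 2,
                            pore_model = list(target_porosity_percent = 5,
                                              diameter = list(kind = "fixed",
                                                              d_um = 1)),
                            seed = 1),
               "at least one voxel")
})
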