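test_that("thinning preserves topology and leaves thin structures alone", {
  # a one-voxel-wide straight line is already its own skeleton
  m <- array(FALSE, c(40, 9, 9)); m[5:34, 5, 5] <- TRUE
  expect_identical(skeletonize(m), m)

  # connected-component count is preserved on random fields
  set.seed(7)
  for (rep in 1:10) {
    m <- array(runif(3375) < 0.3, c(15, 15, 15))
    s <- skeletonize(m)
    expect_equal(oracle_component_count(s, 26), oracle_component_count(m, 26))
    expect_true(all(m[s]))  # skeleton is a subset of the object
  }

  # two disjoint capsules give two skeleton components
  two <- generate_tube_phantom(list(
    list(start = c(5, 8, 8), end = c(35, 8, 8), radius = 3),
    list(start = c(5, 22, 22), end = c(35, 22, 22), radius = 3)),
    grid_shape = c(40, 30, 30))
  s2 <- skeletonize(two$truth$phase_map)
  expect_equal(oracle_component_count(s2, 26), 2L)
})

test_that("the distance map is an exact Euclidean transform in physical units", {
  # single pore voxel: distance one voxel (center-to-center)
  m <- array(FALSE, c(7, 7, 7)); m[4, 4, 4] <- TRUE
  dm <- distance_map(m, voxel_size_um = 79.4)
  expect_equal(dm[4, 4, 4], 79.4)
  expect_equal(sum(dm > 0), 1L)

  # capsule of radius 5: the axial maximum is the capsule radius +- half a voxel
  cap <- generate_tube_phantom(list(list(start = c(7, 15, 15),
                                         end = c(57, 15, 15), radius = 5)),
                               grid_shape = c(64, 30, 30))
  dmc <- distance_map(cap$truth$phase_map)
  expect_gte(max(dmc), 4.5); expect_lte(max(dmc), 5.5)

  # brute-force oracle on random 15^3 fields
  set.seed(11)
  for (rep in 1:3) {
    m <- array(runif(3375) < 0.5, c(15, 15, 15))
    expect_equal(distance_map(m)^2, oracle_edt_sq(m), tolerance = 1e-12)
  }
})

test_that("network extraction recovers tube-phantom topology and geometry", {
  # straight capsule: 2 endpoints, 1 edge; lengths and throat from truth
  cap <- generate_tube_phantom(list(list(start = c(7, 15, 15),
                                         end = c(57, 15, 15), radius = 5)),
                               grid_shape = c(64, 30, 30))
  g <- extract_network(skeletonize(cap$truth$phase_map),
                       distance_map(cap$truth$phase_map), 1)
  expect_equal(nrow(g$nodes), 2L)
  expect_equal(nrow(g$edges), 1L)
  expect_setequal(g$nodes$type, "endpoint")
  expect_lt(abs(g$edges$path_length_um - 50), 3)
  expect_lt(abs(g$edges$throat_diameter_um - 10) / 10, 0.10)

  # Y junction: 1 junction with coordination 3, 3 endpoints, 3 edges
  y <- generate_tube_phantom(list(
    list(start = c(30, 30, 10), end = c(30, 30, 40), radius = 4),
    list(start = c(30, 30, 40), end = c(12, 30, 60), radius = 4),
    list(start = c(30, 30, 40), end = c(48, 30, 60), radius = 4)),
    grid_shape = c(60, 60, 70))
  gy <- extract_network(skeletonize(y$truth$phase_map),
                        distance_map(y$truth$phase_map), 1)
  expect_equal(sum(gy$nodes$type == "junction"), 1L)
  expect_equal(sum(gy$nodes$type == "endpoint"), 3L)
  expect_equal(nrow(gy$edges), 3L)
  jn <- gy$nodes[gy$nodes$type == "junction", ]
  truth_j <- y$truth$junctions[1, ] + 0.5  # voxel-center physical coords
  expect_lt(sqrt(sum((c(jn$x_um, jn$y_um, jn$z_um) - truth_j)^2)), 2)
  # total skeleton path length within 5% of the truth centerline length
  expect_lt(abs(sum(gy$edges$path_length_um) - y$truth$total_length_vox) /
              y$truth$total_length_vox, 0.05)
  # pore length (body diameter) of equal-radius tubes: within 15% of 2r
  expect_lt(abs(network_stats(gy)$avg_pore_length_um - 8) / 8, 0.15)

  # mismatched shapes are rejected
  expect_error(extract_network(skeletonize(y$truth$phase_map),
                               array(0, c(3, 3, 3)), 1), "shapes")
})

test_that("an isolated round void collapses to one node with coordination 0", {
  ball <- fixture_ball(8)
  g <- extract_network(skeletonize(ball), distance_map(ball), 1)
  expect_equal(nrow(g$nodes), 1L)
  expect_equal(nrow(g$edges), 0L)
  expect_identical(g$nodes$type, "isolated")
  st <- network_stats(g)
  expect_equal(st$avg_coordination, 0)
  expect_equal(st$max_coordination, 0)
})

test_that("degree sums, empty graphs and hand-built stats behave", {
  # sum of node degrees = 2 * edge count on tube networks
  y <- generate_tube_phantom(list(
    list(start = c(20, 20, 5), end = c(20, 20, 30), radius = 3),
    list(start = c(20, 20, 30), end = c(8, 20, 44), radius = 3),
    list(start = c(20, 20, 30), end = c(32, 20, 44), radius = 3)),
    grid_shape = c(40, 40, 50))
  g <- extract_network(skeletonize(y$truth$phase_map),
                       distance_map(y$truth$phase_map), 1)
  expect_equal(sum(g$nodes$degree), 2L * nrow(g$edges))
  # throat diameter never exceeds twice the larger adjacent body radius
  lim <- 2 * pmax(g$nodes$body_radius_um[g$edges$node_a],
                  g$nodes$body_radius_um[g$edges$node_b])
  expect_true(all(g$edges$throat_diameter_um <= lim + 1e-9))

  # empty pore phase: empty graph, all-zero stats
  e <- extract_network(skeletonize(array(FALSE, c(5, 5, 5))),
                       distance_map(array(FALSE, c(5, 5, 5))), 1)
  st0 <- network_stats(e)
  expect_equal(st0$n_nodes, 0L)
  expect_equal(st0$avg_coordination, 0)

  # hand-built graph: degrees {3,1,1,1} -> avg 1.5, max 3
  hand <- structure(list(
    nodes = data.frame(id = 1:4, x_um = 0, y_um = 0, z_um = 0,
                       type = c("junction", rep("endpoint", 3)),
                       body_radius_um = c(4, 2, 2, 2), degree = c(3L, 1L, 1L, 1L)),
    edges = data.frame(node_a = 1L, node_b = 2:4,
                       path_length_um = c(10, 12, 14),
                       throat_diameter_um = c(3, 3, 4),
                       throat_length_um = c(5, 7, 9)),
    paths = list(), voxel_size_um = 1), class = "skeleton_graph")
  st <- network_stats(hand)
  expect_equal(st$avg_coordination, 1.5)
  expect_equal(st$max_coordination, 3L)
  expect_equal(st$avg_throat_length_um, 7)
  expect_equal(st$avg_pore_length_um, mean(2 * c(4, 2, 2, 2)))
})

test_that("skeleton statistics are invariant under 90-degree rotations", {
  y <- generate_tube_phantom(list(
    list(start = c(20, 20, 5), end = c(20, 20, 30), radius = 3),
    list(start = c(20, 20, 30), end = c(8, 20, 44), radius = 3),
    list(start = c(20, 20, 30), end = c(32, 20, 44), radius = 3)),
    grid_shape = c(40, 40, 50))
  pore <- y$truth$phase_map$phase == 2L
  g1 <- extract_network(skeletonize(pore), distance_map(pore), 1)
  rot <- aperm(pore, c(3, 2, 1))  # 90-degree rotation in the x-z plane
  g2 <- extract_network(skeletonize(rot), distance_map(rot), 1)
  expect_equal(nrow(g2$nodes), nrow(g1$nodes))
  expect_equal(nrow(g2$edges), nrow(g1$edges))
  expect_lt(abs(sum(g2$edges$path_length_um) - sum(g1$edges$path_length_um)),
            2)  # within a couple of voxel steps
})
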