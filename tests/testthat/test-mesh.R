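# Torus triangulation, clipping, the triangle/triangle test against the
# brute-force oracle, and the pairwise intersection components.

test_that("torus triangulation has the right combinatorics and sits on the surface", {
  tor <- pg_torus(c(1, -2, 0.5), c(0, 0, 1), 5, 0.3)
  for (res in list(c(240L, 24L), c(16L, 8L))) {
    m <- triangulate_torus(tor, res[1], res[2])
    expect_equal(nrow(m$vertices), res[1] * res[2])
    expect_equal(nrow(m$triangles), 2L * res[1] * res[2])
    expect_lt(max(point_torus_distance(m$vertices, tor)), 1e-9)
    # closed surface: every edge shared by exactly two triangles
    e <- rbind(m$triangles[, 1:2], m$triangles[, 2:3], m$triangles[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    expect_true(all(table(key) == 2))
  }
  expect_error(triangulate_torus(tor, 4, 24))
})

test_that("clipping keeps triangles with a vertex inside the region", {
  tor_in <- pg_torus(c(0, 0, 0), c(0, 0, 1), 3, 0.3)
  m <- triangulate_torus(tor_in, 60, 12)
  expect_equal(nrow(clip_mesh_to_region(m, pg_region(8))$triangles),
               nrow(m$triangles))

  tor_big <- pg_torus(c(0, 0, 0), c(0, 0, 1), 10, 0.3)
  mb <- triangulate_torus(tor_big, 120, 12)
  # all surface points lie at |p| >= R - r = 9.7: fully outside a radius-8 ball
  expect_equal(nrow(clip_mesh_to_region(mb, pg_region(8))$triangles), 0L)
  # a region radius cutting through the tube keeps a strict fraction,
  # matching a brute-force vertex containment count
  cl <- clip_mesh_to_region(mb, pg_region(9.9))
  frac <- nrow(cl$triangles) / nrow(mb$triangles)
  expect_gt(frac, 0)
  expect_lt(frac, 1)
  inside <- sqrt(rowSums(mb$vertices^2)) <= 9.9
  brute <- sum(inside[mb$triangles[, 1]] | inside[mb$triangles[, 2]] |
                 inside[mb$triangles[, 3]])
  expect_equal(nrow(cl$triangles), brute)
  # clipped vertices are re-indexed consistently
  expect_lt(max(point_torus_distance(cl$vertices, tor_big)), 1e-9)
})

test_that("triangle/triangle test returns the plane-interval segment", {
  t1 <- rbind(c(-1, -1, 0), c(1, -1, 0), c(0, 2, 0))   # plane z = 0
  t2 <- rbind(c(0, -0.5, -1), c(0, 0.5, -1), c(0, 0, 2))  # plane x = 0
  hit <- tri_tri_intersect(t1, t2)
  expect_false(hit$coplanar)
  expect_lt(max(abs(hit$segment[, c(1, 3)])), 1e-12)  # on the line x = z = 0

  expect_null(tri_tri_intersect(t1, t2 + 10))
  # shared vertex: touching counts as a zero-length contact
  t3 <- rbind(c(0, 2, 0), c(3, 5, 1), c(3, 4, -1))
  touch <- tri_tri_intersect(t1, t3)
  expect_false(is.null(touch))
  expect_lt(sum((touch$segment[1, ] - touch$segment[2, ])^2), 1e-18)
  # coplanar overlap is flagged, with no segment geometry
  cop <- tri_tri_intersect(t1, t1 * 0.5)
  expect_true(cop$coplanar)
  expect_null(cop$segment)
  expect_error(tri_tri_intersect(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)), t1),
               "degenerate")
})

test_that("triangle test agrees with the brute-force clipping oracle", {
  set.seed(123)
  n <- 2000
  a1 <- matrix(rnorm(9 * n), n, 9)
  a2 <- matrix(rnorm(9 * n), n, 9)
  fast <- pgrange:::cpp_tri_tri_batch(a1, a2)
  slow <- vapply(seq_len(n), function(k) {
    oracle_tri_tri(matrix(a1[k, ], 3, 3, byrow = TRUE),
                   matrix(a2[k, ], 3, 3, byrow = TRUE))
  }, logical(1))
  expect_identical(fast, slow)
  expect_gt(mean(fast), 0.02)  # the sample exercises both outcomes
  expect_lt(mean(fast), 0.98)
})

test_that("tori from couples sharing an emission point intersect near it", {
  set.seed(11)
  p0 <- c(0.3, -0.2, 0.1)
  m1 <- clip_mesh_to_region(triangulate_torus(make_noise_free_torus(p0)),
                            pg_region(8))
  m2 <- clip_mesh_to_region(triangulate_torus(make_noise_free_torus(p0)),
                            pg_region(8))
  comps <- torus_pair_intersection_positions(m1, m2)
  expect_gte(length(comps), 1)
  dmin <- min(vapply(comps, function(cc)
    sqrt(sum((cc$centroid - p0)^2)), numeric(1)))
  expect_lt(dmin, 0.3)

  # symmetry in the arguments
  comps_rev <- torus_pair_intersection_positions(m2, m1)
  expect_equal(length(comps_rev), length(comps))
  for (cc in comps) {
    d <- min(vapply(comps_rev, function(rr)
      sqrt(sum((rr$centroid - cc$centroid)^2)), numeric(1)))
    expect_lt(d, 0.1)
  }
})

test_that("disjoint and identical torus meshes yield no components", {
  t1 <- pg_torus(c(0, 0, 0), c(0, 0, 1), 2, 0.3)
  t2 <- pg_torus(c(50, 0, 0), c(0, 0, 1), 2, 0.3)
  m1 <- triangulate_torus(t1, 60, 12)
  m2 <- triangulate_torus(t2, 60, 12)
  expect_length(torus_pair_intersection_positions(m1, m2), 0)
  expect_warning(res <- torus_pair_intersection_positions(m1, m1),
                 "identical")
  expect_length(res, 0)
})

test_that("perpendicular tube crossing yields the two components the voxel oracle finds", {
  t1 <- pg_torus(c(0, 0, 0), c(0, 0, 1), 1, 0.15)
  t2 <- pg_torus(c(0, 1, 1), c(1, 0, 0), 1, 0.3)
  comps <- torus_pair_intersection_positions(triangulate_torus(t1, 240, 24),
                                             triangulate_torus(t2, 240, 24))
  expect_length(comps, 2)

  # brute-force voxelised surface-proximity oracle around the crossing
  g <- seq(-0.6, 0.6, by = 0.02)
  gr <- as.matrix(expand.grid(x = g, y = g + 1, z = g))
  near <- gr[point_torus_distance(gr, t1) < 0.02 &
               point_torus_distance(gr, t2) < 0.02, , drop = FALSE]
  cl <- cutree(hclust(dist(near), method = "single"), h = 0.05)
  expect_equal(length(unique(cl)), 2L)
  # each mesh component centroid matches one oracle blob centroid (the
  # centroid of an intersection loop lies off the surface, so blobs are
  # compared centre to centre)
  blob_centres <- t(vapply(unique(cl), function(g)
    colMeans(near[cl == g, , drop = FALSE]), numeric(3)))
  for (cc in comps)
    expect_lt(min(sqrt(rowSums(sweep(blob_centres, 2, cc$centroid)^2))), 0.1)
})

test_that("component centroids converge under mesh refinement", {
  set.seed(5)
  p0 <- c(0.2, 0.4, -0.3)
  tor1 <- make_noise_free_torus(p0)
  tor2 <- make_noise_free_torus(p0)
  reg <- pg_region(8)
  coarse <- torus_pair_intersection_positions(
    clip_mesh_to_region(triangulate_torus(tor1, 240, 24), reg),
    clip_mesh_to_region(triangulate_torus(tor2, 240, 24), reg))
  fine <- torus_pair_intersection_positions(
    clip_mesh_to_region(triangulate_torus(tor1, 480, 48), reg),
    clip_mesh_to_region(triangulate_torus(tor2, 480, 48), reg))
  expect_gte(length(fine), length(coarse))
  for (cc in coarse) {
    d <- min(vapply(fine, function(ff)
      sqrt(sum((ff$centroid - cc$centroid)^2)), numeric(1)))
    expect_lt(d, 0.05)
  }
})
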