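test_that("segment sampling includes endpoints and respects the step", {
  seg <- segment(c(0, 0, 0), c(10, 0, 0))
  pts <- sample_segment(seg, 1)
  expect_identical(nrow(pts), 11L)
  expect_equal(pts[, 1], 0:10)
  expect_equal(pts[11, ], c(10, 0, 0))

  # step larger than the segment: just the two endpoints
  pts2 <- sample_segment(seg, 25)
  expect_identical(nrow(pts2), 2L)
  expect_equal(pts2, rbind(c(0, 0, 0), c(10, 0, 0)))

  # samples are collinear and at most one step apart
  seg3 <- segment(c(1, 2, 3), c(4, 8, -2))
  pts3 <- sample_segment(seg3, 0.7)
  gaps <- sqrt(rowSums(diff(pts3)^2))
  expect_lte(max(gaps), 0.7 + 1e-12)
  d <- sweep(pts3, 2, seg3$p0)
  proj <- (d %*% seg3$dir) %*% t(seg3$dir)
  expect_lt(max(sqrt(rowSums((d - proj)^2))), 1e-9)

  expect_error(segment(c(1, 1, 1), c(1, 1, 1)), class = "npl_geometry_error")
  expect_error(sample_segment(seg, 0), class = "npl_geometry_error")
})

test_that("segment-mask intersection agrees with dense sampling away from surfaces", {
  g <- voxel_grid(c(24, 24, 24), c(1.5, 1, 2))
  mask <- grid_mask(g, function(X, Y, Z)
    (X - 16)^2 + (Y - 12)^2 + (Z - 20)^2 <= 36 |
    (X >= 5 & X <= 9 & Y >= 3 & Y <= 20 & Z >= 10 & Z <= 30))

  # clear hit and clear miss
  expect_true(segment_intersects(mask, g, segment(c(0, 12, 20), c(34, 12, 20))))
  expect_false(segment_intersects(mask, g, segment(c(0, 0, 0), c(34, 0, 0))))
  expect_warning(
    expect_false(segment_intersects(mask, g, segment(c(100, 100, 100), c(120, 100, 100)))),
    class = "npl_warning")

  set.seed(42)
  lo <- g$origin; hi <- g$origin + g$spacing * (g$shape - 1)
  n_disagree <- 0L
  for (i in 1:60) {
    p0 <- runif(3, lo, hi); p1 <- runif(3, lo, hi)
    if (sqrt(sum((p1 - p0)^2)) < 1) next
    seg <- segment(p0, p1)
    coarse <- segment_intersects(mask, g, seg)
    fine <- segment_intersects(mask, g, seg, step = min(g$spacing) / 20)
    if (coarse != fine) {
      n_disagree <- n_disagree + 1L
      # disagreements only happen when the segment grazes the surface
      clear <- oracle_segment_clearance(mask, g, p0, p1, step = 0.05)
      expect_lte(clear, half_diag(g))
    }
  }
  expect_lte(n_disagree, 6L)
})

test_that("the distance transform is exact", {
  # 3-4-5 triangle at unit spacing
  g <- voxel_grid(c(10, 10, 10))
  mask <- array(FALSE, dim = g$shape); mask[3, 3, 3] <- TRUE
  f <- distance_transform(mask, g)
  expect_identical(f$values[3, 3, 3], 0)
  expect_equal(f$values[6, 7, 3], 5.0)

  # plane of marked voxels at z = 0 with spacing (1, 1, 2): k = 2 is 4 mm away
  g2 <- voxel_grid(c(6, 6, 6), c(1, 1, 2))
  mask2 <- array(FALSE, dim = g2$shape); mask2[, , 1] <- TRUE
  f2 <- distance_transform(mask2, g2)
  expect_equal(f2$values[4, 2, 3], 4.0)
  expect_true(all(f2$values[, , 1] == 0))

  expect_error(distance_transform(array(FALSE, c(3, 3, 3)), voxel_grid(c(3, 3, 3))),
               class = "npl_config_error")
})

test_that("the distance transform matches brute-force search on random volumes", {
  for (seed in 1:4) {
    set.seed(seed)
    sh <- sample(3:14, 3, replace = TRUE)
    sp <- runif(3, 0.5, 3)
    g <- voxel_grid(sh, sp)
    mask <- array(runif(prod(sh)) < 0.08, dim = sh)
    if (!any(mask)) mask[1, 1, 1] <- TRUE
    f <- distance_transform(mask, g)
    expect_equal(f$values, oracle_edt(mask, g), tolerance = 1e-9)
  }
})

test_that("minimum clearance along a segment matches the field", {
  g <- voxel_grid(c(20, 20, 20))
  mask <- array(FALSE, dim = g$shape); mask[, , 1] <- TRUE   # plane z = 0
  f <- distance_transform(mask, g)
  seg <- segment(c(2, 3, 7), c(15, 12, 7))   # parallel to the plane at 7 mm
  expect_equal(min_distance_along_segment(f, seg), 7, tolerance = 1e-9)
  seg0 <- segment(c(2, 3, 0), c(15, 12, 5))  # touches the structure
  expect_equal(min_distance_along_segment(f, seg0), 0, tolerance = 1e-9)

  # refinement: coarse minimum within one step of the dense minimum (Lipschitz)
  set.seed(7)
  mask2 <- array(runif(8000) < 0.03, dim = g$shape)
  mask2[1, 1, 1] <- TRUE
  f2 <- distance_transform(mask2, g)
  for (i in 1:20) {
    p0 <- runif(3, 0, 19); p1 <- runif(3, 0, 19)
    if (sqrt(sum((p1 - p0)^2)) < 1) next
    seg <- segment(p0, p1)
    coarse <- min_distance_along_segment(f2, seg, step = 0.5)
    dense <- min_distance_along_segment(f2, seg, step = 0.05)
    expect_lte(abs(coarse - dense), 0.5)
    expect_gte(coarse, dense - 1e-9)  # denser sampling can only find smaller minima
  }
})

test_that("capsule crossing is located to within tolerance", {
  g <- voxel_grid(c(30, 30, 30))
  # liver = half space i >= 10; rasterized boundary at x = 9.5
  liver <- grid_mask(g, function(X, Y, Z) X >= 10)
  seg <- segment(c(2, 15, 15), c(25, 15, 15))
  cr <- capsule_crossing(liver, g, seg)
  expect_false(cr$degenerate)
  expect_lt(abs(cr$point[1] - 9.5), 0.1)
  expect_equal(cr$point[2:3], c(15, 15))

  # segment starting inside the liver is degenerate
  cr2 <- capsule_crossing(liver, g, segment(c(15, 15, 15), c(25, 15, 15)))
  expect_true(cr2$degenerate)
  expect_equal(cr2$point, c(15, 15, 15))

  # segment that never enters the liver
  expect_error(capsule_crossing(liver, g, segment(c(1, 15, 15), c(5, 15, 15))),
               class = "npl_no_crossing")

  # radial ray into a rasterized sphere: crossing radius within half a voxel
  # diagonal (rasterization) plus the bisection tolerance of the true radius
  gs <- voxel_grid(c(40, 40, 40))
  ctr <- c(19.5, 19.5, 19.5); R <- 12
  sphere <- grid_mask(gs, function(X, Y, Z)
    (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <= R^2)
  for (u in list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1) / sqrt(3), c(-1, 2, 0.5) / sqrt(5.25))) {
    seg <- segment(ctr + 19 * u, ctr)
    cr <- capsule_crossing(sphere, gs, seg)
    r_cross <- sqrt(sum((cr$point - ctr)^2))
    expect_lt(abs(r_cross - R), half_diag(gs) + 0.1)
  }
})

test_that("surface normals match analytic directions", {
  g <- voxel_grid(c(30, 30, 30))
  slab <- grid_mask(g, function(X, Y, Z) Z <= 14)
  n <- surface_normal(slab, g, c(15, 15, 14.5))
  expect_equal(sqrt(sum(n^2)), 1, tolerance = 1e-9)
  ang <- acos(abs(sum(n * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 2)
  expect_gt(n[3], 0)  # outward = away from the slab interior

  gs <- voxel_grid(c(40, 40, 40))
  ctr <- c(19.5, 19.5, 19.5); R <- 12
  sphere <- grid_mask(gs, function(X, Y, Z)
    (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <= R^2)
  for (u in list(c(1, 0, 0), c(0, 0, -1), c(1, 1, 1) / sqrt(3), c(2, -1, 0.5) / sqrt(5.25))) {
    n <- surface_normal(sphere, gs, ctr + R * u)
    ang <- acos(pmin(abs(sum(n * u)), 1)) * 180 / pi
    expect_lt(ang, 3)
    expect_gt(sum(n * u), 0)  # outward
  }
})

test_that("capsule angles agree with analytic values on slabs", {
  g <- voxel_grid(c(40, 40, 40))
  liver <- grid_mask(g, function(X, Y, Z) Z >= 20)
  # perpendicular insertion
  a90 <- capsule_angle(liver, g, segment(c(20, 20, 5), c(20, 20, 35)))
  expect_lt(abs(a90 - 90), 2)
  # 45 degree insertion
  a45 <- capsule_angle(liver, g, segment(c(5, 20, 5), c(33, 20, 33)))
  expect_lt(abs(a45 - 45), 3)
  # shallow insertion at 30 degrees to the surface
  d <- c(cos(30 * pi / 180), 0, sin(30 * pi / 180))
  p1 <- c(4, 20, 12) + 26 * d
  a30 <- capsule_angle(liver, g, segment(c(4, 20, 12), p1))
  expect_lt(abs(a30 - 30), 3)
})
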