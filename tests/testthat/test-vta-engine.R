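test_that("activating function is the peak interior second difference", {
  expect_equal(activating_function(c(0, -1, 0)), 2)
  # any linear ramp has zero second difference
  expect_equal(activating_function(0.3 * (1:9) + 2), 0)
  v <- c(-0.1, -0.5, -0.9, -0.4, -0.2)
  expect_equal(activating_function(2 * v), 2 * activating_function(v))
  expect_error(activating_function(c(1, 2)), "3 nodes")
})

test_that("calibration hits the single-electrode anchor radius", {
  model <- test_model()
  expect_equal(model$calibration_anchor$radius, 3.0)
  v <- build_micc(c("2" = -100), model$calibration_anchor$amplitude)
  cs <- cross_section(v, test_z0())
  expect_equal(vta_radius(cs, equal_area_bisector(cs)), 3.0,
               tolerance = 0.026)
})

test_that("single-electrode radius is non-decreasing over the anchor amplitude series", {
  model <- test_model()
  z0 <- test_z0()
  radii <- vapply(anchor_amplitudes()$single_mA, function(a) {
    cs <- cross_section(build_micc(c("2" = -100), a), z0)
    vta_radius(cs, equal_area_bisector(cs))
  }, numeric(1))
  expect_true(all(diff(radii) >= 0))
})

test_that("zero amplitude yields an empty VTA; growth in amplitude is monotone", {
  model <- test_model()
  v0 <- build_micc(c("2" = -50, "3" = -50), 0)
  expect_equal(v0$n_voxels, 0)
  expect_equal(vta_volume(v0), 0)
  v1 <- build_micc(c("2" = -70, "3" = -30), 1.2)
  v2 <- build_micc(c("2" = -70, "3" = -30), 2.9)
  expect_true(all(v1$keys %in% v2$keys))  # exact subset (linearity)
  expect_lt(v1$n_voxels, v2$n_voxels)
})

test_that("equal split is mirror-symmetric about the 60-degree half-plane", {
  v <- build_micc(c("2" = -50, "3" = -50), 2.4)
  m <- steering_metrics(v, test_z0(), expected = 60)
  expect_equal(m$rotation_deg, 60)
  expect_equal(m$deviation_deg, 0)
  # active lattice points map onto themselves under the reflection
  ap <- v$active_points
  key <- function(p, r, z) paste(round(r, 6), round(z, 6), round(p %% 360, 6))
  expect_setequal(key(ap$plane_deg, ap$r, ap$z_offset),
                  key(120 - ap$plane_deg, ap$r, ap$z_offset))
})

test_that("swapped fractionalizations are mirror images", {
  a <- build_micc(c("2" = -70, "3" = -30), 2.2)
  b <- build_micc(c("2" = -30, "3" = -70), 2.2)
  ra <- steering_metrics(a, test_z0())$rotation_deg
  rb <- steering_metrics(b, test_z0())$rotation_deg
  # reflection about the 60-degree half-plane maps one onto the other
  expect_equal((ra + rb) %% 360, 120, tolerance = 1)
  expect_equal(vta_volume(a), vta_volume(b), tolerance = 0.02 * vta_volume(a))
  # voxel sets agree after reflecting the active points
  bp <- b$active_points
  bp$plane_deg <- (120 - bp$plane_deg) %% 360
  key <- function(p) paste(round(p$r, 6), round(p$z_offset, 6),
                           round(p$plane_deg %% 360, 6))
  expect_setequal(key(a$active_points), key(bp))
})

test_that("VTA radius agrees with a dense 1-D scan of the same field model", {
  model <- test_model()
  geom <- test_geometry()
  grid <- test_grid()
  for (amp in c(1.0, 1.6, 2.6)) {
    src <- make_sources(geom, c("2" = -100), amp)
    # dense 1-D scan: axons along the steering direction (0 degrees)
    rr <- seq(grid$inner_radial_margin, grid$radial_extent, by = 0.01)
    lat <- data.frame(x = rr, y = 0, z = test_z0(), plane_deg = 0, r = rr,
                      z_offset = 0, tx = 0, ty = 1)
    af <- compute_af(src, grid, test_tissue(), lat)
    r_dense <- max(rr[af >= model$af_threshold])
    v <- build_vta(src, model, grid)
    cs <- cross_section(v, test_z0())
    r_vox <- vta_radius(cs, equal_area_bisector(cs))
    # lattice quantization bounds the disagreement by half a lattice step
    expect_lt(abs(r_vox - r_dense), grid$grid_spacing / 2 + 0.06)
  }
})

test_that("titration converges to lattice-attainable target radii", {
  model <- test_model()
  for (target in c(2, 3, 4)) {
    ti <- titrate_amplitude(c("2" = -50, "3" = -50), target, "micc", model,
                            test_geometry(), test_grid())
    expect_true(ti$converged)
    expect_equal(ti$achieved_radius, target, tolerance = 0.026)
  }
  # single electrode to the anchor radius recovers the anchor amplitude
  ti <- titrate_amplitude(c("2" = -100, "3" = 0), 3, "micc", model,
                          test_geometry(), test_grid())
  expect_equal(ti$total_amplitude, 1.6, tolerance = 0.011)
})

test_that("off-grid targets stop on the amplitude interval and record the radius", {
  model <- test_model()
  ti <- titrate_amplitude(c("2" = -50, "3" = -50), 2.25, "micc", model,
                          test_geometry(), test_grid())
  # contract: either the radius converged or the interval did
  expect_true(ti$converged || ti$iterations > 0)
  expect_gte(ti$achieved_radius, 2.25 - 0.026)
  expect_error(
    titrate_amplitude(c("2" = -50, "3" = -50), 30, "micc", model,
                      test_geometry(), test_grid()),
    "not bracketable")
})

test_that("titrated amplitude is non-decreasing in target radius (sweep oracle)", {
  model <- test_model()
  amps <- vapply(c(2, 2.5, 3, 3.5, 4), function(r) {
    titrate_amplitude(c("2" = -60, "3" = -40), r, "micc", model,
                      test_geometry(), test_grid())$total_amplitude
  }, numeric(1))
  expect_true(all(diff(amps) > 0))
  # brute-force amplitude sweep: radius is non-decreasing in amplitude
  src <- make_sources(test_geometry(), c("2" = -60, "3" = -40), 1)
  lat <- axon_lattice(test_geometry(), test_grid())
  lat0 <- lat[lat$z_offset == 0, ]
  af <- compute_af(src, test_grid(), test_tissue(), lat0)
  radii <- vapply(seq(0.5, 6, by = 0.25), function(a) {
    pts <- lat0[af * a >= model$af_threshold, ]
    if (nrow(pts) == 0) return(0)
    cs <- vtasteer:::cs_from_points(pts, 0.25, NA)
    max(cs$radii[colSums(cs$occupancy) > 0]) + cs$radial_step / 2
  }, numeric(1))
  expect_true(all(diff(radii) >= 0))
})

test_that("interleaved VTAs of an equal split are 120-degree rotated copies", {
  model <- test_model()
  pr <- build_interleaving_vtas(c("2" = -50, "3" = -50), 3.0, model,
                                test_geometry(), test_grid())
  expect_false(is.null(pr$vta2))
  expect_equal(vta_volume(pr$vta1), vta_volume(pr$vta2),
               tolerance = 0.02 * vta_volume(pr$vta1))
  r1 <- steering_metrics(pr$vta1, test_z0())$rotation_deg
  r2 <- steering_metrics(pr$vta2, test_z0())$rotation_deg
  expect_equal((r2 - r1) %% 360, 120, tolerance = 1)
  # rotating vta1's active points by 120 degrees reproduces vta2's
  p1 <- pr$vta1$active_points
  p1$plane_deg <- (p1$plane_deg + 120) %% 360
  key <- function(p) paste(round(p$r, 6), round(p$z_offset, 6),
                           round(p$plane_deg %% 360, 6))
  expect_setequal(key(p1), key(pr$vta2$active_points))
})

test_that("a zero-amplitude program yields an absent second VTA", {
  pr <- build_interleaving_vtas(c("2" = -100, "3" = 0), 2.0, test_model(),
                                test_geometry(), test_grid())
  expect_false(is.null(pr$vta1))
  expect_null(pr$vta2)
})

test_that("union and intersection obey set algebra", {
  a <- random_blob(seed = 11)
  b <- random_blob(seed = 12)
  expect_equal(vta_union(a, a)$keys, a$keys)
  expect_equal(vta_intersection(a, a)$keys, a$keys)
  # inclusion-exclusion against brute-force enumeration
  u <- vta_union(a, b)
  i <- vta_intersection(a, b)
  expect_equal(u$n_voxels + i$n_voxels, a$n_voxels + b$n_voxels)
  expect_equal(sort(u$keys), sort(union(a$keys, b$keys)))
  expect_equal(sort(i$keys), sort(intersect(a$keys, b$keys)))
  expect_true(all(i$keys %in% a$keys) && all(i$keys %in% b$keys))
  # disjoint sets intersect to nothing
  far <- vta_from_voxels(cbind(100:104, 0, 0), 0.1)
  expect_equal(vta_intersection(a, far)$n_voxels, 0)
  # mismatched grids error
  expect_error(vta_union(a, vta_from_voxels(cbind(1, 1, 1), 0.2)),
               "different voxel grids")
})

test_that("intersection VTA is contained in both; union contains both", {
  model <- test_model()
  pr <- build_interleaving_vtas(c("2" = -60, "3" = -40), 3.2, model,
                                test_geometry(), test_grid())
  u <- vta_union(pr$vta1, pr$vta2)
  i <- vta_intersection(pr$vta1, pr$vta2)
  expect_true(all(i$keys %in% pr$vta1$keys))
  expect_true(all(i$keys %in% pr$vta2$keys))
  expect_true(all(pr$vta1$keys %in% u$keys))
  expect_true(all(pr$vta2$keys %in% u$keys))
})
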