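# helpers constructing analytic voxel shapes on a 0.1 mm grid
disc_vta <- function(R, res = 0.1, k = 0) {
  n <- ceiling(R / res) + 1
  g <- expand.grid(i = -n:n, j = -n:n)
  c2 <- ((g$i + 0.5) * res)^2 + ((g$j + 0.5) * res)^2
  vta_from_voxels(cbind(g$i[c2 <= R^2], g$j[c2 <= R^2], k), res)
}

sector_vta <- function(from, to, R, res = 0.1, k = 0) {
  n <- ceiling(R / res) + 1
  g <- expand.grid(i = -n:n, j = -n:n)
  cx <- (g$i + 0.5) * res
  cy <- (g$j + 0.5) * res
  ang <- (atan2(cy, cx) * 180 / pi) %% 360
  keep <- cx^2 + cy^2 <= R^2 & ang >= from & ang < to
  vta_from_voxels(cbind(g$i[keep], g$j[keep], k), res)
}

test_that("cross-section flags empty slices and covers full discs", {
  empty <- vta_from_voxels(matrix(numeric(0), ncol = 3), 0.1)
  cs <- cross_section(empty, 0)
  expect_true(cs$empty)
  expect_error(equal_area_bisector(cs), "empty")

  d <- disc_vta(2)
  cs <- cross_section(d, 0.05)
  inner <- cs$radii < 2 - 0.1
  expect_true(all(cs$occupancy[, inner]))
})

test_that("polar occupancy area matches the voxel-slice area on random blobs", {
  for (seed in 1:3) {
    b <- random_blob(n = 400, spread = 15, seed = seed)
    cs <- cross_section(b, 0.05)  # layer k = 0
    # area of occupied polar cells: r * dr * dtheta
    polar_area <- sum((cs$occupancy %*% cs$radii) * cs$radial_step *
                        cs$angle_step * pi / 180)
    nvox <- sum(voxel_coords(b)[, "k"] == 0)
    expect_equal(polar_area, nvox * 0.1^2, tolerance = 2 * 0.1^2 / polar_area)
  }
})

test_that("equal-area bisector recovers analytic symmetry axes", {
  half <- sector_vta(0, 180, 2)
  expect_equal(equal_area_bisector(cross_section(half, 0.05)), 90)
  sec <- sector_vta(20, 100, 2)
  expect_equal(equal_area_bisector(cross_section(sec, 0.05)), 60)
})

test_that("returned bisector is the global minimum of the 1-degree sweep", {
  for (seed in 4:6) {
    b <- random_blob(n = 300, spread = 18, seed = seed)
    cs <- cross_section(b, 0.05)
    theta <- equal_area_bisector(cs) %% 180
    w <- as.vector(cs$occupancy %*% cs$radii)
    imb <- function(t) {
      inside <- ((cs$angles - t) %% 360) < 180
      abs(sum(w[inside]) - sum(w[!inside]))
    }
    all_imb <- vapply(0:179, imb, numeric(1))
    expect_equal(imb(theta), min(all_imb), tolerance = 1e-9)
  }
})

test_that("bisector is equivariant under rotation of the shape", {
  # same analytic sector rotated by 25 degrees
  a <- sector_vta(10, 130, 2.5)
  b <- sector_vta(35, 155, 2.5)
  ba <- equal_area_bisector(cross_section(a, 0.05))
  bb <- equal_area_bisector(cross_section(b, 0.05))
  expect_equal((bb - ba) %% 360, 25, tolerance = 1)
})

test_that("vta_radius matches the disc radius and a ray-marching oracle", {
  d <- disc_vta(1.8)
  cs <- cross_section(d, 0.05)
  expect_equal(vta_radius(cs, 77), 1.8, tolerance = 0.05)
  # empty direction reports zero
  sec <- sector_vta(20, 100, 2)
  expect_equal(vta_radius(cross_section(sec, 0.05), 200), 0)
  # brute-force ray marching on a random blob
  b <- random_blob(n = 300, spread = 18, seed = 9)
  cs <- cross_section(b, 0.05)
  keys <- cs$keys2
  for (ang in c(0, 33, 120, 251)) {
    rr <- seq(0.005, max(cs$radii) + 0.025, by = 0.005)
    xx <- floor(rr * cos(ang * pi / 180) / 0.1)
    yy <- floor(rr * sin(ang * pi / 180) / 0.1)
    hit <- vtasteer:::encode_voxels_2d(cbind(xx, yy)) %in% keys
    oracle <- if (any(hit)) max(rr[hit]) else 0
    expect_equal(vta_radius(cs, ang), oracle, tolerance = 0.055)
  }
})

test_that("expected rotation angles follow the linear proportion", {
  expect_equal(expected_rotation_angle(c("2" = -70, "3" = -30)), 36)
  expect_equal(expected_rotation_angle(c("2" = -100, "3" = 0)), 0)
  expect_equal(expected_rotation_angle(c("2" = -50, "3" = -50)), 60)
  expect_error(expected_rotation_angle(c("2" = -34, "3" = -33, "4" = -33)),
               "two-electrode")
})

test_that("rotation deviation wraps around the circle", {
  expect_equal(rotation_deviation(60, 60), 0)
  expect_equal(rotation_deviation(36, 29), 7)
  expect_equal(rotation_deviation(359, 1), 2)
})

test_that("volume counts voxels and matches a brute-force oracle", {
  empty <- vta_from_voxels(matrix(numeric(0), ncol = 3), 0.1)
  expect_equal(vta_volume(empty), 0)
  eight <- vta_from_voxels(expand.grid(i = 0:1, j = 0:1, k = 0:1), 0.5)
  expect_equal(vta_volume(eight), 1.0)
  for (seed in 1:3) {
    b <- random_blob(seed = seed)
    expect_equal(vta_volume(b), nrow(voxel_coords(b)) * 0.1^3)
  }
})

test_that("overlap percentages behave as set ratios", {
  a <- random_blob(seed = 21)
  expect_equal(overlap_percent(a, a), 100)
  far <- vta_from_voxels(cbind(200, 200, 0), 0.1)
  expect_equal(overlap_percent(a, far), 0)
  quarter <- vta_from_voxels(voxel_coords(a)[seq_len(a$n_voxels %/% 4), ], 0.1)
  expect_equal(overlap_percent(quarter, a), 100 * (a$n_voxels %/% 4) / a$n_voxels)
  b <- random_blob(seed = 22)
  expect_lte(overlap_percent(a, vta_union(a, b)), 100)
  expect_error(overlap_percent(a, vta_from_voxels(matrix(numeric(0), ncol = 3), 0.1)),
               "empty")
})
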