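#' Polar cross-section of a VTA
#'
#' Resamples the voxel layer containing `z_plane` (by convention the
#' vertical centre of the activated electrodes) onto a polar raster with
#' 1 degree angular and 0.05 mm radial steps. A polar cell is occupied
#' when its centre falls inside an occupied voxel.
#'
#' @param vta A `vta` object.
#' @param z_plane Height of the cross-section in mm.
#' @param angle_step Angular step in degrees.
#' @param radial_step Radial step in mm.
#' @return An object of class `cross_section` with the occupancy matrix
#'   (angles x radii), the sample angles and radii (cell centres) and an
#'   `empty` flag.
#' @export
cross_section <- function(vta, z_plane, angle_step = 1, radial_step = 0.05) {
  stopifnot(inherits(vta, "vta"))
  if (!is.null(vta$active_points)) {
    pts <- vta$active_points
    pts <- pts[abs(pts$z - z_plane) <= vta$half + .RAS_EPS, , drop = FALSE]
    return(cs_from_points(pts, vta$half, z_plane, angle_step, radial_step))
  }
  res <- vta$resolution
  k0 <- floor(z_plane / res)
  keys2 <- numeric(0)
  if (length(vta$keys) > 0) {
    ijk <- decode_voxels(vta$keys)
    sl <- ijk[ijk[, "k"] == k0, , drop = FALSE]
    if (nrow(sl) > 0) keys2 <- sort(encode_voxels_2d(sl[, c("i", "j"), drop = FALSE]))
  }
  cs_from_keys2d(keys2, res, z_plane, angle_step, radial_step)
}

#' Equal-area bisector angle of a cross-section
#'
#' Rotates a straight line through the lead axis in 1 degree steps and
#' returns the direction that divides the occupied cross-section area
#' into two equal parts. Cell areas are weighted by their radius (the
#' polar area element). Of the two directions of the bisecting line, the
#' one closer to the occupancy centroid is returned; ties are broken
#' toward the smaller angle. This direction is the VTA rotation angle.
#'
#' @param cs A [cross_section()].
#' @return Angle in degrees in `[0, 360)`.
#' @export
equal_area_bisector <- function(cs) {
  stopifnot(inherits(cs, "cross_section"))
  if (cs$empty) stop("cross-section is empty")
  w <- as.vector(cs$occupancy %*% cs$radii)  # area weight per angle
  n <- length(cs$angles)
  half <- n %/% 2
  total <- sum(w)
  cum <- cumsum(c(w, w))
  # left(theta_idx) = sum of w over the half-turn starting at theta_idx
  left <- cum[seq_len(half) + half - 1] - c(0, cum[seq_len(half - 1)])
  imbalance <- abs(2 * left - total)
  i_star <- which.min(imbalance)  # smallest angle wins ties
  theta <- (i_star - 1) * cs$angle_step  # split line through angle theta
  # occupancy centroid angle
  ang_rad <- cs$angles * pi / 180
  cx <- sum(w * cos(ang_rad))
  cy <- sum(w * sin(ang_rad))
  cand <- c(theta, (theta + 180) %% 360)
  if (cx == 0 && cy == 0) return(min(cand))
  c_ang <- (atan2(cy, cx) * 180 / pi) %% 360
  d <- vapply(cand, rotation_deviation, numeric(1), expected = c_ang)
  if (abs(d[1] - d[2]) < 1e-9) min(cand) else cand[which.min(d)]
}

#' Maximum occupied radius along a direction
#'
#' Marches a ray at the exact requested angle through the voxel layer in
#' radial-step increments and returns the outer edge of the outermost
#' occupied sample.
#'
#' @param cs A [cross_section()].
#' @param angle Direction in degrees, `[0, 360)`.
#' @return Radius in mm; 0 when nothing is occupied along the direction.
#' @export
vta_radius <- function(cs, angle) {
  stopifnot(inherits(cs, "cross_section"))
  if (cs$empty) return(0)
  r <- cs$radii
  if (identical(cs$method, "lattice")) {
    pts <- cs$points
    if (nrow(pts) == 0) return(0)
    occ <- rep(FALSE, length(r))
    for (p in seq_len(nrow(pts))) {
      delta <- (angle - pts$plane_deg[p] + 180) %% 360 - 180
      occ <- occ | covered_by_point(r, delta, pts$r[p], cs$half)
    }
  } else {
    a <- angle * pi / 180
    ii <- floor(r * cos(a) / cs$voxel_resolution)
    jj <- floor(r * sin(a) / cs$voxel_resolution)
    occ <- encode_voxels_2d(cbind(ii, jj)) %in% cs$keys2
  }
  if (!any(occ)) return(0)
  max(r[occ]) + cs$radial_step / 2
}

#' Expected rotation angle of a fractionalization
#'
#' Linear-proportion expectation for a two-electrode split between
#' adjacent segments 120 degrees apart: the fraction on the secondary
#' electrode times 120 degrees (so -50/-50 steers to 60 degrees and
#' -100/0 stays at 0).
#'
#' @param distribution Two-electrode fractionalization (named percent
#'   vector, e.g. `c("2" = -70, "3" = -30)`).
#' @return Expected angle in degrees.
#' @export
expected_rotation_angle <- function(distribution) {
  frac <- normalize_distribution(distribution)
  if (length(frac) != 2) {
    stop("expected rotation is defined for two-electrode fractionalizations")
  }
  unname(abs(frac[2])) / 100 * 120
}

#' Angular deviation on the circle
#'
#' Absolute difference between a measured and an expected angle, taking
#' the shorter way around the circle.
#'
#' @param measured,expected Angles in degrees.
#' @return Deviation in degrees, in `[0, 180]`.
#' @export
rotation_deviation <- function(measured, expected) {
  stopifnot(is.finite(measured), is.finite(expected))
  d <- abs(measured - expected) %% 360
  min(d, 360 - d)
}

#' VTA volume
#'
#' Sum of the volumes of the occupied voxels.
#'
#' @param vta A `vta` object.
#' @return Volume in mm^3.
#' @export
vta_volume <- function(vta) {
  stopifnot(inherits(vta, "vta"))
  vta$n_voxels * vta$resolution^3
}

#' Percentage of one VTA covered by another
#'
#' `100 * |a intersect b| / |b|`: the share of `b`'s volume that `a`
#' covers.
#'
#' @param a,b `vta` objects on the same voxel grid; `b` must be
#'   non-empty.
#' @return Percentage in `[0, 100]`.
#' @export
overlap_percent <- function(a, b) {
  check_same_grid(a, b)
  if (b$n_voxels == 0) stop("reference VTA is empty")
  100 * length(intersect(a$keys, b$keys)) / b$n_voxels
}

#' Steering metrics of a VTA
#'
#' Convenience wrapper computing the rotation angle (equal-area
#' bisector), metric radius, deviation from an expected angle, and
#' volume at the electrode-centre cross-section.
#'
#' @param vta A `vta` object.
#' @param z_plane Cross-section height in mm.
#' @param expected Expected rotation angle in degrees (optional).
#' @return List with `rotation_deg`, `radius_mm`, `deviation_deg`
#'   (`NA` without `expected`) and `volume_mm3`. Empty VTAs yield `NA`
#'   rotation and zero radius/volume.
#' @export
steering_metrics <- function(vta, z_plane, expected = NULL) {
  cs <- cross_section(vta, z_plane)
  if (cs$empty) {
    return(list(rotation_deg = NA_real_, radius_mm = 0,
                deviation_deg = NA_real_, volume_mm3 = vta_volume(vta)))
  }
  rot <- equal_area_bisector(cs)
  list(
    rotation_deg = rot,
    radius_mm = vta_radius(cs, rot),
    deviation_deg = if (is.null(expected)) NA_real_ else rotation_deviation(rot, expected),
    volume_mm3 = vta_volume(vta)
  )
}
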