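#' Axon sampling lattice specification
#'
#' Straight myelinated axons, oriented perpendicular to the lead shaft,
#' are sampled on two-dimensional matrices (planes containing the lead
#' axis) rotated around the lead in equal angular steps. Within a plane,
#' axons sit on a regular grid of radial distance x height with the given
#' spacing; each axon carries an odd number of nodes spaced along its
#' (tangential) direction. Radial positions start at the first multiple
#' of half the lattice spacing at or beyond the inner margin, so the
#' rasterized VTA boundary (lattice radius + half spacing) falls on the
#' 0.25 mm grid of the target radii.
#'
#' @param plane_angles Plane azimuths in degrees; must cover a full turn
#'   in equal steps (default 0 to 330 in 30 degree steps).
#' @param grid_spacing Lattice spacing within a plane in mm.
#' @param radial_extent Maximum radial distance sampled, in mm.
#' @param vertical_extent Total vertical extent sampled (centred on the
#'   active electrode level), in mm.
#' @param node_spacing Node spacing along each axon in mm (about the
#'   internodal length of a 5.7 um fibre).
#' @param nodes_per_axon Odd number of nodes per axon (>= 3).
#' @param inner_radial_margin Inner radial cutoff in mm; defaults to the
#'   shaft radius plus encapsulation thickness (tissue inside the
#'   encapsulation sheath is not sampled).
#' @return An object of class `axon_grid_spec`.
#' @export
axon_grid_spec <- function(plane_angles = seq(0, 330, by = 30),
                           grid_spacing = 0.5,
                           radial_extent = 6,
                           vertical_extent = 9,
                           node_spacing = 0.5,
                           nodes_per_axon = 21,
                           inner_radial_margin = 1.15) {
  stopifnot(grid_spacing > 0, node_spacing > 0,
            nodes_per_axon >= 3, nodes_per_axon %% 2 == 1,
            radial_extent > inner_radial_margin, vertical_extent > 0)
  steps <- diff(sort(plane_angles %% 360))
  if (length(plane_angles) < 2 ||
      any(abs(steps - 360 / length(plane_angles)) > 1e-9)) {
    stop("plane_angles must cover a full turn in equal steps")
  }
  structure(
    list(plane_angles = plane_angles, grid_spacing = grid_spacing,
         radial_extent = radial_extent, vertical_extent = vertical_extent,
         node_spacing = node_spacing, nodes_per_axon = as.integer(nodes_per_axon),
         inner_radial_margin = inner_radial_margin),
    class = "axon_grid_spec"
  )
}

#' Vertical centre of a directional level
#'
#' @param geometry A [lead_geometry()].
#' @param level Directional level id (`"1"` or `"2"`).
#' @return z coordinate in mm.
#' @export
level_z <- function(geometry, level = "1") {
  e <- geometry$electrodes[geometry$electrodes$level == level, ]
  if (nrow(e) == 0) stop("no such directional level: ", level)
  mean(e$z_center)
}

#' Build the axon lattice around a lead
#'
#' Enumerates the axon lattice points of an [axon_grid_spec()] around the
#' given directional level. Each lattice point is the centre node of a
#' straight axon running tangentially (perpendicular to the shaft and to
#' the radial direction).
#'
#' @param geometry A [lead_geometry()].
#' @param grid An [axon_grid_spec()].
#' @param level Directional level around which axons are centred.
#' @return Data frame with lattice point coordinates `x`,`y`,`z` (mm),
#'   plane azimuth `plane_deg`, radial distance `r`, vertical offset
#'   `z_offset` and tangent direction `tx`,`ty`.
#' @export
axon_lattice <- function(geometry, grid, level = "1") {
  stopifnot(inherits(grid, "axon_grid_spec"))
  z0 <- level_z(geometry, level)
  h <- grid$grid_spacing / 2
  r_first <- ceiling(grid$inner_radial_margin / h) * h
  radii <- seq(r_first, grid$radial_extent, by = grid$grid_spacing)
  zoff <- seq(-grid$vertical_extent / 2, grid$vertical_extent / 2,
              by = grid$grid_spacing)
  g <- expand.grid(plane_deg = grid$plane_angles, r = radii, z_offset = zoff,
                   KEEP.OUT.ATTRS = FALSE)
  a <- g$plane_deg * pi / 180
  data.frame(
    x = g$r * cos(a), y = g$r * sin(a), z = z0 + g$z_offset,
    plane_deg = g$plane_deg, r = g$r, z_offset = g$z_offset,
    tx = -sin(a), ty = cos(a)
  )
}

#' Peak activating function of an axon
#'
#' The activating function is the discrete second difference of the
#' extracellular potential along the axon's nodes,
#' `V[i-1] - 2 V[i] + V[i+1]`; its maximum over interior nodes predicts
#' where cathodic stimulation depolarizes the fibre. It is exactly linear
#' in the potentials (and hence in the stimulation amplitude).
#'
#' @param node_potentials Numeric vector of node potentials in volts
#'   (>= 3 nodes).
#' @return Peak activating function in volts.
#' @export
#' @examples
#' activating_function(c(0, -1, 0))  # 2
activating_function <- function(node_potentials) {
  v <- as.numeric(node_potentials)
  if (length(v) < 3) stop("an axon needs at least 3 nodes")
  n <- length(v)
  max(v[1:(n - 2)] - 2 * v[2:(n - 1)] + v[3:n])
}

#' Activating-function values over an axon lattice
#'
#' Evaluates the extracellular potential at every node of every lattice
#' axon for a source configuration and returns each axon's peak
#' activating function. Linear in the total amplitude, so values for one
#' amplitude can be rescaled to any other.
#'
#' @param sources A [make_sources()] configuration.
#' @param grid An [axon_grid_spec()].
#' @param tissue A [tissue_model()].
#' @param lattice Optional precomputed [axon_lattice()] (defaults to the
#'   full lattice of `grid` around level 1).
#' @return Numeric vector of peak activating-function values (volts), one
#'   per lattice row.
#' @export
compute_af <- function(sources, grid, tissue = tissue_model(), lattice = NULL) {
  if (is.null(lattice)) lattice <- axon_lattice(sources$geometry, grid)
  n_ax <- nrow(lattice)
  nn <- grid$nodes_per_axon
  if (n_ax == 0) return(numeric(0))
  offs <- (seq_len(nn) - (nn + 1) / 2) * grid$node_spacing
  nodes <- data.frame(
    x = rep(lattice$x, each = nn) + rep(lattice$tx, each = nn) * offs,
    y = rep(lattice$y, each = nn) + rep(lattice$ty, each = nn) * offs,
    z = rep(lattice$z, each = nn)
  )
  v <- potential_at(nodes, sources, tissue)
  vm <- matrix(v, nrow = nn)  # nodes x axons
  d2 <- vm[1:(nn - 2), , drop = FALSE] - 2 * vm[2:(nn - 1), , drop = FALSE] +
    vm[3:nn, , drop = FALSE]
  apply(d2, 2, max)
}

#' Activation model
#'
#' A single scalar activating-function threshold calibrated against an
#' (amplitude, radius) anchor of a single-electrode setting. A lattice
#' axon is considered activated when its peak activating function meets
#' or exceeds the threshold.
#'
#' @param af_threshold Threshold in volts (> 0).
#' @param calibration_anchor List with `amplitude` (mA) and `radius` (mm)
#'   used for calibration (metadata).
#' @param axon_diameter Fibre diameter in micrometres (metadata).
#' @return An object of class `activation_model`.
#' @export
activation_model <- function(af_threshold,
                             calibration_anchor = list(amplitude = 1.6, radius = 3.0),
                             axon_diameter = 5.7) {
  stopifnot(af_threshold > 0)
  structure(list(af_threshold = af_threshold,
                 calibration_anchor = calibration_anchor,
                 axon_diameter = axon_diameter),
            class = "activation_model")
}

# --- internal: cross-section machinery shared with vta_metrics ----------

# Polar cross-section machinery. Polar cells are sampled at their
# centres (half an angular and half a radial step off the origin), which
# keeps the raster symmetric under the reflections that map the axon
# lattice onto itself.
#
# Two occupancy backends exist:
#  * "lattice": directly against the continuous oriented-square
#    footprints of the active lattice points. A point's polar coverage
#    depends only on its radius, the sample radius and the half-width,
#    plus the angle relative to its plane, so mirror-image
#    configurations produce exactly mirrored occupancy (no voxel-grid
#    bias). Used for VTAs built from the axon lattice.
#  * "voxel": membership of sample centres in the rasterized voxel
#    layer. Used for VTAs given as raw voxel sets.

cs_structure <- function(occ, angles, radii, angle_step, radial_step,
                         z_plane, method, keys2 = NULL,
                         voxel_resolution = NA_real_, points = NULL,
                         half = NA_real_) {
  structure(
    list(occupancy = occ, angles = angles, radii = radii,
         angle_step = angle_step, radial_step = radial_step,
         voxel_resolution = voxel_resolution, keys2 = keys2,
         points = points, half = half,
         z_plane = z_plane, method = method, empty = !any(occ)),
    class = "cross_section"
  )
}

# occupancy of polar samples (vectors r_s, delta_deg relative to a
# point's plane azimuth) by the oriented square of half-width h centred
# at radius r_p in its plane
covered_by_point <- function(r_s, delta_deg, r_p, h) {
  d <- delta_deg * pi / 180
  u <- r_s * cos(d) - r_p   # radial offset in the point frame
  v <- r_s * sin(d)         # tangential offset
  abs(u) <= h + .RAS_EPS & abs(v) <= h + .RAS_EPS
}

cs_from_points <- function(pts, half, z_plane,
                           angle_step = 1, radial_step = 0.05,
                           radial_extent = NULL) {
  angles <- seq(angle_step / 2, 360, by = angle_step)
  reach <- half * sqrt(2)
  if (is.null(radial_extent)) {
    radial_extent <- if (nrow(pts) == 0) radial_step else
      max(pts$r) + reach + radial_step
  }
  radii <- seq(radial_step / 2, radial_extent, by = radial_step)
  occ <- matrix(FALSE, nrow = length(angles), ncol = length(radii))
  for (p in seq_len(nrow(pts))) {
    r_p <- pts$r[p]
    phi <- pts$plane_deg[p]
    ir <- which(radii >= r_p - reach - radial_step &
                  radii <= r_p + reach + radial_step)
    if (length(ir) == 0) next
    dmax <- asin(min(1, (half * sqrt(2) + .RAS_EPS) / max(r_p - reach, radial_step)))
    dmax <- dmax * 180 / pi + angle_step
    delta <- (angles - phi + 180) %% 360 - 180
    ia <- which(abs(delta) <= dmax)
    if (length(ia) == 0) next
    g_r <- rep(radii[ir], each = length(ia))
    g_d <- rep(delta[ia], times = length(ir))
    hit <- covered_by_point(g_r, g_d, r_p, half)
    occ[cbind(rep(ia, times = length(ir)), rep(ir, each = length(ia)))] <-
      occ[cbind(rep(ia, times = length(ir)), rep(ir, each = length(ia)))] | hit
  }
  cs_structure(occ, angles, radii, angle_step, radial_step, z_plane,
               method = "lattice", points = pts, half = half)
}

cs_from_keys2d <- function(keys2, voxel_resolution, z_plane,
                           angle_step = 1, radial_step = 0.05,
                           radial_extent = NULL) {
  angles <- seq(angle_step / 2, 360, by = angle_step)
  if (is.null(radial_extent)) {
    if (length(keys2) == 0) {
      radial_extent <- radial_step
    } else {
      rest <- keys2 %/% .VOX_M
      i <- rest - .VOX_B
      j <- keys2 %% .VOX_M - .VOX_B
      cx <- (i + 0.5) * voxel_resolution
      cy <- (j + 0.5) * voxel_resolution
      radial_extent <- max(sqrt(cx^2 + cy^2)) + voxel_resolution
    }
  }
  radii <- seq(radial_step / 2, radial_extent, by = radial_step)
  occ <- matrix(FALSE, nrow = length(angles), ncol = length(radii))
  if (length(keys2) > 0) {
    g_ang <- rep(angles, times = length(radii)) * pi / 180
    g_r <- rep(radii, each = length(angles))
    ii <- floor(g_r * cos(g_ang) / voxel_resolution)
    jj <- floor(g_r * sin(g_ang) / voxel_resolution)
    kk <- encode_voxels_2d(cbind(ii, jj))
    occ[] <- kk %in% keys2
  }
  cs_structure(occ, angles, radii, angle_step, radial_step, z_plane,
               method = "voxel", keys2 = keys2,
               voxel_resolution = voxel_resolution)
}

# metric radius of a set of active axon points at one z layer:
# rasterize to a 2-D voxel layer, find the equal-area bisector and return
# the maximum occupied radius along it (or the overall maximum radius).
slice_metric_radius <- function(pts, half, voxel_resolution,
                                control = c("max", "bisector")) {
  control <- match.arg(control)
  cs <- cs_from_points(pts, half, z_plane = NA)
  if (cs$empty) return(list(radius = 0, rotation = NA_real_))
  if (control == "max") {
    r <- max(cs$radii[colSums(cs$occupancy) > 0]) + cs$radial_step / 2
    return(list(radius = r, rotation = NA_real_))
  }
  ang <- equal_area_bisector(cs)
  list(radius = vta_radius(cs, ang), rotation = ang)
}

# active central-row lattice points for a MICC configuration at total
# amplitude `amp`, given per-unit-amplitude AF values
active_points_at <- function(lattice0, af_unit, amp, threshold) {
  lattice0[af_unit * amp >= threshold, , drop = FALSE]
}

#' Calibrate the activating-function threshold
#'
#' Finds the scalar threshold at which a single-electrode setting at the
#' anchor amplitude produces a VTA whose equal-area-bisector radius at
#' the electrode-centre cross-section equals the anchor radius. The
#' radius is a step function of the threshold (jumping at the lattice
#' axons' activating-function values), so the calibration scans activated
#' axon counts and places the threshold at the geometric midpoint of the
#' admissible interval, which makes downstream activation decisions
#' robust to rounding.
#'
#' @param geometry A [lead_geometry()].
#' @param tissue A [tissue_model()].
#' @param grid An [axon_grid_spec()].
#' @param anchor List with `amplitude` (mA) and `radius` (mm); default
#'   1.6 mA -> 3.00 mm for a single segmented electrode.
#' @param electrode Electrode carrying the anchor setting.
#' @param voxel_resolution Voxel edge length in mm.
#' @param n_per_axis Contact surface discretization.
#' @param tol Radius tolerance in mm (default half the cross-section
#'   radial step).
#' @return An [activation_model()].
#' @export
calibrate_threshold <- function(geometry, tissue = tissue_model(),
                                grid = axon_grid_spec(),
                                anchor = list(amplitude = 1.6, radius = 3.0),
                                electrode = 2,
                                voxel_resolution = 0.1,
                                n_per_axis = 4,
                                tol = 0.025) {
  stopifnot(anchor$amplitude > 0, anchor$radius > 0)
  if (anchor$radius > grid$radial_extent) {
    stop("anchor radius lies outside the lattice radial extent")
  }
  dist <- stats::setNames(-100, as.character(electrode))
  src <- make_sources(geometry, dist, anchor$amplitude, n_per_axis)
  lat <- axon_lattice(geometry, grid)
  lat0 <- lat[lat$z_offset == 0, , drop = FALSE]
  af0 <- compute_af(src, grid, tissue, lat0)
  ord <- order(af0, decreasing = TRUE)
  af_sorted <- af0[ord]
  half <- grid$grid_spacing / 2
  for (m in seq_along(ord)) {
    if (af_sorted[m] <= 0) break
    pts <- lat0[ord[seq_len(m)], , drop = FALSE]
    r <- slice_metric_radius(pts, half, voxel_resolution)$radius
    if (r >= anchor$radius - tol) {
      if (abs(r - anchor$radius) > tol) {
        stop(sprintf(
          "anchor radius %.2f mm unreachable: nearest attainable %.2f mm",
          anchor$radius, r))
      }
      # place the threshold at the boundary axon's AF (shaved by a
      # relative epsilon so the boundary axon is robustly active): the
      # anchor amplitude is then the smallest amplitude reaching the
      # anchor radius, as the published amplitude-radius pair implies
      thr <- af_sorted[m] * (1 - 1e-9)
      return(activation_model(thr, calibration_anchor = anchor))
    }
  }
  stop("anchor radius unreachable at any finite threshold")
}

#' Build a binary VTA
#'
#' Thresholds the activating function over the full axon lattice and
#' rasterizes every activated lattice point into the voxels within half
#' the lattice spacing of it (per axis). Deterministic for fixed inputs;
#' the active voxel set grows monotonically with amplitude because the
#' activating function is linear in amplitude.
#'
#' @param sources A [make_sources()] configuration.
#' @param model An [activation_model()].
#' @param grid An [axon_grid_spec()].
#' @param voxel_resolution Voxel edge length in mm.
#' @param tissue A [tissue_model()].
#' @return An object of class `vta`: voxel occupancy keys, resolution and
#'   provenance (distribution, total amplitude, paradigm tag).
#' @export
build_vta <- function(sources, model, grid = axon_grid_spec(),
                      voxel_resolution = 0.1, tissue = tissue_model()) {
  stopifnot(inherits(model, "activation_model"))
  lat <- axon_lattice(sources$geometry, grid)
  af <- compute_af(sources, grid, tissue, lat)
  act <- lat[af >= model$af_threshold, , drop = FALSE]
  half <- grid$grid_spacing / 2
  keys <- rasterize_cubes(act[, c("x", "y", "z")], half,
                          voxel_resolution, angles = act$plane_deg)
  new_vta(keys, voxel_resolution,
          provenance = list(distribution = sources$distribution,
                            total_amplitude = sources$total_amplitude,
                            field = "homogeneous point-source surrogate (no encapsulation layer in the field computation)"),
          active_points = act[, c("x", "y", "z", "plane_deg", "r", "z_offset")],
          half = half)
}

new_vta <- function(keys, voxel_resolution, provenance = list(),
                    active_points = NULL, half = NA_real_) {
  structure(list(keys = keys, resolution = voxel_resolution,
                 n_voxels = length(keys), provenance = provenance,
                 active_points = active_points, half = half),
            class = "vta")
}

#' Construct a VTA from explicit voxel indices
#'
#' Mainly for constructing synthetic shapes in tests and examples.
#'
#' @param ijk Integer matrix with three columns of voxel indices (voxel
#'   `i` covers `[i*res, (i+1)*res)` along its axis).
#' @param voxel_resolution Voxel edge length in mm.
#' @param provenance Optional provenance list.
#' @return A `vta` object.
#' @export
vta_from_voxels <- function(ijk, voxel_resolution, provenance = list()) {
  keys <- if (is.null(dim(ijk)) || nrow(ijk) == 0) numeric(0) else
    sort(unique(encode_voxels(ijk)))
  new_vta(keys, voxel_resolution, provenance)
}

#' Voxel indices of a VTA
#'
#' @param vta A `vta` object.
#' @return Integer matrix with columns `i`,`j`,`k`.
#' @export
voxel_coords <- function(vta) {
  stopifnot(inherits(vta, "vta"))
  if (length(vta$keys) == 0) {
    return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("i", "j", "k"))))
  }
  decode_voxels(vta$keys)
}

check_same_grid <- function(a, b) {
  stopifnot(inherits(a, "vta"), inherits(b, "vta"))
  if (!isTRUE(all.equal(a$resolution, b$resolution))) {
    stop("VTAs live on different voxel grids")
  }
}

#' Union of two VTAs
#' @param a,b `vta` objects on the same voxel grid.
#' @return A `vta` object.
#' @export
vta_union <- function(a, b) {
  check_same_grid(a, b)
  ap <- NULL
  half <- NA_real_
  if (!is.null(a$active_points) && !is.null(b$active_points) &&
      isTRUE(all.equal(a$half, b$half))) {
    # the union of oriented-square footprints is the footprint set of the
    # pooled lattice points, so the lattice cross-section backend stays valid
    ap <- unique(rbind(a$active_points, b$active_points))
    half <- a$half
  }
  new_vta(sort(unique(c(a$keys, b$keys))), a$resolution,
          provenance = list(op = "union", a = a$provenance, b = b$provenance),
          active_points = ap, half = half)
}

#' Intersection of two VTAs
#' @param a,b `vta` objects on the same voxel grid.
#' @return A `vta` object.
#' @export
vta_intersection <- function(a, b) {
  check_same_grid(a, b)
  new_vta(sort(intersect(a$keys, b$keys)), a$resolution,
          provenance = list(op = "intersection", a = a$provenance, b = b$provenance))
}

#' @export
print.vta <- function(x, ...) {
  cat(sprintf("VTA: %d voxels at %.3g mm (volume %.2f mm^3)\n",
              x$n_voxels, x$resolution, vta_volume(x)))
  invisible(x)
}

#' Titrate the total pulse amplitude to a target VTA radius
#'
#' Bisection on the total cathodic amplitude at a fixed fractionalization
#' until the controlled radius reaches the target. For MICC the
#' controlled radius is the equal-area-bisector radius of the summed-field
#' VTA at the electrode-centre cross-section; for Interleaving/MSS the
#' fractionalization splits the amplitude across two alternately active
#' electrodes whose fields are thresholded independently, and the
#' controlled radius is that of their union. Bisection stops when the
#' achieved radius is within `rad_tol` of the target or the amplitude
#' interval shrinks below `amp_tol`, whichever comes first; the smallest
#' amplitude whose controlled radius reaches the target is returned. Because the
#' surrogate's radius is a step function of amplitude, targets not
#' aligned with the lattice quantization converge on the amplitude
#' interval with `converged = FALSE` and the achieved radius recorded.
#'
#' @param distribution Fractionalization (named percent vector, see
#'   [make_sources()]).
#' @param target_radius Target radius in mm.
#' @param paradigm `"micc"` or `"interleaving"`.
#' @param model An [activation_model()].
#' @param geometry A [lead_geometry()].
#' @param grid An [axon_grid_spec()].
#' @param tissue A [tissue_model()].
#' @param voxel_resolution Voxel edge length in mm.
#' @param n_per_axis Contact surface discretization.
#' @param control `"max"` (overall maximum cross-section radius, the
#'   default: it grows monotonically with amplitude, which keeps the
#'   bisection well posed) or `"bisector"` (radius along the equal-area
#'   bisector; that direction swings as the VTA rotates, so the
#'   controlled radius need not be monotone in amplitude).
#' @param amp_tol Amplitude interval tolerance in mA.
#' @param rad_tol Radius tolerance in mm.
#' @param max_iter Maximum bisection iterations.
#' @param amp_max Largest amplitude tried when bracketing, in mA.
#' @return List of class `titration`: `total_amplitude` (mA),
#'   `achieved_radius` (mm), `converged` (radius within `rad_tol`),
#'   `iterations`, plus the call configuration.
#' @export
titrate_amplitude <- function(distribution, target_radius,
                              paradigm = c("micc", "interleaving"),
                              model, geometry,
                              grid = axon_grid_spec(),
                              tissue = tissue_model(),
                              voxel_resolution = 0.1,
                              n_per_axis = 4,
                              control = c("max", "bisector"),
                              amp_tol = 0.01, rad_tol = 0.025,
                              max_iter = 60, amp_max = 64) {
  paradigm <- match.arg(paradigm)
  control <- match.arg(control)
  frac <- normalize_distribution(distribution)
  lat <- axon_lattice(geometry, grid)
  lat0 <- lat[lat$z_offset == 0, , drop = FALSE]
  half <- grid$grid_spacing / 2
  thr <- model$af_threshold

  if (paradigm == "micc") {
    src <- make_sources(geometry, distribution, 1, n_per_axis)
    af_unit <- compute_af(src, grid, tissue, lat0)
    radius_at <- function(amp) {
      pts <- active_points_at(lat0, af_unit, amp, thr)
      slice_metric_radius(pts, half, voxel_resolution, control)$radius
    }
  } else {
    active_ids <- names(frac)[frac != 0]
    if (length(active_ids) > 2) {
      stop("interleaving titration needs a one- or two-electrode fractionalization")
    }
    af_units <- lapply(active_ids, function(id) {
      one <- stats::setNames(-100, id)
      compute_af(make_sources(geometry, one, 1, n_per_axis), grid, tissue, lat0)
    })
    fr <- abs(frac[active_ids]) / 100
    radius_at <- function(amp) {
      act <- rep(FALSE, nrow(lat0))
      for (i in seq_along(af_units)) {
        act <- act | (af_units[[i]] * (fr[i] * amp) >= thr)
      }
      slice_metric_radius(lat0[act, , drop = FALSE],
                          half, voxel_resolution, control)$radius
    }
  }

  # bracket: find an upper amplitude whose radius reaches the target
  hi <- 1
  iter <- 0L
  while (radius_at(hi) < target_radius - rad_tol) {
    hi <- hi * 2
    iter <- iter + 1L
    if (hi > amp_max) {
      stop(sprintf("target radius %.2f mm not bracketable below %g mA",
                   target_radius, amp_max))
    }
  }
  lo <- 0
  while (hi - lo > amp_tol && iter < max_iter) {
    mid <- (lo + hi) / 2
    r <- radius_at(mid)
    if (r >= target_radius - rad_tol) hi <- mid else lo <- mid
    iter <- iter + 1L
  }
  achieved <- radius_at(hi)
  structure(
    list(total_amplitude = hi, achieved_radius = achieved,
         converged = abs(achieved - target_radius) <= rad_tol,
         iterations = iter, paradigm = paradigm, distribution = frac,
         target_radius = target_radius, control = control),
    class = "titration"
  )
}

#' Build the two interleaved VTAs of a fractionalization
#'
#' Each VTA results from one electrode active alone at its fractional
#' amplitude; the fields are never summed. When the weaker electrode's
#' field nowhere reaches the activation threshold, its VTA is reported
#' absent (`NULL`) -- the mechanism behind Interleaving/MSS steering
#' failures at strongly unequal fractionalizations.
#'
#' @param distribution Two-electrode fractionalization (named percent
#'   vector).
#' @param total_amplitude Total amplitude in mA, split by the
#'   fractionalization across the alternating programs.
#' @param model An [activation_model()].
#' @param geometry A [lead_geometry()].
#' @param grid An [axon_grid_spec()].
#' @param tissue A [tissue_model()].
#' @param voxel_resolution Voxel edge length in mm.
#' @param n_per_axis Contact surface discretization.
#' @return List with `vta1` (dominant electrode) and `vta2` (`NULL` when
#'   absent).
#' @export
build_interleaving_vtas <- function(distribution, total_amplitude, model,
                                    geometry, grid = axon_grid_spec(),
                                    tissue = tissue_model(),
                                    voxel_resolution = 0.1, n_per_axis = 4) {
  frac <- normalize_distribution(distribution)
  if (length(frac) != 2) stop("interleaving requires a two-electrode fractionalization")
  ids <- names(frac)[order(-abs(frac))]
  one_vta <- function(id) {
    amp <- abs(frac[id]) / 100 * total_amplitude
    if (amp == 0) return(NULL)
    src <- make_sources(geometry, stats::setNames(-100, id), amp, n_per_axis)
    v <- build_vta(src, model, grid, voxel_resolution, tissue)
    if (v$n_voxels == 0) NULL else v
  }
  list(vta1 = one_vta(ids[1]),
       vta2 = if (length(ids) > 1) one_vta(ids[2]) else NULL)
}
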