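#' Directional lead geometry
#'
#' Describes an eight-contact segmented ("1-3-3-1") directional DBS lead:
#' a ring contact at the tip, two directional levels of three 120
#' degree-spaced segments each, and a ring contact at the top. All
#' steering metrics in the package are expressed in the angular frame of
#' this geometry: electrode 2 is centred at 0 degrees and the positive
#' direction points toward electrode 3, so two-electrode steering between
#' E2 and E3 spans expected rotation angles of 0-60 degrees.
#'
#' Published dimensions for 2202-class directional leads are used as
#' defaults; every dimension is configurable because downstream results
#' are reported relative to this geometry.
#'
#' @param shaft_radius Lead shaft radius in mm.
#' @param contact_height Height of each contact in mm.
#' @param intercontact_gap Vertical gap between contacts in mm.
#' @param segment_span Angular span of a directional segment in degrees;
#'   must lie in (0, 120) so that neighbouring segments do not touch.
#' @param marker_angle Angular position of the orientation marker in
#'   degrees. The marker defines the 0 degree reference; electrode 2 is
#'   centred on it.
#' @return An object of class `lead_geometry`: a list with the scalar
#'   dimensions and an `electrodes` data frame (one row per contact with
#'   `index`, `level` (`1`, `2` or `"ring"`), `z_center` mm,
#'   `angular_center` and `angular_span` degrees; ring contacts have
#'   `NA` centre and 360 degree span).
#' @export
#' @examples
#' geom <- lead_geometry()
#' subset(geom$electrodes, level == "1")
lead_geometry <- function(shaft_radius = 0.65,
                          contact_height = 1.5,
                          intercontact_gap = 0.5,
                          segment_span = 90,
                          marker_angle = 0) {
  stopifnot(shaft_radius > 0, contact_height > 0, intercontact_gap >= 0)
  if (!(segment_span > 0 && segment_span < 120)) {
    stop("segment_span must lie in (0, 120) degrees")
  }
  pitch <- contact_height + intercontact_gap
  z <- contact_height / 2 + pitch * 0:3  # contact centres from the tip
  ang <- function(k) (marker_angle + 120 * k) %% 360
  electrodes <- data.frame(
    index = 1:8,
    level = c("ring", "1", "1", "1", "2", "2", "2", "ring"),
    z_center = c(z[1], rep(z[2], 3), rep(z[3], 3), z[4]),
    angular_center = c(NA, ang(0:2), ang(0:2), NA),
    angular_span = c(360, rep(segment_span, 6), 360),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      shaft_radius = shaft_radius,
      contact_height = contact_height,
      intercontact_gap = intercontact_gap,
      segment_span = segment_span,
      marker_angle = marker_angle,
      electrodes = electrodes
    ),
    class = "lead_geometry"
  )
}

#' Default directional lead
#'
#' Convenience constructor for the default 8-contact 1-3-3-1 lead with
#' electrode 2 centred at 0 degrees, electrode 3 at +120 and electrode 4
#' at +240 degrees.
#'
#' @return A [lead_geometry()] object.
#' @export
build_default_lead <- function() lead_geometry()

electrode_row <- function(geometry, electrode) {
  i <- match(electrode, geometry$electrodes$index)
  if (is.na(i)) stop("unknown electrode id: ", electrode)
  geometry$electrodes[i, ]
}

#' Discretize an electrode contact into surface point sources
#'
#' Places an `n_per_axis` x `n_per_axis` midpoint grid of point sources on
#' the cylindrical surface patch of a contact (over its angular span and
#' height for a segment; over the full circumference for a ring contact).
#' Weights are uniform and sum to one, so a contact amplitude is conserved
#' when distributed over its surface points.
#'
#' @param geometry A [lead_geometry()].
#' @param electrode Electrode index (1-8).
#' @param n_per_axis Number of grid points along each of the angular and
#'   vertical axes (>= 1); `n_per_axis = 1` yields the single contact-centre
#'   point with weight 1.
#' @return Data frame with columns `x`, `y`, `z` (mm) and `weight`.
#' @export
electrode_surface_points <- function(geometry, electrode, n_per_axis = 4) {
  stopifnot(inherits(geometry, "lead_geometry"), n_per_axis >= 1)
  e <- electrode_row(geometry, electrode)
  n <- as.integer(n_per_axis)
  # midpoints of n equal subdivisions of [-1/2, 1/2]
  u <- (seq_len(n) - 0.5) / n - 0.5
  centre <- if (is.na(e$angular_center)) 0 else e$angular_center
  ang <- (centre + u * e$angular_span) * pi / 180
  zz <- e$z_center + u * geometry$contact_height
  g <- expand.grid(ang = ang, z = zz)
  data.frame(
    x = geometry$shaft_radius * cos(g$ang),
    y = geometry$shaft_radius * sin(g$ang),
    z = g$z,
    weight = rep(1 / (n * n), n * n)
  )
}

#' Rotate a lead geometry about its axis
#'
#' Rotating by +120 degrees maps electrode 2 onto electrode 3's position,
#' 3 onto 4's, and 4 onto 2's (the permutation symmetry of a directional
#' level).
#'
#' @param geometry A [lead_geometry()].
#' @param degrees Rotation angle (positive toward electrode 3).
#' @return The rotated `lead_geometry`.
#' @export
rotate_geometry <- function(geometry, degrees) {
  geometry$marker_angle <- (geometry$marker_angle + degrees) %% 360
  ac <- geometry$electrodes$angular_center
  geometry$electrodes$angular_center <- ifelse(is.na(ac), NA, (ac + degrees) %% 360)
  geometry
}

#' Serialize a lead geometry to JSON
#'
#' @param geometry A [lead_geometry()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
lead_to_json <- function(geometry, path = NULL) {
  stopifnot(inherits(geometry, "lead_geometry"))
  js <- jsonlite::toJSON(unclass(geometry), digits = NA, auto_unbox = TRUE,
                         dataframe = "columns")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize a lead geometry from JSON
#'
#' @param json JSON string or path to a JSON file produced by
#'   [lead_to_json()].
#' @return A [lead_geometry()] object.
#' @export
lead_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  geom <- lead_geometry(
    shaft_radius = x$shaft_radius,
    contact_height = x$contact_height,
    intercontact_gap = x$intercontact_gap,
    segment_span = x$segment_span,
    marker_angle = x$marker_angle
  )
  geom
}
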