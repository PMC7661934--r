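#' Tissue conductivity model
#'
#' Bulk tissue conductivity and encapsulation-layer parameters. The field
#' engine itself uses analytic point-source superposition in an infinite
#' homogeneous medium at the bulk conductivity; the encapsulation layer
#' (the fibrous sheath that forms around an implanted lead) is carried as
#' metadata. It sets the inner radial margin of the axon lattice (tissue
#' inside the sheath is not sampled) but is omitted from the potential
#' computation: a resistive shell concentric with a current source changes
#' the potential only inside the shell, not the external field that drives
#' axonal activation, while measured electrode impedances enter the energy
#' model, which is decoupled from the field model.
#'
#' @param bulk_conductivity Bulk (grey matter) conductivity in S/m.
#' @param encapsulation_thickness Encapsulation thickness in micrometres.
#' @param encapsulation_conductivity Encapsulation conductivity in S/m.
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(bulk_conductivity = 0.2,
                         encapsulation_thickness = 500,
                         encapsulation_conductivity = 0.1) {
  stopifnot(bulk_conductivity > 0, encapsulation_conductivity > 0,
            encapsulation_thickness >= 0)
  structure(
    list(
      bulk_conductivity = bulk_conductivity,
      encapsulation_thickness = encapsulation_thickness,
      encapsulation_conductivity = encapsulation_conductivity
    ),
    class = "tissue_model"
  )
}

normalize_distribution <- function(distribution) {
  if (is.null(names(distribution)) || any(!nzchar(names(distribution)))) {
    stop("distribution must be a named vector: electrode index -> percent")
  }
  frac <- as.numeric(distribution)
  if (abs(sum(abs(frac)) - 100) > 1e-9) {
    stop("distribution fractions must sum to 100% in magnitude, got ",
         sum(abs(frac)))
  }
  names(frac) <- names(distribution)
  frac
}

#' Build a cathodic source configuration
#'
#' Distributes a total cathodic pulse amplitude over electrodes according
#' to a fractionalization (percent split) and discretizes each active
#' contact into weighted surface point sources. Cathodic currents are
#' stored with negative sign; each electrode's point currents sum to that
#' electrode's amplitude.
#'
#' @param geometry A [lead_geometry()].
#' @param distribution Named numeric vector mapping electrode index to
#'   percent of the total amplitude (signs indicate polarity; all standard
#'   settings are cathodic, i.e. negative). Magnitudes must sum to 100.
#'   Example: `c("2" = -70, "3" = -30)`.
#' @param total_amplitude Total pulse amplitude magnitude in mA.
#' @param n_per_axis Surface discretization per contact axis (see
#'   [electrode_surface_points()]).
#' @return An object of class `source_config`: data frame `points`
#'   (`x`,`y`,`z` mm, `electrode`, `current_mA` signed per point), the
#'   per-electrode amplitudes, the distribution, the total amplitude and
#'   the geometry.
#' @export
#' @examples
#' geom <- lead_geometry()
#' s <- make_sources(geom, c("2" = -50, "3" = -50), 2.0)
#' s$amplitudes_mA  # 1 mA cathodic on each of E2 and E3
make_sources <- function(geometry, distribution, total_amplitude,
                         n_per_axis = 4) {
  stopifnot(inherits(geometry, "lead_geometry"), total_amplitude >= 0)
  frac <- normalize_distribution(distribution)
  ids <- as.integer(names(frac))
  amp <- frac / 100 * total_amplitude  # signed mA per electrode
  pts <- do.call(rbind, lapply(seq_along(ids), function(i) {
    if (amp[i] == 0) return(NULL)
    p <- electrode_surface_points(geometry, ids[i], n_per_axis)
    data.frame(x = p$x, y = p$y, z = p$z, electrode = ids[i],
               current_mA = amp[i] * p$weight)
  }))
  if (is.null(pts)) {
    pts <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      electrode = integer(0), current_mA = numeric(0))
  }
  structure(
    list(
      points = pts,
      amplitudes_mA = stats::setNames(amp, ids),
      distribution = frac,
      total_amplitude = total_amplitude,
      geometry = geometry
    ),
    class = "source_config"
  )
}

#' Extracellular potential of a source configuration
#'
#' Analytic point-source superposition in an infinite homogeneous medium:
#' `V(x) = sum_k I_k / (4 pi sigma |x - x_k|)`. Cathodic (negative)
#' currents give negative potentials. The potential is exactly linear in
#' the source amplitudes.
#'
#' @param points Numeric matrix (or data frame) with columns `x`,`y`,`z`
#'   of query positions in mm.
#' @param sources A [make_sources()] configuration.
#' @param tissue A [tissue_model()].
#' @return Numeric vector of potentials in volts.
#' @export
potential_at <- function(points, sources, tissue = tissue_model()) {
  stopifnot(inherits(sources, "source_config"), inherits(tissue, "tissue_model"))
  pts <- as.matrix(as.data.frame(points)[, c("x", "y", "z")])
  sp <- sources$points
  if (nrow(sp) == 0) return(rep(0, nrow(pts)))
  # distances in metres; currents mA -> A
  v <- numeric(nrow(pts))
  sigma <- tissue$bulk_conductivity
  for (k in seq_len(nrow(sp))) {
    d2 <- (pts[, 1] - sp$x[k])^2 + (pts[, 2] - sp$y[k])^2 + (pts[, 3] - sp$z[k])^2
    if (any(d2 == 0)) stop("query point coincides with a source point")
    v <- v + (sp$current_mA[k] * 1e-3) / sqrt(d2)
  }
  unname(v / (4 * pi * sigma * 1e-3))  # mm -> m in the distance
}
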