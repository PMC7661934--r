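# Integer voxel indexing on a fixed global grid.
#
# Voxel i along an axis covers [i*res, (i+1)*res) mm with centre
# (i+0.5)*res; indices are encoded into a single double-precision key
# (exact for |index| < 4096, i.e. +/- 400 mm at 0.1 mm resolution).

.VOX_B <- 4096
.VOX_M <- 8192

encode_voxels <- function(ijk) {
  ijk <- as.matrix(ijk)
  if (any(abs(ijk) >= .VOX_B)) stop("voxel index out of range")
  ((ijk[, 1] + .VOX_B) * .VOX_M + (ijk[, 2] + .VOX_B)) * .VOX_M +
    (ijk[, 3] + .VOX_B)
}

decode_voxels <- function(keys) {
  k <- keys %% .VOX_M - .VOX_B
  rest <- keys %/% .VOX_M
  j <- rest %% .VOX_M - .VOX_B
  i <- rest %/% .VOX_M - .VOX_B
  cbind(i = i, j = j, k = k)
}

encode_voxels_2d <- function(ij) {
  ij <- as.matrix(ij)
  if (any(abs(ij) >= .VOX_B)) stop("voxel index out of range")
  (ij[, 1] + .VOX_B) * .VOX_M + (ij[, 2] + .VOX_B)
}

# index range along one axis whose voxel centres fall within [p-h, p+h]
axis_index_range <- function(p, h, res) {
  lo <- ceiling((p - h) / res - 0.5)
  hi <- floor((p + h) / res - 0.5)
  list(lo = lo, hi = hi)
}

# Mark all voxels whose centre lies within half the lattice spacing of a
# point, measured along the point's own in-plane (radial, tangential)
# axes and the vertical axis. The rasterized footprint of a lattice
# point is therefore a square prism oriented with its plane, which makes
# the continuous union covariant with the lattice's rotational and
# mirror symmetries (axis-aligned cubes are not invariant under 60 or
# 120 degree reflections and would bias the steering metrics). With
# `angles = NULL` the footprint is the axis-aligned cube. Returns sorted
# unique 3-D keys.
.RAS_EPS <- 1e-9

rasterize_cubes <- function(points, half, res, angles = NULL) {
  pts <- as.matrix(points)
  if (nrow(pts) == 0) return(numeric(0))
  reach <- if (is.null(angles)) half else half * sqrt(2)
  rx <- axis_index_range(pts[, 1], reach, res)
  ry <- axis_index_range(pts[, 2], reach, res)
  rz <- axis_index_range(pts[, 3], half, res)
  keys <- vector("list", nrow(pts))
  for (p in seq_len(nrow(pts))) {
    g <- expand.grid(i = rx$lo[p]:rx$hi[p], j = ry$lo[p]:ry$hi[p],
                     k = rz$lo[p]:rz$hi[p], KEEP.OUT.ATTRS = FALSE)
    if (!is.null(angles)) {
      a <- angles[p] * pi / 180
      dx <- (g$i + 0.5) * res - pts[p, 1]
      dy <- (g$j + 0.5) * res - pts[p, 2]
      keep <- abs(dx * cos(a) + dy * sin(a)) <= half + .RAS_EPS &
        abs(-dx * sin(a) + dy * cos(a)) <= half + .RAS_EPS
      g <- g[keep, , drop = FALSE]
    }
    keys[[p]] <- encode_voxels(g)
  }
  sort(unique(unlist(keys, use.names = FALSE)))
}

# 2-D variant used for cross-section work at a single voxel layer.
rasterize_squares <- function(xy, half, res, angles = NULL) {
  pts <- as.matrix(xy)
  if (nrow(pts) == 0) return(numeric(0))
  reach <- if (is.null(angles)) half else half * sqrt(2)
  rx <- axis_index_range(pts[, 1], reach, res)
  ry <- axis_index_range(pts[, 2], reach, res)
  keys <- vector("list", nrow(pts))
  for (p in seq_len(nrow(pts))) {
    g <- expand.grid(i = rx$lo[p]:rx$hi[p], j = ry$lo[p]:ry$hi[p],
                     KEEP.OUT.ATTRS = FALSE)
    if (!is.null(angles)) {
      a <- angles[p] * pi / 180
      dx <- (g$i + 0.5) * res - pts[p, 1]
      dy <- (g$j + 0.5) * res - pts[p, 2]
      keep <- abs(dx * cos(a) + dy * sin(a)) <= half + .RAS_EPS &
        abs(-dx * sin(a) + dy * cos(a)) <= half + .RAS_EPS
      g <- g[keep, , drop = FALSE]
    }
    keys[[p]] <- encode_voxels_2d(g)
  }
  sort(unique(unlist(keys, use.names = FALSE)))
}
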