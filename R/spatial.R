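# Spatial convention: world RAS mm throughout; voxel indices 0-based;
# world -> voxel uses the inverse affine then nearest-integer rounding with
# halves away from zero. Left hemisphere is world x < 0.

#' Round half away from zero
#' @param x numeric vector.
#' @return Rounded values (base `round()` rounds halves to even, which is the
#'   wrong convention for voxel snapping here).
#' @keywords internal
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert world coordinates to 0-based voxel indices
#'
#' @param points n-by-3 matrix of world RAS mm coordinates.
#' @param affine 4x4 voxel-to-world matrix.
#' @param round snap to nearest voxel (half away from zero)?
#' @return n-by-3 matrix of voxel indices (0-based).
#' @export
worldToVoxel <- function(points, affine, round = TRUE) {
  points <- rbind(points)  # accept a bare length-3 vector
  inv <- solve(affine)
  v <- cbind(points, 1) %*% t(inv)
  v <- v[, 1:3, drop = FALSE]
  if (round) v <- roundHalfAway(v)
  v
}

#' Convert 0-based voxel indices to world coordinates (voxel centers)
#'
#' @param voxels n-by-3 matrix of 0-based voxel indices.
#' @param affine 4x4 voxel-to-world matrix.
#' @return n-by-3 matrix of world RAS mm coordinates.
#' @export
voxelToWorld <- function(voxels, affine) {
  voxels <- rbind(voxels)
  w <- cbind(voxels, 1) %*% t(affine)
  w[, 1:3, drop = FALSE]
}

# Linear (row-major-free) index into a 3-D array from 0-based voxel triples;
# NA for out-of-grid voxels.
.voxelLinearIndex <- function(vox, dims) {
  i <- vox[, 1]; j <- vox[, 2]; k <- vox[, 3]
  ok <- i >= 0 & i < dims[1] & j >= 0 & j < dims[2] & k >= 0 & k < dims[3]
  idx <- 1 + i + dims[1] * (j + dims[2] * k)
  idx[!ok] <- NA_integer_
  idx
}

#' Resample a streamline at a fixed arc-length step
#'
#' Linear interpolation along cumulative arc length; the original first and
#' last points are always retained.
#'
#' @param points n-by-3 matrix of coordinates.
#' @param stepMm target spacing in mm (default 1).
#' @return Resampled m-by-3 matrix.
#' @export
resampleStreamline <- function(points, stepMm = 1) {
  seg <- sqrt(rowSums(diff(points)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= stepMm) return(points[c(1, nrow(points)), , drop = FALSE])
  target <- unique(c(seq(0, total, by = stepMm), total))
  out <- cbind(approx(s, points[, 1], xout = target, ties = "ordered")$y,
               approx(s, points[, 2], xout = target, ties = "ordered")$y,
               approx(s, points[, 3], xout = target, ties = "ordered")$y)
  out
}

# Unique linear voxel indices touched by a set of streamlines after 1 mm
# resampling; the common support for tract volume and mean FA.
.tractVoxelSet <- function(streamlines, affine, dims, stepMm = 1) {
  pts <- do.call(rbind, lapply(streamlines, resampleStreamline, stepMm = stepMm))
  vox <- worldToVoxel(pts, affine)
  idx <- .voxelLinearIndex(vox, dims)
  unique(idx[!is.na(idx)])
}
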