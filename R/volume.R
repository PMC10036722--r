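#' Scalar count volume
#'
#' A `scalar_volume` wraps a 3D array of non-negative counts together with
#' its voxel spacing in millimetres.  The axis convention used throughout
#' the package is the short-axis convention for reoriented myocardial
#' perfusion volumes: X runs septal-to-lateral (toward the patient's
#' right), Y anterior-to-inferior, and Z along the left-ventricular long
#' axis with the apex toward negative Z and the base toward positive Z.
#' Voxel centres sit at integer grid coordinates; the voxel at array index
#' `[i, j, k]` (1-based, as usual in R) has world position
#' `((i - 1) * sx, (j - 1) * sy, (k - 1) * sz)` in mm.
#'
#' @param data 3D numeric array of counts; all values must be finite and
#'   non-negative, and every dimension must have at least 16 voxels.
#' @param spacing Numeric vector of length 3, voxel size in mm per axis
#'   (all positive).  A single number is recycled to all three axes.
#'
#' @return An object of class `scalar_volume`: a list with elements
#'   `data` (the array) and `spacing` (length-3 numeric).
#' @examples
#' v <- scalar_volume(array(1, dim = c(16, 16, 16)), spacing = 6.4)
#' dim(v$data)
#' @export
scalar_volume <- function(data, spacing = 6.4) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 16L))
    stop("volume dimensions must be at least 16 voxels per axis")
  if (anyNA(data) || any(!is.finite(data)))
    stop("volume contains non-finite values")
  if (any(data < 0))
    stop("volume contains negative counts")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel sizes in mm")
  structure(list(data = data, spacing = spacing), class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<scalar_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  counts: max %.4g, total %.4g\n",
              max(x$data), sum(x$data)))
  invisible(x)
}

#' @export
dim.scalar_volume <- function(x) dim(x$data)

as_scalar_volume <- function(x, spacing = 6.4) {
  if (inherits(x, "scalar_volume")) return(x)
  scalar_volume(x, spacing)
}

#' World extent of a volume (mm)
#'
#' Maximum world coordinate per axis (the position of the last voxel
#' centre); the first voxel centre sits at the origin.
#' @param vol A [scalar_volume()].
#' @return Length-3 numeric, mm.
#' @keywords internal
vol_extent_mm <- function(vol) (dim(vol$data) - 1) * vol$spacing

#' Convert between voxel indices and world coordinates
#'
#' `voxel_to_mm()` maps 1-based array indices to mm positions;
#' `mm_to_voxel()` is the inverse (returning fractional indices).
#'
#' @param idx,pos Matrix (n x 3) or length-3 vector.
#' @param vol A [scalar_volume()].
#' @return n x 3 matrix.
#' @export
voxel_to_mm <- function(idx, vol) {
  idx <- rbind_pts(idx)
  sweep(idx - 1, 2, vol$spacing, "*")
}

#' @rdname voxel_to_mm
#' @export
mm_to_voxel <- function(pos, vol) {
  pos <- rbind_pts(pos)
  sweep(pos, 2, vol$spacing, "/") + 1
}

rbind_pts <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  if (ncol(p) != 3L) stop("points must have 3 columns")
  storage.mode(p) <- "double"
  p
}

#' Trilinear interpolation of a volume at world positions
#'
#' Samples the volume at arbitrary mm positions with trilinear
#' interpolation.  Positions outside the grid contribute zero (background
#' counts in perfusion volumes are near zero, so zero padding is the
#' natural boundary condition).
#'
#' @param vol A [scalar_volume()].
#' @param pos n x 3 matrix of mm positions (or a length-3 vector).
#' @return Numeric vector of length n.
#' @examples
#' v <- scalar_volume(array(2, dim = c(16, 16, 16)), spacing = 1)
#' interp_trilinear(v, c(3.5, 4.2, 7.9))
#' @export
interp_trilinear <- function(vol, pos) {
  pos <- rbind_pts(pos)
  g <- mm_to_voxel(pos, vol)           # fractional 1-based indices
  d <- dim(vol$data)
  i0 <- floor(g)
  f <- g - i0
  out <- numeric(nrow(g))

  # accumulate the 8 corner contributions; corners outside the grid are 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- i0[, 1] + dx; jj <- i0[, 2] + dy; kk <- i0[, 3] + dz
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3] &
      w > 0
    if (any(ok)) {
      lin <- ii[ok] + (jj[ok] - 1) * d[1] + (kk[ok] - 1) * d[1] * d[2]
      out[ok] <- out[ok] + w[ok] * vol$data[lin]
    }
  }
  out
}

#' Rotate a volume about the Y axis
#'
#' Resamples the volume after a rotation by `angle_deg` degrees about the
#' Y axis through the volume centre, using trilinear interpolation with
#' zero padding.  Used to bring transversal reconstructions into an
#' approximate short-axis orientation before LV model fitting.
#'
#' @param vol A [scalar_volume()].
#' @param angle_deg Rotation angle in degrees; 0 returns the input
#'   unchanged (no resampling).
#' @return A [scalar_volume()] on the same grid.
#' @export
rotate_volume_y <- function(vol, angle_deg) {
  if (abs(angle_deg) < 1e-12) return(vol)
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), 0, sin(th),
                0,       1, 0,
                -sin(th), 0, cos(th)), 3, 3, byrow = TRUE)
  resample_rotated(vol, R)
}

#' Rotate a volume by an arbitrary rotation matrix
#'
#' @param vol A [scalar_volume()].
#' @param R 3x3 rotation matrix (applied about the volume centre): output
#'   voxel at world position p samples the input at `centre + R (p - centre)`.
#' @return A [scalar_volume()].
#' @keywords internal
resample_rotated <- function(vol, R) {
  d <- dim(vol$data)
  ctr <- (d - 1) * vol$spacing / 2
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  pos <- voxel_to_mm(idx, vol)
  src <- sweep(sweep(pos, 2, ctr, "-") %*% t(R), 2, ctr, "+")
  vals <- interp_trilinear(vol, src)
  vals[vals < 0] <- 0
  scalar_volume(array(vals, dim = d), vol$spacing)
}

#' Voxel volume in millilitres
#' @param vol A [scalar_volume()].
#' @return Scalar, ml per voxel.
#' @export
voxel_ml <- function(vol) prod(vol$spacing) / 1000

#' Mask volume in millilitres
#' @param mask Logical/0-1 3D array.
#' @param vol The [scalar_volume()] the mask is aligned to (for spacing).
#' @return Scalar, ml.
#' @export
mask_volume_ml <- function(mask, vol) sum(mask != 0) * voxel_ml(vol)

# world coordinate vectors for each axis of a volume grid
axis_mm <- function(vol) {
  d <- dim(vol$data)
  list(x = (seq_len(d[1]) - 1) * vol$spacing[1],
       y = (seq_len(d[2]) - 1) * vol$spacing[2],
       z = (seq_len(d[3]) - 1) * vol$spacing[3])
}
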