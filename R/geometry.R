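#' Geometric models for ventricular segmentation
#'
#' `sphere_model()` describes the spherical RV model (centre in mm and
#' radius); `ellipsoid_model()` describes the LV mid-myocardial ellipsoid
#' (centre, the three semi-axes in mm sorted increasingly, and a rotation
#' matrix whose columns are the corresponding axis directions).
#'
#' @param center Length-3 numeric, mm.
#' @param radius Positive scalar, mm.
#' @return `sphere_model()` returns a `sphere_model`; `ellipsoid_model()`
#'   an `ellipsoid_model`.
#' @export
sphere_model <- function(center, radius) {
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("sphere centre must be a finite 3-vector")
  if (!is.finite(radius) || radius <= 0) stop("sphere radius must be > 0")
  structure(list(center = center, radius = as.numeric(radius)),
            class = "sphere_model")
}

#' @rdname sphere_model
#' @param semi_axes Length-3 positive numeric, mm; stored sorted
#'   increasingly.
#' @param orientation 3x3 rotation matrix (orthonormal, det +1); columns
#'   are the axis directions matching `semi_axes`.
#' @export
ellipsoid_model <- function(center, semi_axes, orientation = diag(3)) {
  center <- as.numeric(center)
  semi_axes <- as.numeric(semi_axes)
  if (length(center) != 3L || length(semi_axes) != 3L)
    stop("centre and semi_axes must be 3-vectors")
  if (any(!is.finite(semi_axes)) || any(semi_axes <= 0))
    stop("semi-axes must be positive")
  o <- sort(semi_axes, index.return = TRUE)
  semi_axes <- o$x
  orientation <- orientation[, o$ix, drop = FALSE]
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("orientation must be orthonormal")
  if (det(orientation) < 0) orientation[, 1] <- -orientation[, 1]
  structure(list(center = center, semi_axes = semi_axes,
                 orientation = orientation),
            class = "ellipsoid_model")
}

#' @export
print.sphere_model <- function(x, ...) {
  cat(sprintf("<sphere_model> centre (%.2f, %.2f, %.2f) mm, radius %.2f mm\n",
              x$center[1], x$center[2], x$center[3], x$radius))
  invisible(x)
}

#' @export
print.ellipsoid_model <- function(x, ...) {
  cat(sprintf(
    "<ellipsoid_model> centre (%.2f, %.2f, %.2f) mm, semi-axes %.2f/%.2f/%.2f mm\n",
    x$center[1], x$center[2], x$center[3],
    x$semi_axes[1], x$semi_axes[2], x$semi_axes[3]))
  invisible(x)
}

#' Sphere-adequacy ratio of the LV from its sphericity index
#'
#' The distance f from a septal sphere centre to the apex relates to the
#' LV short- and long-axis lengths a and b through
#' f = (1/2) sqrt(a^2 + b^2), so with the sphericity index x = a/b the
#' ratio f/b equals (1/2) sqrt(x^2 + 1).  Values of f/b near 1 indicate
#' that a sphere centred on the septum reaches the apex at roughly the
#' long-axis distance, i.e. that a spherical RV model is geometrically
#' reasonable.
#'
#' @param x Sphericity index a/b, positive.
#' @return The ratio f/b.
#' @examples
#' sphericity_ratio(2)    # ~1.118
#' sphericity_ratio(1.7)  # ~0.986
#' @export
sphericity_ratio <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("sphericity index must be positive")
  0.5 * sqrt(x^2 + 1)
}

#' Half the RV eccentricity index
#'
#' With c and d the longest and shortest mid-RV short-axis diameters, the
#' distance m from a septal sphere centre to the RV free wall is
#' approximately c/2, so m/d is approximately (c/d)/2, i.e. half the
#' eccentricity index.  Values near 1 support a spherical RV model.
#'
#' @param eccentricity Eccentricity index c/d, at least 1 (c is the
#'   longest diameter).
#' @return The ratio m/d.
#' @examples
#' eccentricity_half(1.8)  # 0.9
#' @export
eccentricity_half <- function(eccentricity) {
  if (any(!is.finite(eccentricity)) || any(eccentricity < 1))
    stop("eccentricity index must be >= 1")
  eccentricity / 2
}

#' Regular angular grid of unit directions
#'
#' Directions on a regular (polar, azimuth) grid: polar angles are the
#' band centres `pi * (i - 1/2) / n_long` measured from +Z, azimuths
#' `2 * pi * (j - 1) / n_lat` measured from +X toward +Y.  Rows are
#' ordered azimuth-fastest.
#'
#' @param n_long,n_lat Number of longitudinal (polar) and latitudinal
#'   (azimuthal) divisions.
#' @return List with `dirs` (n_long*n_lat x 3 unit rows), `theta`, `phi`
#'   (per-row angles), and `index` (two-column matrix of (i, j)).
#' @keywords internal
angular_grid <- function(n_long, n_lat) {
  theta <- pi * (seq_len(n_long) - 0.5) / n_long
  phi <- 2 * pi * (seq_len(n_lat) - 1) / n_lat
  g <- expand.grid(j = seq_len(n_lat), i = seq_len(n_long))
  th <- theta[g$i]; ph <- phi[g$j]
  dirs <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  list(dirs = dirs, theta = th, phi = ph,
       index = cbind(i = g$i, j = g$j))
}

#' Extract radial count profiles from a volume
#'
#' Samples the volume along rays from a common origin on a regular
#' (polar, azimuth) grid of directions covering the full sphere.  Samples
#' are taken by trilinear interpolation at radii 0, step, 2*step, ... up
#' to `max_radius`; positions outside the grid read zero.
#'
#' @param vol A [scalar_volume()].
#' @param origin Length-3 mm position; must lie inside the volume.
#' @param n_long,n_lat Longitudinal and latitudinal profile counts (the
#'   model-fitting stage uses 48 x 96 = 4608 profiles, the surface
#'   refinement stage 120 x 320 = 38400).
#' @param step Radial sampling step in mm (default half the smallest
#'   voxel size, for sub-voxel localisation of surface crossings).
#' @param max_radius Outermost sampled radius in mm.
#' @return A `radial_profiles` object: list with `origin`, `step`,
#'   `radii` (sample radii), `dirs` (n x 3 unit directions), `samples`
#'   (n x length(radii) matrix), `theta`, `phi`, `index`.
#' @export
extract_radial_profiles <- function(vol, origin, n_long, n_lat,
                                    step = min(vol$spacing) / 2,
                                    max_radius = 100) {
  origin <- as.numeric(origin)
  ext <- vol_extent_mm(vol)
  if (any(origin < 0) || any(origin > ext))
    stop("profile origin lies outside the volume")
  if (n_long < 1 || n_lat < 1) stop("profile counts must be >= 1")
  if (step <= 0 || max_radius <= 0) stop("step and max_radius must be > 0")
  ag <- angular_grid(n_long, n_lat)
  radii <- seq(0, max_radius, by = step)
  n <- nrow(ag$dirs)
  # sample all rays at once: positions are origin + r * dir
  pts <- matrix(0, n * length(radii), 3)
  for (a in 1:3)
    pts[, a] <- origin[a] + outer(ag$dirs[, a], radii)  # n x nr, col-major
  vals <- interp_trilinear(vol, pts)
  samples <- matrix(vals, nrow = n)
  structure(list(origin = origin, step = step, radii = radii,
                 dirs = ag$dirs, samples = samples,
                 theta = ag$theta, phi = ag$phi, index = ag$index),
            class = "radial_profiles")
}

#' @export
print.radial_profiles <- function(x, ...) {
  cat(sprintf("<radial_profiles> %d profiles, %d samples each, step %.2f mm\n",
              nrow(x$samples), ncol(x$samples), x$step))
  invisible(x)
}

#' Algebraic least-squares sphere fit
#'
#' Fits a sphere to 3D points by the linear (algebraic) least-squares
#' formulation: minimise the residual of
#' x^2 + y^2 + z^2 + D x + E y + F z + G = 0 over (D, E, F, G).  This is
#' closed-form and deterministic; at the noise levels of count-profile
#' mid-myocardial points it agrees with the geometric least-squares
#' sphere to a small fraction of a millimetre.
#'
#' @param points n x 3 matrix of mm positions, n >= 4, not coplanar.
#' @return A [sphere_model()].
#' @examples
#' p <- rbind(c(6,2,3), c(-4,2,3), c(1,7,3), c(1,-3,3), c(1,2,8), c(1,2,-2))
#' fit_sphere_least_squares(p)  # centre (1,2,3), radius 5
#' @export
fit_sphere_least_squares <- function(points) {
  points <- rbind_pts(points)
  if (nrow(points) < 4L) stop("sphere fit needs at least 4 points")
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  sv <- svd(A)
  if (sv$d[4] < 1e-8 * sv$d[1])
    stop("degenerate sphere fit: points are coplanar or collinear")
  coef <- sv$v %*% ((crossprod(sv$u, b)) / sv$d)
  ctr <- coef[1:3]
  r2 <- coef[4] + sum(ctr^2)
  if (r2 <= 0) stop("degenerate sphere fit: non-positive squared radius")
  sphere_model(ctr, sqrt(r2))
}

#' Algebraic least-squares ellipsoid fit
#'
#' Fits a general quadric to points by minimising the algebraic residual
#' under a unit-norm coefficient constraint (smallest singular vector),
#' then verifies that the quadric is an ellipsoid and decomposes it into
#' centre, semi-axes and orientation.  Points are centred and scaled
#' before fitting for numerical conditioning.
#'
#' @param points n x 3 matrix, n >= 9, in general position on (or near)
#'   an ellipsoid.
#' @return An [ellipsoid_model()].
#' @export
fit_ellipsoid_least_squares <- function(points) {
  points <- rbind_pts(points)
  if (nrow(points) < 9L) stop("ellipsoid fit needs at least 9 points")
  mu <- colMeans(points)
  sc <- mean(sqrt(rowSums(sweep(points, 2, mu)^2)))
  if (sc <= 0) stop("degenerate ellipsoid fit: coincident points")
  p <- sweep(points, 2, mu) / sc
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  V <- cbind(x^2, y^2, z^2, x * y, x * z, y * z, x, y, z, 1)
  sv <- svd(V)
  if (sv$d[10] > 1e-6 * sv$d[1] && nrow(points) == 9L) {
    # exactly determined; fine
  }
  q <- sv$v[, 10]
  # quadric matrix form: [A b; b' c], quadric = u'Au + 2 b'u + c = 0
  A <- matrix(c(q[1], q[4] / 2, q[5] / 2,
                q[4] / 2, q[2], q[6] / 2,
                q[5] / 2, q[6] / 2, q[3]), 3, 3)
  bq <- q[7:9] / 2
  cq <- q[10]
  eg <- eigen(A, symmetric = TRUE)
  if (any(abs(eg$values) < 1e-10 * max(abs(eg$values))))
    stop("degenerate ellipsoid fit: singular quadric")
  if (any(eg$values > 0) && any(eg$values < 0))
    stop("fitted quadric is not an ellipsoid")
  ctr <- -solve(A, bq)
  k <- as.numeric(t(ctr) %*% A %*% ctr) - cq
  lam <- eg$values / k
  if (any(lam <= 0)) stop("fitted quadric is not an ellipsoid")
  semi <- 1 / sqrt(lam)
  # undo centring/scaling
  ellipsoid_model(center = mu + sc * ctr,
                  semi_axes = sc * semi,
                  orientation = eg$vectors)
}

#' Moment-based ellipsoid estimate
#'
#' Robust initialiser: centre at the centroid, axis directions from the
#' principal components, semi-axes from the eigenvalue scale of a thin
#' shell (`sqrt(3 lambda)`).  Always returns an ellipsoid, unlike the
#' algebraic quadric fit, so it serves as the fallback when the cluster
#' shape (e.g. LV merged with a bright RV crescent) drives the quadric
#' out of the ellipsoid class.
#'
#' @param points n x 3 matrix of mm positions, n >= 4.
#' @return An [ellipsoid_model()].
#' @export
moment_ellipsoid <- function(points) {
  points <- rbind_pts(points)
  if (nrow(points) < 4L) stop("moment ellipsoid needs at least 4 points")
  mu <- colMeans(points)
  cv <- stats::cov(points)
  eg <- eigen(cv, symmetric = TRUE)
  if (any(eg$values <= 0)) stop("degenerate point cloud")
  ellipsoid_model(mu, sqrt(3 * eg$values), eg$vectors)
}

#' Evaluate the ellipsoid quadratic form at positions
#'
#' Returns `rho^2`, the squared normalised radius of each position in the
#' ellipsoid's frame (1 on the surface, <1 inside).
#'
#' @param model An [ellipsoid_model()].
#' @param pos n x 3 mm positions.
#' @param inflate_mm Added to each semi-axis before evaluating (e.g. to
#'   test against an epicardial offset surface).
#' @return Numeric vector.
#' @keywords internal
ellipsoid_rho2 <- function(model, pos, inflate_mm = 0) {
  pos <- rbind_pts(pos)
  u <- sweep(pos, 2, model$center) %*% model$orientation
  ax <- model$semi_axes + inflate_mm
  rowSums(sweep(u, 2, ax, "/")^2)
}

#' Distance from a ray origin to its exit from an ellipsoid
#'
#' For rays `origin + t * dir`, returns the largest non-negative t at
#' which the ray crosses the (optionally inflated) ellipsoid surface, or
#' NA when the ray never intersects it.
#'
#' @param model An [ellipsoid_model()].
#' @param origin Length-3 mm.
#' @param dirs n x 3 unit directions.
#' @inheritParams ellipsoid_rho2
#' @return Numeric vector of exit distances (mm), NA where no crossing.
#' @keywords internal
ray_ellipsoid_exit <- function(model, origin, dirs, inflate_mm = 0) {
  dirs <- rbind_pts(dirs)
  ax <- model$semi_axes + inflate_mm
  o <- as.numeric((origin - model$center) %*% model$orientation) / ax
  d <- sweep(dirs %*% model$orientation, 2, ax, "/")
  a <- rowSums(d^2)
  b <- 2 * (d %*% o)[, 1]
  c0 <- sum(o^2) - 1
  disc <- b^2 - 4 * a * c0
  out <- rep(NA_real_, nrow(dirs))
  ok <- disc >= 0
  t2 <- (-b[ok] + sqrt(disc[ok])) / (2 * a[ok])
  t2[t2 < 0] <- NA_real_
  out[ok] <- t2
  out
}

#' Distance from a ray origin to a sphere surface along directions
#'
#' Largest non-negative t with `|origin + t dir - centre| = radius`;
#' NA when the ray misses the sphere.
#' @param model A [sphere_model()].
#' @param origin Length-3 mm.
#' @param dirs n x 3 unit directions.
#' @return Numeric vector (mm).
#' @keywords internal
ray_sphere_exit <- function(model, origin, dirs) {
  dirs <- rbind_pts(dirs)
  o <- origin - model$center
  b <- 2 * (dirs %*% o)[, 1]
  c0 <- sum(o^2) - model$radius^2
  disc <- b^2 - 4 * c0
  out <- rep(NA_real_, nrow(dirs))
  ok <- disc >= 0
  t2 <- (-b[ok] + sqrt(disc[ok])) / 2
  t2[t2 < 0] <- NA_real_
  out[ok] <- t2
  out
}
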