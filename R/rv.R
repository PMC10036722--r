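#' Initial RV sphere from the LV model
#'
#' Places the initial RV spherical model relative to the fitted LV
#' ellipsoid: the centre is the LV centre shifted by the smallest LV
#' semi-axis toward the patient's right (-X) and by one fifth of the
#' largest semi-axis toward the apex (-Z); the radius is 1.5 times the
#' smallest LV semi-axis.  Both are empirical and may be overridden by
#' the user when the model is misplaced (the semiautomatic contract).
#'
#' @param lv An `lv_result` from [segment_lv()] (only the model is
#'   used).
#' @param center,radius Optional user overrides; when given they are
#'   returned verbatim.
#' @return A [sphere_model()].
#' @examples
#' lv <- list(model = ellipsoid_model(c(0, 0, 0), c(20, 25, 40)))
#' init_rv_sphere(lv)  # centre (-20, 0, -8), radius 30
#' @export
init_rv_sphere <- function(lv, center = NULL, radius = NULL) {
  m <- lv$model
  r_min <- min(m$semi_axes)
  r_max <- max(m$semi_axes)
  if (is.null(center)) center <- m$center + c(-r_min, 0, -0.2 * r_max)
  if (is.null(radius)) radius <- 1.5 * r_min
  sphere_model(center, radius)
}

#' Adaptive delineation threshold
#'
#' The count threshold separating RV myocardium from background along a
#' valid profile:
#' `threshold = 0.8 * C_profile / (1 - 0.4 * (C_max - C_profile))`,
#' where `C_profile` is the accepted local-maximum count of the profile
#' and `C_max` is half the maximum LV count, both expressed as fractions
#' of the LV maximum.  The threshold adapts to the local RV intensity:
#' fainter walls are delineated at a proportionally lower level.
#'
#' @param C_profile Normalised profile peak count(s), in (0, 1].
#' @param C_max Normalised half-LV-maximum, 0.5 under the package's
#'   normalisation convention.
#' @return Threshold(s) on the same normalised scale.
#' @examples
#' eq5_threshold(0.5)   # 0.40
#' eq5_threshold(0.25)  # 0.2222...
#' @export
eq5_threshold <- function(C_profile, C_max = 0.5) {
  den <- 1 - 0.4 * (C_max - C_profile)
  if (any(den <= 0)) stop("non-positive denominator in adaptive threshold")
  0.8 * C_profile / den
}

#' Validity selection of RV count profiles
#'
#' A profile is valid when one of its local maxima lies within one voxel
#' size of the current sphere surface along the ray and exceeds one
#' quarter of the maximum LV count.  Among qualifying maxima the one
#' nearest the surface is chosen; its value becomes `C_profile`.
#'
#' @param profiles A `radial_profiles` object on counts normalised to
#'   LV max = 1.
#' @param sphere The current [sphere_model()] (profiles are assumed to
#'   originate at its centre, so the surface lies at radius
#'   `sphere$radius` along every ray).
#' @param voxel Voxel size in mm (the distance tolerance).
#' @param floor_value Minimum normalised peak value (default 0.25).
#' @return A list with `valid` (logical), `C_profile` (numeric, NA when
#'   invalid) and `peak_index` (integer sample index, NA when invalid).
#' @export
select_valid_profiles <- function(profiles, sphere, voxel = 6.4,
                                  floor_value = 0.25) {
  S <- profiles$samples
  n <- nrow(S); m <- ncol(S)
  radii <- profiles$radii
  inner <- S[, 2:(m - 1), drop = FALSE]
  is_max <- inner > S[, 1:(m - 2), drop = FALSE] &
    inner >= S[, 3:m, drop = FALSE]
  cand <- is_max & inner > floor_value
  dist <- abs(matrix(radii[2:(m - 1)], n, m - 2, byrow = TRUE) -
                sphere$radius)
  ok <- cand & dist <= voxel
  pen <- dist
  pen[!ok] <- Inf
  best <- max.col(-pen, ties.method = "first")
  valid <- is.finite(pen[cbind(seq_len(n), best)])
  peak_index <- ifelse(valid, best + 1L, NA_integer_)
  C_profile <- rep(NA_real_, n)
  C_profile[valid] <- S[cbind(which(valid), peak_index[valid])]
  list(valid = valid, C_profile = C_profile, peak_index = peak_index)
}

#' Delineate epicardial and endocardial points on valid profiles
#'
#' For each valid profile the adaptive threshold [eq5_threshold()] is
#' computed from its `C_profile`; the contiguous above-threshold run
#' containing the chosen maximum is taken as RV myocardium along that
#' ray.  The outer and inner threshold crossings (located to sub-sample
#' precision by linear interpolation) give the epicardial and
#' endocardial points, their midpoint the mid-myocardial point.  A
#' crossing farther than two voxel sizes from the sphere surface is
#' flagged far-off; far-off points do not contribute to model refitting.
#'
#' @inheritParams select_valid_profiles
#' @param sel Result of [select_valid_profiles()].
#' @param C_max Normalised half-LV-maximum (0.5).
#' @return A tibble with one row per profile: angular indices and
#'   angles, `valid`, `C_profile`, `endo_r`, `mid_r`, `epi_r`,
#'   `far_off_endo`, `far_off_epi`.
#' @export
delineate_profiles <- function(profiles, sel, sphere, voxel = 6.4,
                               C_max = 0.5) {
  idx <- sel$peak_index
  thr <- rep(NA_real_, length(idx))
  thr[sel$valid] <- eq5_threshold(sel$C_profile[sel$valid], C_max)
  del <- delineate_runs(profiles, idx, abs_threshold = thr)
  valid <- sel$valid & !is.na(del$mid)
  far_epi <- valid & abs(del$epi - sphere$radius) > 2 * voxel
  far_endo <- valid & abs(del$endo - sphere$radius) > 2 * voxel
  tibble::tibble(
    long_index = profiles$index[, "i"],
    lat_index = profiles$index[, "j"],
    theta = profiles$theta, phi = profiles$phi,
    valid = valid,
    C_profile = sel$C_profile,
    endo_r = del$endo, mid_r = del$mid, epi_r = del$epi,
    far_off_endo = far_endo, far_off_epi = far_epi)
}

#' Iterative spherical-model RV fit
#'
#' The core model-fitting loop: 48 x 96 radial count profiles are
#' extracted from the current sphere centre of the LV-masked, normalised
#' volume; valid profiles are selected and delineated; the sphere is
#' refitted (algebraic least squares) to the mid-myocardial points whose
#' epicardial and endocardial crossings are both within the far-off
#' distance; and the loop repeats until the centre moves less than
#' `tol` mm and the radius changes less than `tol` mm, or `max_iter`
#' iterations are reached.
#'
#' @param vol_norm A [scalar_volume()] normalised to LV max = 1 with the
#'   LV region already excluded (see [segment_rv()]).
#' @param init Initial [sphere_model()] from [init_rv_sphere()] or a
#'   user override.
#' @param voxel Voxel size in mm.
#' @param n_long,n_lat Profile grid (default 48 x 96 = 4608 profiles).
#' @param tol,max_iter Convergence tolerance (mm) and iteration cap.
#' @param lv_epi Optional [ellipsoid_model()] of the (dilated) LV
#'   exclusion surface.  Delineations whose endocardial crossing abuts
#'   the exclusion boundary are truncated by it, not by true RV
#'   anatomy, and are dropped from the refit.
#' @return List with `model` (final [sphere_model()]), `iterations`,
#'   `n_valid` (valid-profile count at the final iteration) and
#'   `converged`.
#' @export
fit_rv_model <- function(vol_norm, init, voxel = max(vol_norm$spacing),
                         n_long = 48, n_lat = 96, tol = 0.1,
                         max_iter = 50, lv_epi = NULL) {
  model <- init
  converged <- FALSE
  n_valid <- 0L
  it <- 0
  for (it in seq_len(max_iter)) {
    prof <- extract_radial_profiles(
      vol_norm, model$center, n_long, n_lat,
      max_radius = model$radius + 4 * voxel)
    sel <- select_valid_profiles(prof, model, voxel)
    del <- delineate_profiles(prof, sel, model, voxel)
    trunc <- junction_truncated(del, prof$dirs, model$center, lv_epi, voxel)
    use <- del$valid & !del$far_off_endo & !del$far_off_epi & !trunc
    n_valid <- sum(del$valid)
    if (sum(use) < 4)
      stop("RV not detectable: fewer than 4 usable mid-myocardial points; ",
           "re-initialise the sphere model")
    pts <- sweep(prof$dirs[use, , drop = FALSE] * del$mid_r[use], 2,
                 model$center, "+")
    new_model <- fit_sphere_least_squares(pts)
    dc <- sqrt(sum((new_model$center - model$center)^2))
    dr <- abs(new_model$radius - model$radius)
    model <- new_model
    if (dc < tol && dr < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("RV sphere fit did not converge within ", max_iter,
            " iterations")
  list(model = model, iterations = it, n_valid = n_valid,
       converged = converged)
}

#' Dense surface refinement
#'
#' Repeats the delineation on a dense 120 x 320 profile grid from the
#' final sphere centre, refits a refreshed sphere to the usable dense
#' mid points, and replaces every epicardial/endocardial point whose
#' profile failed the local-maxima criterion with the corresponding
#' point of the refreshed sphere (mid at the sphere surface, epicardial
#' and endocardial at plus/minus half the nominal wall thickness).
#'
#' @inheritParams fit_rv_model
#' @param model Final converged [sphere_model()].
#' @param wall Nominal wall thickness (mm) for replacement offsets.
#' @param n_long,n_lat Dense grid (default 120 x 320 = 38400 profiles).
#' @param lv_epi Optional LV exclusion surface, as in [fit_rv_model()];
#'   junction-truncated delineations are replaced by the refreshed
#'   sphere (the true mid surface continues spherically through the
#'   junction).
#' @return List with `delineation` (tibble as in
#'   [delineate_profiles()] plus a `replaced` flag), `refreshed`
#'   ([sphere_model()]), `n_long`, `n_lat`, `origin`.
#' @export
refine_surfaces <- function(vol_norm, model, voxel = max(vol_norm$spacing),
                            wall = 12.8, n_long = 120, n_lat = 320,
                            lv_epi = NULL) {
  prof <- extract_radial_profiles(
    vol_norm, model$center, n_long, n_lat,
    max_radius = model$radius + 4 * voxel)
  sel <- select_valid_profiles(prof, model, voxel)
  del <- delineate_profiles(prof, sel, model, voxel)
  trunc <- junction_truncated(del, prof$dirs, model$center, lv_epi, voxel)
  use <- del$valid & !del$far_off_endo & !del$far_off_epi & !trunc
  refreshed <- if (sum(use) >= 4) {
    pts <- sweep(prof$dirs[use, , drop = FALSE] * del$mid_r[use], 2,
                 model$center, "+")
    fit_sphere_least_squares(pts)
  } else model
  # replacement radii: distance from the profile origin to the
  # refreshed sphere surface along each ray
  t_s <- ray_sphere_exit(refreshed, model$center, prof$dirs)
  t_s[is.na(t_s)] <- refreshed$radius
  replaced <- !del$valid | trunc
  del$mid_r[replaced] <- t_s[replaced]
  del$epi_r[replaced] <- t_s[replaced] + wall / 2
  del$endo_r[replaced] <- pmax(t_s[replaced] - wall / 2, 0)
  del$replaced <- replaced
  list(delineation = del, refreshed = refreshed, dirs = prof$dirs,
       n_long = n_long, n_lat = n_lat, origin = model$center)
}

#' RV valve plane from the LV valve plane
#'
#' The RV valve plane shares the LV valve plane's tilt in the vertical
#' long-axis view, is parallel to the X axis in the horizontal long-axis
#' view (its normal has no X component), and passes through the line
#' where the LV valve plane meets the LV epicardial surface on the
#' septal side.
#'
#' @param lv An `lv_result` (needs `valve_plane` and `epi`).
#' @return A plane: list with `point` (mm) and `normal` (unit,
#'   basal-pointing).
#' @export
rv_valve_plane <- function(lv) {
  n <- lv$valve_plane$normal
  n_rv <- c(0, n[2], n[3])
  n_rv <- n_rv / sqrt(sum(n_rv^2))
  if (n_rv[3] < 0) n_rv <- -n_rv
  # septal-side point of the LV valve plane on the epicardial surface:
  # walk from the plane's central point toward -X to the ellipsoid exit
  p0 <- lv$valve_plane$point
  t_exit <- ray_ellipsoid_exit(lv$epi, p0, matrix(c(-1, 0, 0), 1))
  pt <- if (is.na(t_exit)) p0 else p0 + c(-t_exit, 0, 0)
  list(point = pt, normal = n_rv)
}

# bivariate polynomial design matrix in (centred polar angle, unwrapped
# azimuth about the free-wall centre), total degree <= degree
rv_poly_basis <- function(theta, phi, degree = 5) {
  u <- theta - pi / 2
  v <- ((phi - pi + pi) %% (2 * pi)) - pi   # azimuth unwrapped about -X
  cols <- list()
  for (i in 0:degree) for (j in 0:(degree - i))
    cols[[length(cols) + 1]] <- u^i * v^j
  do.call(cbind, cols)
}

#' Fit the fifth-degree polynomial mid-myocardial surface
#'
#' Represents the mid-myocardial radius as a bivariate polynomial of
#' total degree 5 in the sphere's angular coordinates (polar angle,
#' azimuth unwrapped about the RV free-wall centre at -X), fitted by
#' damped (Levenberg-Marquardt-style ridge) least squares to the dense
#' mid-myocardial points.  The septal boundary condition ties the
#' surface to the LV epicardium: directions whose LV-epicardial exit
#' distance is close to the sphere radius (the septal junction) enter
#' the fit as high-weight constraint points at that exit distance.
#'
#' @param refined Result of [refine_surfaces()].
#' @param lv An `lv_result` (for the epicardial surface), or `NULL` to
#'   skip the boundary condition.
#' @param degree Polynomial total degree.
#' @param lambda Ridge damping of the normal equations.
#' @param boundary_weight Weight of the septal junction constraints.
#' @return An `rv_surface` object: list with `coef`, `degree`,
#'   `origin`, `refreshed`, `rms_residual`.
#' @export
build_mid_surface <- function(refined, lv = NULL, degree = 5,
                              lambda = 1e-6, boundary_weight = 100) {
  del <- refined$delineation
  keep <- !(del$valid & (del$far_off_endo | del$far_off_epi))
  th <- del$theta[keep]; ph <- del$phi[keep]; r <- del$mid_r[keep]
  w <- rep(1, sum(keep))
  if (!is.null(lv)) {
    # the septal junction is the thin ring of directions where the
    # refreshed sphere meets the LV epicardial surface; only there is
    # the surface tied to the epicardium
    t_exit <- ray_ellipsoid_exit(lv$epi, refined$origin, refined$dirs)
    junction <- !is.na(t_exit) &
      abs(t_exit - refined$refreshed$radius) <= 1
    if (any(junction)) {
      th <- c(th, del$theta[junction])
      ph <- c(ph, del$phi[junction])
      r <- c(r, t_exit[junction])
      w <- c(w, rep(boundary_weight, sum(junction)))
    }
  }
  A <- rv_poly_basis(th, ph, degree)
  if (length(r) < ncol(A) || qr(A)$rank < ncol(A))
    stop("under-determined mid-surface fit")
  AtW <- t(A * w)
  coef <- solve(AtW %*% A + lambda * diag(ncol(A)), AtW %*% r)
  fitted <- as.numeric(A %*% coef)
  rms <- sqrt(stats::weighted.mean((fitted - r)^2, w))
  structure(list(coef = as.numeric(coef), degree = degree,
                 origin = refined$origin, refreshed = refined$refreshed,
                 rms_residual = rms),
            class = "rv_surface")
}

#' Evaluate the polynomial mid-surface radius along directions
#'
#' @param surface An `rv_surface` from [build_mid_surface()].
#' @param theta,phi Polar angles from +Z and azimuths from +X (radians).
#' @return Radii in mm (floored at 1 mm).
#' @export
rv_surface_radius <- function(surface, theta, phi) {
  r <- as.numeric(rv_poly_basis(theta, phi, surface$degree) %*% surface$coef)
  pmax(r, 1)
}

#' @export
print.rv_surface <- function(x, ...) {
  cat(sprintf(
    "<rv_surface> degree-%d polynomial about (%.1f, %.1f, %.1f) mm, RMS residual %.2f mm\n",
    x$degree, x$origin[1], x$origin[2], x$origin[3], x$rms_residual))
  invisible(x)
}

#' Build RV masks and the cavity volume
#'
#' The myocardium mask contains the voxels within half a wall thickness
#' of the polynomial mid-myocardial surface; the cavity mask the voxels
#' strictly inside the endocardial surface (mid minus half wall).  Both
#' are restricted to the apical side of the RV valve plane and exclude
#' the LV epicardial interior.  The cavity volume is the cavity voxel
#' count times the voxel volume.
#'
#' @param surface An `rv_surface`.
#' @param valve RV valve plane (list `point`, `normal`).
#' @param vol The working [scalar_volume()] (grid reference).
#' @param lv An `lv_result` (its epicardial ellipsoid is excluded), or
#'   `NULL`.
#' @param wall_thickness Nominal wall thickness in mm.
#' @return List with `mask_myocardium`, `mask_cavity` (logical arrays)
#'   and `cavity_volume_ml`.
#' @export
build_masks <- function(surface, valve, vol, lv = NULL,
                        wall_thickness = 12.8) {
  d <- dim(vol$data)
  origin <- surface$origin
  rmax <- surface$refreshed$radius + wall_thickness + 15
  lo <- pmax(floor((origin - rmax) / vol$spacing) + 1, 1)
  hi <- pmin(ceiling((origin + rmax) / vol$spacing) + 1, d)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  xs <- (ii - 1) * vol$spacing[1]
  ys <- (jj - 1) * vol$spacing[2]
  zs <- (kk - 1) * vol$spacing[3]
  nx <- length(ii); ny <- length(jj); nz <- length(kk)
  X <- rep(xs, times = ny * nz)
  Y <- rep(rep(ys, each = nx), times = nz)
  Z <- rep(zs, each = nx * ny)
  dx <- X - origin[1]; dy <- Y - origin[2]; dz <- Z - origin[3]
  r <- sqrt(dx^2 + dy^2 + dz^2)
  r[r == 0] <- 1e-9
  theta <- acos(pmin(pmax(dz / r, -1), 1))
  phi <- atan2(dy, dx) %% (2 * pi)
  mid <- rv_surface_radius(surface, theta, phi)
  apical <- (X - valve$point[1]) * valve$normal[1] +
    (Y - valve$point[2]) * valve$normal[2] +
    (Z - valve$point[3]) * valve$normal[3] <= 0
  keep <- apical
  if (!is.null(lv)) {
    keep <- keep & ellipsoid_rho2(lv$epi, cbind(X, Y, Z)) >= 1
    if (!is.null(lv$mask))
      keep <- keep & !lv$mask[cbind(rep(ii, times = ny * nz),
                                    rep(rep(jj, each = nx), times = nz),
                                    rep(kk, each = nx * ny))]
  }
  myo <- abs(r - mid) <= wall_thickness / 2 & keep
  cav <- r < mid - wall_thickness / 2 & keep
  mask_myo <- array(FALSE, d); mask_myo[ii, jj, kk] <- myo
  mask_cav <- array(FALSE, d); mask_cav[ii, jj, kk] <- cav
  list(mask_myocardium = mask_myo, mask_cavity = mask_cav,
       cavity_volume_ml = sum(cav) * prod(vol$spacing) / 1000)
}

#' Segment the right ventricle
#'
#' Full RV pipeline given a segmented LV: normalise counts to the LV
#' maximum, exclude the LV (voxels inside the epicardial surface dilated
#' by one voxel are zeroed), initialise the sphere from the LV model
#' (or user overrides), run the iterative spherical fit, refine the
#' surfaces on the dense profile grid, place the RV valve plane,
#' construct the polynomial mid-myocardial surface and build the masks.
#'
#' @param vol The working short-axis [scalar_volume()] (same grid as
#'   `lv$volume`).
#' @param lv An `lv_result` from [segment_lv()].
#' @param wall_thickness Nominal RV wall thickness in mm (apparent,
#'   resolution-driven; default two voxels total).
#' @param init_center,init_radius Optional user overrides of the
#'   initial sphere.
#' @param n_long,n_lat Model-stage profile grid.
#' @param dense_long,dense_lat Refinement-stage profile grid.
#' @return An `rv_result`: `model`, `refreshed`, `surface`,
#'   `delineation`, `valve_plane`, `mask_myocardium`, `mask_cavity`,
#'   `cavity_volume_ml`, `n_valid_profiles`, `iterations`, `converged`.
#' @export
segment_rv <- function(vol, lv, wall_thickness = 12.8,
                       init_center = NULL, init_radius = NULL,
                       n_long = 48, n_lat = 96,
                       dense_long = 120, dense_lat = 320) {
  voxel <- max(vol$spacing)
  norm <- vol$data / lv$max_count
  # LV exclusion: zero out the epicardial interior dilated by one voxel
  d <- dim(vol$data)
  idx <- which(array(TRUE, d))
  # evaluate the inflated ellipsoid only near the LV for speed
  lo <- pmax(floor((lv$epi$center - max(lv$epi$semi_axes) - voxel) /
                     vol$spacing) + 1, 1)
  hi <- pmin(ceiling((lv$epi$center + max(lv$epi$semi_axes) + voxel) /
                       vol$spacing) + 1, d)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  pos <- as.matrix(expand.grid(x = (ii - 1) * vol$spacing[1],
                               y = (jj - 1) * vol$spacing[2],
                               z = (kk - 1) * vol$spacing[3]))
  inside <- ellipsoid_rho2(lv$epi, pos, inflate_mm = voxel) < 1
  sub <- norm[ii, jj, kk]
  sub[array(inside, dim = c(length(ii), length(jj), length(kk)))] <- 0
  norm[ii, jj, kk] <- sub
  vol_norm <- scalar_volume(norm, vol$spacing)

  lv_excl <- ellipsoid_model(lv$epi$center, lv$epi$semi_axes + voxel,
                             lv$epi$orientation)
  init <- init_rv_sphere(lv, center = init_center, radius = init_radius)
  if (is.null(init_radius)) {
    # batch-mode stand-in for the interactive re-initialisation the
    # semiautomatic workflow offers on "RV not detectable": retry with
    # alternative initial radii in a fixed, deterministic order
    fit <- NULL
    for (mult in c(1, 1.2, 0.8, 1.4)) {
      cand <- sphere_model(init$center, mult * init$radius)
      fit <- tryCatch(fit_rv_model(vol_norm, cand, voxel, n_long, n_lat,
                                   lv_epi = lv_excl),
                      error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit))
      stop("RV not detectable: fewer than 4 usable mid-myocardial points; ",
           "re-initialise the sphere model")
  } else {
    fit <- fit_rv_model(vol_norm, init, voxel, n_long, n_lat,
                        lv_epi = lv_excl)
  }
  refined <- refine_surfaces(vol_norm, fit$model, voxel, wall_thickness,
                             dense_long, dense_lat, lv_epi = lv_excl)
  valve <- rv_valve_plane(lv)
  surface <- build_mid_surface(refined, lv)
  masks <- build_masks(surface, valve, vol, lv, wall_thickness)

  structure(c(list(model = fit$model, refreshed = refined$refreshed,
                   surface = surface, delineation = refined$delineation,
                   valve_plane = valve, init = init,
                   volume_norm = vol_norm,
                   n_valid_profiles = fit$n_valid,
                   iterations = fit$iterations,
                   converged = fit$converged,
                   wall_thickness = wall_thickness),
              masks),
            class = "rv_result")
}

#' @export
print.rv_result <- function(x, ...) {
  cat(sprintf(
    "<rv_result> sphere centre (%.1f, %.1f, %.1f) mm, radius %.1f mm\n",
    x$model$center[1], x$model$center[2], x$model$center[3],
    x$model$radius))
  cat(sprintf(
    "  %d/%d profiles valid at convergence (%d iterations), cavity %.1f ml\n",
    x$n_valid_profiles, 48 * 96, x$iterations, x$cavity_volume_ml))
  invisible(x)
}

#' Segment both ventricles
#'
#' Convenience wrapper: pre-reorientation, LV segmentation (automatic
#' initial cluster unless a bounding box is supplied), then RV
#' segmentation on the LV's working volume.
#'
#' @param vol A [scalar_volume()].
#' @param box Optional LV bounding box override (2 x 3 voxel ranges).
#' @param prior_angle Pre-reorientation angle in degrees.
#' @param ... Passed on to [segment_rv()].
#' @return List with elements `lv` and `rv`.
#' @export
segment_ventricles <- function(vol, box = NULL, prior_angle = 0, ...) {
  vol <- prereorient(vol, prior_angle)
  lv <- segment_lv(vol, box = box)
  rv <- segment_rv(lv$volume, lv, ...)
  list(lv = lv, rv = rv)
}


# delineations whose endocardial crossing abuts the LV-exclusion
# boundary are truncated by the exclusion, not by anatomy
junction_truncated <- function(del, dirs, origin, lv_epi, voxel) {
  if (is.null(lv_epi)) return(rep(FALSE, nrow(del)))
  t_x <- ray_ellipsoid_exit(lv_epi, origin, dirs)
  del$valid & !is.na(t_x) & del$endo_r <= t_x + voxel / 2
}
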