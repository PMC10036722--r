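#' Pre-reorientation of a transversal volume
#'
#' Rotates the reconstructed transversal volume about the Y axis by a
#' predefined prior angle to approximate the short-axis view before any
#' model fitting.  The prior angle is a population average and is
#' dataset-dependent; synthetic phantoms from [generate_phantom()] are
#' already short-axis, so the default is 0 degrees (identity, no
#' resampling).
#'
#' @param vol A [scalar_volume()].
#' @param prior_angle Rotation angle in degrees about Y.
#' @return A [scalar_volume()].
#' @export
prereorient <- function(vol, prior_angle = 0) rotate_volume_y(vol, prior_angle)

#' Initial LV cluster detection
#'
#' Binarises the volume at 50% of the maximum count found in the
#' upper-right search region of the transversal slices, labels connected
#' components (26-connectivity), and selects the component that looks
#' most like an LV: volume within the expected size window and closest
#' to the centre of the search region.  The returned bounding box is a
#' suggestion; in the semiautomatic workflow the user may confirm or
#' replace it.
#'
#' @param vol A [scalar_volume()].
#' @param quadrant Length-4 fractions `(x_lo, x_hi, y_lo, y_hi)` of the
#'   grid defining the search region in array coordinates; the default
#'   is the x-upper / y-lower half ("upper-right" in the display
#'   convention where image rows run along Y).  Orientation dialects
#'   vary between vendors, so this is deliberately configurable.
#' @param size_window_ml LV candidate volume window in ml.
#' @return List with `mask` (logical array, the selected component),
#'   `box` (2 x 3 matrix of voxel index ranges), `threshold` (counts).
#' @export
initial_cluster <- function(vol, quadrant = c(0.5, 1, 0, 0.5),
                            size_window_ml = c(15, 400)) {
  d <- dim(vol$data)
  if (max(vol$data) <= min(vol$data)) stop("no LV candidate: constant volume")
  xr <- ceiling(quadrant[1] * d[1]):floor(max(quadrant[2] * d[1], 1))
  yr <- max(ceiling(quadrant[3] * d[2]), 1):floor(quadrant[4] * d[2])
  region_max <- max(vol$data[xr, yr, ])
  if (region_max <= 0) stop("no LV candidate: empty search region")
  thr <- 0.5 * region_max
  fg <- vol$data >= thr
  # restrict to the search region
  keep <- array(FALSE, d); keep[xr, yr, ] <- TRUE
  fg <- fg & keep
  if (!any(fg)) stop("no LV candidate: nothing above threshold")
  lab <- label_components_26(fg)
  sizes <- tabulate(lab[lab > 0])
  vox_ml <- voxel_ml(vol)
  ok <- which(sizes * vox_ml >= size_window_ml[1] &
                sizes * vox_ml <= size_window_ml[2])
  if (length(ok) == 0L)
    stop("no LV candidate in the size window; supply a bounding box")
  qc <- c(mean(range(xr)), mean(range(yr)), (d[3] + 1) / 2)
  score <- vapply(ok, function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    ctr <- colMeans(w)
    -sqrt(sum((ctr - qc)^2))
  }, numeric(1))
  sel <- ok[which.max(score)]
  mask <- lab == sel
  w <- which(mask, arr.ind = TRUE)
  box <- rbind(lo = apply(w, 2, min), hi = apply(w, 2, max))
  list(mask = mask, box = box, threshold = thr)
}

# 26-connected component labelling by breadth-first flood fill over
# foreground voxels (foreground is sparse in binarised MPI volumes).
# The array is padded by one background layer so that linear-index
# neighbour offsets can never wrap across a face into foreground.
label_components_26 <- function(fg) {
  d <- dim(fg)
  dp <- d + 2L
  fgp <- array(FALSE, dp)
  fgp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- fg
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  off_lin <- off[, 1] + off[, 2] * dp[1] + off[, 3] * dp[1] * dp[2]
  labp <- array(0L, dp)
  cur <- 0L
  for (s in which(fgp)) {
    if (labp[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    labp[s] <- cur
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, off_lin, "+")))
      nb <- nb[fgp[nb] & labp[nb] == 0L]
      labp[nb] <- cur
      frontier <- nb
    }
  }
  labp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
}

#' Intra-patient count threshold
#'
#' Generates 10 longitudinal x 10 latitudinal radial count profiles from
#' the centre of the LV bounding box, averages them sample-wise, and
#' returns the maximum of the averaged profile.  This average-profile
#' maximum adapts the myocardial threshold to the count level of the
#' individual study.
#'
#' @param vol A [scalar_volume()].
#' @param box 2 x 3 matrix of voxel index ranges (rows lo/hi), as
#'   returned by [initial_cluster()].
#' @return Scalar threshold in counts.
#' @export
intra_patient_threshold <- function(vol, box) {
  box <- as.matrix(box)
  d <- dim(vol$data)
  if (any(box[1, ] > box[2, ])) stop("empty bounding box")
  if (any(box[2, ] < 1) || any(box[1, ] > d)) stop("box outside volume")
  ctr_vox <- colMeans(box)
  ctr <- (ctr_vox - 1) * vol$spacing
  half_diag <- sqrt(sum(((box[2, ] - box[1, ]) * vol$spacing / 2)^2))
  prof <- extract_radial_profiles(vol, ctr, n_long = 10, n_lat = 10,
                                  max_radius = max(half_diag, 10))
  max(colMeans(prof$samples))
}

# pick the best myocardial point on each profile: the global maximum if
# it lies within `prox` mm of the model surface along the ray, otherwise
# the local maximum nearest the surface; returns NA index when no local
# maximum clears `floor_value`
choose_profile_peaks <- function(samples, radii, surf_r, prox, floor_value) {
  n <- nrow(samples); m <- ncol(samples)
  inner <- samples[, 2:(m - 1), drop = FALSE]
  is_max <- inner > samples[, 1:(m - 2), drop = FALSE] &
    inner >= samples[, 3:m, drop = FALSE]
  idx <- rep(NA_integer_, n)
  gi <- max.col(samples, ties.method = "first")
  g_ok <- abs(radii[gi] - surf_r) <= prox & samples[cbind(1:n, gi)] > floor_value
  idx[g_ok] <- gi[g_ok]
  todo <- which(!g_ok)
  if (length(todo)) {
    cand <- is_max[todo, , drop = FALSE] &
      inner[todo, , drop = FALSE] > floor_value
    pen <- abs(matrix(radii[2:(m - 1)], length(todo), m - 2, byrow = TRUE) -
                 surf_r[todo])
    pen[!cand] <- Inf
    best <- max.col(-pen, ties.method = "first")
    has <- is.finite(pen[cbind(seq_along(todo), best)])
    idx[todo[has]] <- best[has] + 1L
  }
  idx
}

#' Segment the left ventricle
#'
#' Iterative ellipsoid-model LV segmentation: voxels of the initial
#' cluster above the intra-patient threshold seed an algebraic ellipsoid
#' fit; radial count profiles from the ellipsoid centre then provide one
#' best myocardial point each (profile maximum near the current surface),
#' the model is refitted, and the loop repeats until the centre moves
#' less than `tol` mm and no semi-axis changes by more than `tol` mm (or
#' `max_iter` iterations, with a warning).  The volume is considered
#' already short-axis if the fitted long axis lies within `reorient_tol`
#' degrees of Z; otherwise it is rotated to align the long axis with Z
#' and the model is refitted once.  The valve plane is the basal-most
#' plane perpendicular to the long axis at which the circumferential
#' mean mid-myocardial count falls below half the mid-ventricular
#' plateau (the median over the middle third of the long axis).
#'
#' @param vol A [scalar_volume()] (short-axis or near short-axis).
#' @param box Optional 2 x 3 bounding box (voxel index ranges); when
#'   `NULL`, [initial_cluster()] is run.  Supplying the box is the
#'   semiautomatic override.
#' @param wall LV wall thickness in mm used for the epicardial offset
#'   surface and delineation fallbacks.
#' @param n_long,n_lat Profile grid used during model iteration.
#' @param tol,max_iter Convergence tolerance (mm) and iteration cap.
#' @param reorient_tol Degrees of long-axis tilt tolerated without
#'   resampling.
#' @param floor_frac Minimum accepted myocardial-point count as a
#'   fraction of the box maximum.  Keeps the model on the LV when a
#'   bright RV free wall leaks into the initial cluster: by the
#'   method's premise the RV stays well below the LV peak.
#' @return An `lv_result` list: `model` (mid-myocardial
#'   [ellipsoid_model()]), `epi`/`endo` models (offset by half the
#'   wall), `mask` (logical array), `valve_plane` (list `point`,
#'   `normal`), `max_count`, `intra_patient_threshold`, `iterations`,
#'   `converged`, `volume` (the possibly reoriented working volume),
#'   `profile_radii` (tibble of per-profile epi/mid/endo radii).
#' @export
segment_lv <- function(vol, box = NULL, wall = 10,
                       n_long = 24, n_lat = 48,
                       tol = 0.1, max_iter = 50, reorient_tol = 3,
                       floor_frac = 0.65) {
  if (is.null(box)) {
    ic <- initial_cluster(vol)
    box <- ic$box
  } else box <- as.matrix(box)
  thr <- intra_patient_threshold(vol, box)

  sub <- vol$data[box[1, 1]:box[2, 1], box[1, 2]:box[2, 2],
                  box[1, 3]:box[2, 3], drop = FALSE]
  floor_lv <- max(thr, floor_frac * max(sub))
  w <- which(sub >= floor_lv, arr.ind = TRUE)
  if (nrow(w) < 9) stop("too few voxels above the intra-patient threshold")
  pts <- voxel_to_mm(sweep(w, 2, box[1, ] - 1, "+"), vol)
  # the cluster can merge the LV with a bright RV crescent, driving the
  # algebraic quadric out of the ellipsoid class; fall back to the
  # moment estimate and let the profile iterations refine it
  model <- tryCatch(fit_ellipsoid_least_squares(pts),
                    error = function(e) moment_ellipsoid(pts))

  box_max <- max(sub)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    prof <- extract_radial_profiles(
      vol, model$center, n_long, n_lat,
      max_radius = 1.6 * max(model$semi_axes) + 10)
    surf_r <- ray_ellipsoid_exit(model, model$center, prof$dirs)
    surf_r[is.na(surf_r)] <- max(model$semi_axes)
    idx <- choose_profile_peaks(prof$samples, prof$radii, surf_r,
                                prox = 2 * max(vol$spacing),
                                floor_value = floor_frac * box_max)
    sel <- which(!is.na(idx))
    if (length(sel) < 9) stop("degenerate LV fit: too few profile points")
    ppts <- prof$dirs[sel, , drop = FALSE] * prof$radii[idx[sel]]
    ppts <- sweep(ppts, 2, model$center, "+")
    new_model <- tryCatch(fit_ellipsoid_least_squares(ppts),
                          error = function(e) moment_ellipsoid(ppts))
    dc <- sqrt(sum((new_model$center - model$center)^2))
    da <- max(abs(new_model$semi_axes - model$semi_axes))
    model <- new_model
    if (dc < tol && da < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("LV ellipsoid fit did not converge; using the last model")

  # reorient so the long axis lies along Z
  long_axis <- model$orientation[, 3]
  if (long_axis[3] < 0) long_axis <- -long_axis
  tilt <- acos(min(max(long_axis[3], -1), 1)) * 180 / pi
  if (tilt > reorient_tol) {
    R <- rotation_between(c(0, 0, 1), long_axis)
    vol <- resample_rotated(vol, R)
    ctr_g <- (dim(vol$data) - 1) * vol$spacing / 2
    model <- ellipsoid_model(
      center = as.numeric(ctr_g + t(R) %*% (model$center - ctr_g)),
      semi_axes = model$semi_axes,
      orientation = t(R) %*% model$orientation)
  }

  # dense per-profile delineation at 50% of the per-profile peak
  dn_long <- 48; dn_lat <- 96
  origin <- model$center
  prof <- extract_radial_profiles(
    vol, origin, dn_long, dn_lat,
    max_radius = 1.6 * max(model$semi_axes) + 10)
  surf_r <- ray_ellipsoid_exit(model, model$center, prof$dirs)
  surf_r[is.na(surf_r)] <- max(model$semi_axes)
  idx <- choose_profile_peaks(prof$samples, prof$radii, surf_r,
                              prox = 2 * max(vol$spacing),
                              floor_value = floor_frac * box_max)
  del <- delineate_runs(prof, idx, rel_threshold = 0.5)
  mid_r <- del$mid; epi_r <- del$epi; endo_r <- del$endo
  fallback <- is.na(mid_r)

  # final refit on the sub-sample-accurate delineated mid points; the
  # peak samples used during iteration are quantised to the radial step
  if (sum(!fallback) >= 9) {
    mpts <- sweep(prof$dirs[!fallback, , drop = FALSE] * mid_r[!fallback],
                  2, model$center, "+")
    refit <- tryCatch(fit_ellipsoid_least_squares(mpts),
                      error = function(e) NULL)
    if (!is.null(refit)) model <- refit
  }
  surf_r <- ray_ellipsoid_exit(model, origin, prof$dirs)
  surf_r[is.na(surf_r)] <- max(model$semi_axes)
  mid_r[fallback] <- surf_r[fallback]
  epi_r[fallback] <- surf_r[fallback] + wall / 2
  endo_r[fallback] <- pmax(surf_r[fallback] - wall / 2, 0)

  valve <- lv_valve_plane(vol, model)

  mask <- mask_from_radial_surface(vol, origin, dn_long, dn_lat,
                                   endo_r, epi_r, valve)
  max_count <- if (any(mask)) max(vol$data[mask]) else max(vol$data)

  structure(list(
    model = model,
    epi = ellipsoid_model(model$center, model$semi_axes + wall / 2,
                          model$orientation),
    endo = ellipsoid_model(model$center,
                           pmax(model$semi_axes - wall / 2, 1),
                           model$orientation),
    wall = wall,
    mask = mask,
    valve_plane = valve,
    max_count = max_count,
    intra_patient_threshold = thr,
    iterations = it,
    converged = converged,
    volume = vol,
    profile_radii = tibble::tibble(
      long_index = prof$index[, "i"], lat_index = prof$index[, "j"],
      theta = prof$theta, phi = prof$phi,
      endo_r = endo_r, mid_r = mid_r, epi_r = epi_r,
      delineated = !fallback)),
    class = "lv_result")
}

#' @export
print.lv_result <- function(x, ...) {
  cat(sprintf(
    "<lv_result> semi-axes %.1f/%.1f/%.1f mm, centre (%.1f, %.1f, %.1f) mm\n",
    x$model$semi_axes[1], x$model$semi_axes[2], x$model$semi_axes[3],
    x$model$center[1], x$model$center[2], x$model$center[3]))
  cat(sprintf("  valve plane z = %.1f mm, LV max count %.4g, %d iterations%s\n",
              x$valve_plane$point[3], x$max_count, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

# rotation taking unit vector `from` onto unit vector `to`
rotation_between <- function(to, from) {
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  c0 <- sum(from * to)
  if (c0 < -1 + 1e-12) return(diag(c(-1, -1, 1)))
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c0)
}

# circumferential mean of mid-myocardial counts per axial level, then
# the basal-most plane where it drops below half the plateau
lv_valve_plane <- function(vol, model) {
  a <- model$semi_axes
  cz <- model$center[3]
  b <- a[3]
  zs <- seq(cz - 0.95 * b, cz + 0.95 * b, by = vol$spacing[3] / 2)
  ang <- seq(0, 2 * pi, length.out = 65)[-65]
  mean_counts <- vapply(zs, function(z) {
    s <- 1 - ((z - cz) / b)^2
    if (s <= 0) return(0)
    rx <- a[1] * sqrt(s); ry <- a[2] * sqrt(s)
    p <- cbind(model$center[1] + rx * cos(ang),
               model$center[2] + ry * sin(ang), z)
    mean(interp_trilinear(vol, p))
  }, numeric(1))
  mid <- zs >= cz - b / 3 & zs <= cz + b / 3
  plateau <- stats::median(mean_counts[mid])
  basal <- which(zs > cz & mean_counts < 0.5 * plateau)
  z_v <- if (length(basal)) zs[min(basal)] else cz + 0.95 * b
  list(point = c(model$center[1], model$center[2], z_v),
       normal = c(0, 0, 1))
}

# delineate the above-threshold run around each chosen peak; threshold is
# `rel_threshold` times the peak value (LV) -- RV uses eq5_threshold via
# its own wrapper.  Returns epi/endo/mid radii with sub-sample linear
# interpolation of the crossings; NA where idx is NA.
delineate_runs <- function(prof, idx, rel_threshold = NULL,
                           abs_threshold = NULL) {
  n <- nrow(prof$samples); m <- ncol(prof$samples)
  epi <- endo <- mid <- rep(NA_real_, n)
  radii <- prof$radii
  for (p in which(!is.na(idx))) {
    s <- prof$samples[p, ]
    i0 <- idx[p]
    thr <- if (!is.null(rel_threshold)) rel_threshold * s[i0]
           else abs_threshold[p]
    if (!is.finite(thr) || s[i0] <= thr) next
    lo <- i0; while (lo > 1 && s[lo - 1] > thr) lo <- lo - 1
    hi <- i0; while (hi < m && s[hi + 1] > thr) hi <- hi + 1
    endo[p] <- if (lo == 1) radii[1] else
      radii[lo] - (thr - s[lo]) / (s[lo - 1] - s[lo]) * prof$step
    epi[p] <- if (hi == m) radii[m] else
      radii[hi] + (s[hi] - thr) / (s[hi] - s[hi + 1]) * prof$step
    mid[p] <- (epi[p] + endo[p]) / 2
  }
  list(epi = epi, endo = endo, mid = mid)
}

# build a voxel mask from per-direction inner/outer radii given on the
# same regular angular grid as the profiles (nearest-bin lookup), clipped
# to the apical side of a valve plane
mask_from_radial_surface <- function(vol, origin, n_long, n_lat,
                                     r_in, r_out, valve = NULL,
                                     exclude = NULL) {
  d <- dim(vol$data)
  rmax <- max(r_out, na.rm = TRUE)
  lo <- pmax(floor((origin - rmax) / vol$spacing) + 1, 1)
  hi <- pmin(ceiling((origin + rmax) / vol$spacing) + 1, d)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  xs <- (ii - 1) * vol$spacing[1] - origin[1]
  ys <- (jj - 1) * vol$spacing[2] - origin[2]
  zs <- (kk - 1) * vol$spacing[3] - origin[3]
  nx <- length(ii); ny <- length(jj); nz <- length(kk)
  X <- rep(xs, times = ny * nz)
  Y <- rep(rep(ys, each = nx), times = nz)
  Z <- rep(zs, each = nx * ny)
  r <- sqrt(X^2 + Y^2 + Z^2)
  r[r == 0] <- 1e-9
  theta <- acos(pmin(pmax(Z / r, -1), 1))
  phi <- atan2(Y, X) %% (2 * pi)
  bi <- pmin(pmax(ceiling(theta / pi * n_long), 1L), n_long)
  bj <- (round(phi / (2 * pi) * n_lat) %% n_lat) + 1L
  bin <- (bi - 1L) * n_lat + bj
  inside <- r >= r_in[bin] & r <= r_out[bin]
  inside[is.na(inside)] <- FALSE
  if (!is.null(valve)) {
    nrm <- valve$normal
    side <- (X + origin[1] - valve$point[1]) * nrm[1] +
      (Y + origin[2] - valve$point[2]) * nrm[2] +
      (Z + origin[3] - valve$point[3]) * nrm[3]
    inside <- inside & side <= 0
  }
  if (!is.null(exclude)) {
    pos <- cbind(X + origin[1], Y + origin[2], Z + origin[3])
    inside <- inside & ellipsoid_rho2(exclude, pos) >= 1
  }
  mask <- array(FALSE, d)
  mask[ii, jj, kk] <- array(inside, dim = c(nx, ny, nz))
  mask
}
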