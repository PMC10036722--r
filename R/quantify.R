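#' Build the RV polar map
#'
#' Projects the segmented RV myocardium onto a 2D angular grid
#' ("bullseye"): each sector is the part of the myocardium volume seen
#' from the RV sphere centre under a given (polar, azimuth) angle, and
#' its value is the maximum count inside it, normalised to the maximum
#' LV count.  Azimuth is measured about the free-wall centre (the -X
#' direction), increasing toward the inferior wall, so the septum sits
#' at the map's lateral edges.
#'
#' @param vol The working [scalar_volume()] (raw counts).
#' @param lv An `lv_result` (supplies the LV maximum used as the
#'   normaliser).
#' @param rv An `rv_result` (supplies the myocardium mask and sphere
#'   centre).
#' @param n_polar,n_azimuth Sector grid (default 18 x 36).
#' @return An `rv_polar_map`: list with `grid` (n_polar x n_azimuth,
#'   NA where the sector contains no myocardium), `psi` and `theta`
#'   sector-centre angles (radians), and `labels` (filled by
#'   [segment_polar_map()]).
#' @export
build_polar_map <- function(vol, lv, rv, n_polar = 18, n_azimuth = 36) {
  mask <- rv$mask_myocardium
  if (!any(mask)) stop("empty RV myocardium mask")
  w <- which(mask)
  d <- dim(vol$data)
  ai <- arrayInd(w, d)
  pos <- voxel_to_mm(ai, vol)
  ctr <- rv$model$center
  dx <- pos[, 1] - ctr[1]; dy <- pos[, 2] - ctr[2]; dz <- pos[, 3] - ctr[3]
  r <- sqrt(dx^2 + dy^2 + dz^2)
  r[r == 0] <- 1e-9
  theta <- acos(pmin(pmax(dz / r, -1), 1))
  psi <- atan2(dy, -dx)
  bi <- pmin(pmax(ceiling(theta / pi * n_polar), 1L), n_polar)
  bj <- pmin(pmax(ceiling((psi + pi) / (2 * pi) * n_azimuth), 1L),
             n_azimuth)
  val <- vol$data[w] / lv$max_count
  grid <- matrix(NA_real_, n_polar, n_azimuth)
  sect <- (bj - 1L) * n_polar + bi
  agg <- tapply(val, sect, max)
  grid[as.integer(names(agg))] <- agg
  structure(list(grid = grid,
                 theta = pi * (seq_len(n_polar) - 0.5) / n_polar,
                 psi = -pi + 2 * pi * (seq_len(n_azimuth) - 0.5) / n_azimuth,
                 n_polar = n_polar, n_azimuth = n_azimuth,
                 labels = NULL),
            class = "rv_polar_map")
}

#' Label polar-map sectors into the three RV wall segments
#'
#' The azimuth range covering the RV free wall is divided into three
#' equal circumferential thirds labelled, in anatomical order, anterior
#' (toward -Y), lateral (the free-wall centre) and inferior (toward
#' +Y); septal-facing sectors outside the free-wall range are excluded.
#'
#' @param map An `rv_polar_map`.
#' @param free_wall_extent_deg Azimuthal extent of the free wall about
#'   its centre, degrees.
#' @return The map with `labels`: a character matrix
#'   (anterior/lateral/inferior/excluded) aligned with `grid`.
#' @export
segment_polar_map <- function(map, free_wall_extent_deg = 240) {
  if (all(is.na(map$grid))) stop("polar map has no myocardium sectors")
  half <- free_wall_extent_deg / 2 * pi / 180
  lab <- character(map$n_azimuth)
  for (j in seq_len(map$n_azimuth)) {
    p <- map$psi[j]
    lab[j] <- if (abs(p) > half) "excluded"
    else if (p < -half / 3) "anterior"
    else if (p <= half / 3) "lateral"
    else "inferior"
  }
  map$labels <- matrix(rep(lab, each = map$n_polar), map$n_polar,
                       map$n_azimuth)
  map$labels[is.na(map$grid)] <- "excluded"
  map
}

#' RV-to-LV uptake ratios from a labelled polar map
#'
#' For each wall segment, the maximal and average RV/LV uptake ratio
#' (sector values x 100); the stress maximal ratio reported for
#' classification is the maximum within the lateral segment.
#'
#' @param map A labelled `rv_polar_map` (see [segment_polar_map()]).
#' @param cavity_volume_ml Optional cavity volume to carry along.
#' @return An `rv_quant`: list with `segments` (tibble: segment,
#'   max_ratio, mean_ratio, n_sectors), `global_max_ratio` (lateral
#'   maximum, percent), `cavity_volume_ml`.
#' @export
rv_lv_ratios <- function(map, cavity_volume_ml = NA_real_) {
  if (is.null(map$labels))
    map <- segment_polar_map(map)
  segs <- c("anterior", "lateral", "inferior")
  rows <- lapply(segs, function(s) {
    v <- map$grid[map$labels == s & !is.na(map$grid)]
    tibble::tibble(segment = s,
                   max_ratio = if (length(v)) 100 * max(v) else NA_real_,
                   mean_ratio = if (length(v)) 100 * mean(v) else NA_real_,
                   n_sectors = length(v))
  })
  segments <- dplyr::bind_rows(rows)
  structure(list(segments = segments,
                 global_max_ratio =
                   segments$max_ratio[segments$segment == "lateral"],
                 cavity_volume_ml = cavity_volume_ml),
            class = "rv_quant")
}

#' @export
print.rv_polar_map <- function(x, ...) {
  cat(sprintf("<rv_polar_map> %d x %d sectors, %d populated\n",
              x$n_polar, x$n_azimuth, sum(!is.na(x$grid))))
  invisible(x)
}

#' @export
print.rv_quant <- function(x, ...) {
  cat("<rv_quant> RV/LV uptake ratios (% of LV max)\n")
  print(x$segments)
  cat(sprintf("stress maximal ratio (lateral): %.1f\n", x$global_max_ratio))
  if (is.finite(x$cavity_volume_ml))
    cat(sprintf("RV cavity volume: %.1f ml\n", x$cavity_volume_ml))
  invisible(x)
}

#' Quantify a segmented RV
#'
#' Convenience wrapper: polar map, segment labels and uptake ratios in
#' one call.
#'
#' @inheritParams build_polar_map
#' @param ... Passed to [build_polar_map()].
#' @return An `rv_quant` (with the polar map attached as `polar_map`).
#' @export
quantify_rv <- function(vol, lv, rv, ...) {
  map <- segment_polar_map(build_polar_map(vol, lv, rv, ...))
  q <- rv_lv_ratios(map, cavity_volume_ml = rv$cavity_volume_ml)
  q$polar_map <- map
  q
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.rv_polar_map <- function(x, ...) {
  g <- expand.grid(polar = seq_len(x$n_polar),
                   azimuth = seq_len(x$n_azimuth))
  tibble::tibble(
    polar = g$polar, azimuth = g$azimuth,
    theta = x$theta[g$polar], psi = x$psi[g$azimuth],
    value = as.vector(x$grid),
    segment = if (is.null(x$labels)) NA_character_ else
      as.vector(x$labels))
}

#' @export
tidy.rv_quant <- function(x, ...) x$segments

#' @export
glance.rv_quant <- function(x, ...) {
  tibble::tibble(global_max_ratio = x$global_max_ratio,
                 cavity_volume_ml = x$cavity_volume_ml)
}

#' @export
tidy.rv_result <- function(x, ...) {
  d <- x$delineation
  d$replaced <- x$delineation$replaced
  d
}

#' @export
glance.rv_result <- function(x, ...) {
  tibble::tibble(
    center_x = x$model$center[1], center_y = x$model$center[2],
    center_z = x$model$center[3], radius = x$model$radius,
    cavity_volume_ml = x$cavity_volume_ml,
    n_valid_profiles = x$n_valid_profiles,
    iterations = x$iterations, converged = x$converged)
}

#' @export
glance.lv_result <- function(x, ...) {
  tibble::tibble(
    center_x = x$model$center[1], center_y = x$model$center[2],
    center_z = x$model$center[3],
    semi_axis_1 = x$model$semi_axes[1], semi_axis_2 = x$model$semi_axes[2],
    semi_axis_3 = x$model$semi_axes[3],
    valve_z = x$valve_plane$point[3], max_count = x$max_count,
    iterations = x$iterations, converged = x$converged)
}
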