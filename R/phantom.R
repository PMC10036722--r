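#' Specification of an analytic cardiac phantom
#'
#' Describes a digital phantom that emulates a reconstructed non-gated
#' myocardial perfusion SPECT volume: an ellipsoidal LV myocardial shell
#' of unit intensity truncated at a valve plane, a fainter partial
#' spherical RV shell wrapping the septum, an optional perfusion defect
#' on the RV free wall, an optional intense hepatic blob adjacent to the
#' inferior wall, and the degradation chain of a reconstructed study:
#' Gaussian resolution blur, a Poisson count draw, and a Butterworth
#' low-pass post-filter.
#'
#' The RV free wall is the part of the spherical shell of mid-surface
#' radius `rv_radius` that lies outside the LV epicardium and on the
#' apical side of the valve plane, so the crescent shape of the RV and
#' its wrap around the septum emerge from the sphere--ellipsoid
#' intersection rather than from a fixed angular cut.  An additional
#' azimuthal clip about the free-wall centre can be requested through
#' `rv_extent_deg` (the full wrap by default), e.g. to emulate a wall
#' that fades before reaching the septal junction.
#'
#' @param dim_vox Grid size per axis (default 64, the classic SPECT
#'   matrix).
#' @param spacing Voxel size in mm (default 6.4, isotropic).
#' @param lv_center LV centre in mm; defaults to a position in the
#'   upper-right quadrant of the transversal slices, mid-stack axially.
#' @param lv_semi_axes LV mid-myocardial semi-axes (mm), short/short/long.
#' @param lv_wall LV wall thickness (mm).
#' @param lv_valve_frac Valve-plane height as a fraction of the long
#'   semi-axis above the LV centre (base is +Z, apex -Z).
#' @param rv_center_offset RV sphere centre minus LV centre (mm); `NULL`
#'   uses the anatomical default `(-a_min, 0, -0.2 * a_max)` with
#'   `a_min`/`a_max` the smallest/largest LV semi-axis (toward the
#'   patient's right and the apex).
#' @param rv_radius RV mid-myocardial sphere radius (mm).
#' @param rv_wall RV apparent wall thickness (mm); the physical wall is
#'   thinner than a voxel, the apparent thickness is resolution-driven.
#' @param rv_fraction RV-to-LV intensity fraction in `[0.2, 0.6]` for
#'   cohort-sampled phantoms (other values are allowed for targeted
#'   fixtures).
#' @param rv_extent_deg Optional azimuthal clip (degrees) of the free
#'   wall about its centre (-X); `NULL` keeps the full emergent wrap.
#' @param defect `NULL`, or a list with `location` (`"basal"` or
#'   `"apical"`) and `severity` (`"mild"`, `"moderate"`, `"severe"`,
#'   mapped to intensity multipliers 0.6 / 0.3 / 0.0).
#' @param liver `NULL`, or a list with `offset` (mm, relative to the LV
#'   centre), `radius` (mm) and `intensity` (relative to LV).
#' @param fwhm_mm Gaussian point-spread FWHM in mm (default 9, the
#'   system resolution); 0 disables blurring.
#' @param counts_lvmax Expected count in the hottest LV voxel; the
#'   pristine volume is scaled so that its LV maximum equals this value
#'   before the Poisson draw.  `NA` keeps the unit intensity scale.
#' @param noise Draw Poisson counts (default TRUE when `counts_lvmax`
#'   is finite)?
#' @param butterworth Apply the Butterworth post-filter?
#' @param butter_order,butter_cutoff Butterworth order and cutoff
#'   (cycles/voxel); defaults 5 and 0.5.
#' @param seed Integer seed for the Poisson draw.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dim_vox = 64L,
                         spacing = 6.4,
                         lv_center = c(262, 148, 186),
                         lv_semi_axes = c(25, 25, 45),
                         lv_wall = 10,
                         lv_valve_frac = 0.6,
                         rv_center_offset = NULL,
                         rv_radius = 35,
                         rv_wall = 12.8,
                         rv_fraction = 0.4,
                         rv_extent_deg = NULL,
                         defect = NULL,
                         liver = NULL,
                         fwhm_mm = 9,
                         counts_lvmax = 100,
                         noise = is.finite(counts_lvmax),
                         butterworth = TRUE,
                         butter_order = 5,
                         butter_cutoff = 0.5,
                         seed = 1L) {
  lv_semi_axes <- as.numeric(lv_semi_axes)
  if (is.null(rv_center_offset))
    rv_center_offset <- c(-min(lv_semi_axes), 0, -0.2 * max(lv_semi_axes))
  if (rv_radius <= 0 || rv_wall <= 0) stop("RV radius and wall must be > 0")
  if (rv_fraction < 0) stop("RV intensity fraction must be >= 0")
  if (!is.null(defect)) {
    defect$location <- match.arg(defect$location, c("basal", "apical"))
    defect$severity <- match.arg(defect$severity,
                                 c("mild", "moderate", "severe"))
  }
  spec <- list(dim_vox = as.integer(dim_vox), spacing = spacing,
               lv_center = as.numeric(lv_center),
               lv_semi_axes = lv_semi_axes, lv_wall = lv_wall,
               lv_valve_frac = lv_valve_frac,
               rv_center_offset = as.numeric(rv_center_offset),
               rv_radius = rv_radius, rv_wall = rv_wall,
               rv_fraction = rv_fraction, rv_extent_deg = rv_extent_deg,
               defect = defect, liver = liver,
               fwhm_mm = fwhm_mm, counts_lvmax = counts_lvmax,
               noise = noise, butterworth = butterworth,
               butter_order = butter_order, butter_cutoff = butter_cutoff,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

severity_multiplier <- c(mild = 0.6, moderate = 0.3, severe = 0.0)

# world coordinate grids for a phantom spec, cached computation
phantom_grid <- function(spec) {
  n <- spec$dim_vox
  ax <- (seq_len(n) - 1) * spec$spacing
  list(x = rep(ax, times = n * n),
       y = rep(rep(ax, each = n), times = n),
       z = rep(ax, each = n * n),
       n = n)
}

# squared normalised ellipsoid radius on the flat grid
grid_rho2 <- function(g, center, semi) {
  ((g$x - center[1]) / semi[1])^2 +
    ((g$y - center[2]) / semi[2])^2 +
    ((g$z - center[3]) / semi[3])^2
}

#' Generate an analytic cardiac phantom
#'
#' Builds the pristine geometry (and from it the ground truth), then
#' applies the degradation chain: Gaussian blur at the stated FWHM, a
#' Poisson draw after scaling the LV maximum to `counts_lvmax`, and a 3D
#' frequency-domain Butterworth low-pass.  Truth masks and the truth
#' cavity volume are computed from the pre-degradation geometry and are
#' therefore blur- and noise-invariant.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `volume` (a [scalar_volume()]), `truth` (list:
#'   `lv_myo`, `rv_myo`, `rv_cavity` logical arrays, `cavity_volume_ml`,
#'   `rv_center`, `rv_radius`, `rv_endo_radius`, `valve_z`, `lv_epi`
#'   [ellipsoid_model()]), and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(noise = FALSE, fwhm_mm = 0,
#'                                     butterworth = FALSE))
#' ph$truth$cavity_volume_ml
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_grid(spec)
  n <- g$n
  a <- spec$lv_semi_axes
  h <- spec$lv_wall / 2
  cz <- spec$lv_center[3]
  z_valve <- cz + spec$lv_valve_frac * max(a)
  below_valve <- g$z <= z_valve

  rho_out <- grid_rho2(g, spec$lv_center, a + h)
  rho_in <- grid_rho2(g, spec$lv_center, pmax(a - h, 1))
  lv_shell <- rho_out <= 1 & rho_in >= 1 & below_valve

  P <- spec$lv_center + spec$rv_center_offset
  dx <- g$x - P[1]; dy <- g$y - P[2]; dz <- g$z - P[3]
  r <- sqrt(dx^2 + dy^2 + dz^2)
  r_endo <- spec$rv_radius - spec$rv_wall / 2
  r_epi <- spec$rv_radius + spec$rv_wall / 2
  outside_lv <- rho_out >= 1
  rv_shell <- r >= r_endo & r <= r_epi & outside_lv & below_valve
  if (!is.null(spec$rv_extent_deg)) {
    psi <- atan2(dy, -dx)                     # azimuth about free-wall centre
    rv_shell <- rv_shell & abs(psi) <= spec$rv_extent_deg * pi / 360
  }
  if (!any(rv_shell))
    stop("RV shell is empty: the sphere lies entirely inside the LV")
  if (any(rv_shell & lv_shell))
    stop("LV and RV shells overlap")                   # cannot happen by construction

  rv_int <- rep(spec$rv_fraction, length(r))
  if (!is.null(spec$defect)) {
    z_lo <- P[3] - spec$rv_radius
    zr <- z_valve - z_lo
    band <- if (spec$defect$location == "basal")
      g$z >= z_valve - 0.3 * zr else g$z <= z_lo + 0.3 * zr
    psi <- atan2(dy, -dx)
    region <- band & abs(psi) <= pi / 3
    rv_int[region] <- rv_int[region] *
      severity_multiplier[[spec$defect$severity]]
  }

  vol <- numeric(n^3)
  vol[lv_shell] <- 1
  vol[rv_shell] <- rv_int[rv_shell]
  if (!is.null(spec$liver)) {
    lc <- spec$lv_center + spec$liver$offset
    liver_mask <- (g$x - lc[1])^2 + (g$y - lc[2])^2 + (g$z - lc[3])^2 <=
      spec$liver$radius^2
    vol[liver_mask] <- pmax(vol[liver_mask], spec$liver$intensity)
  }

  rv_cavity <- r < r_endo & outside_lv & below_valve
  truth <- list(
    lv_myo = array(lv_shell, dim = c(n, n, n)),
    rv_myo = array(rv_shell, dim = c(n, n, n)),
    rv_cavity = array(rv_cavity, dim = c(n, n, n)),
    cavity_volume_ml = sum(rv_cavity) * spec$spacing^3 / 1000,
    rv_center = P, rv_radius = spec$rv_radius,
    rv_endo_radius = r_endo, rv_epi_radius = r_epi,
    valve_z = z_valve,
    lv_epi = ellipsoid_model(spec$lv_center, a + h),
    lv_endo = ellipsoid_model(spec$lv_center, pmax(a - h, 1)))

  arr <- array(vol, dim = c(n, n, n))
  arr <- degrade_volume(arr, truth$lv_myo, spec)
  list(volume = scalar_volume(arr, spec$spacing), truth = truth, spec = spec)
}

# blur -> scale -> Poisson -> Butterworth, in that order
degrade_volume <- function(arr, lv_mask, spec) {
  n <- dim(arr)[1]
  if (spec$fwhm_mm > 0) {
    sigma_vox <- spec$fwhm_mm / (2 * sqrt(2 * log(2))) / spec$spacing
    arr <- fft_gaussian_blur(arr, sigma_vox)
  }
  if (is.finite(spec$counts_lvmax)) {
    mx <- max(arr[lv_mask])
    if (mx <= 0) stop("LV region has no counts; cannot scale")
    arr <- arr * (spec$counts_lvmax / mx)
  }
  if (spec$noise) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(spec$seed)
    arr <- array(stats::rpois(length(arr), pmax(arr, 0)), dim = dim(arr))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    arr <- arr * 1.0
  }
  if (spec$butterworth)
    arr <- fft_butterworth(arr, spec$butter_order, spec$butter_cutoff)
  arr[arr < 0] <- 0
  arr
}

# frequency coordinates (cycles/voxel) for an FFT of length n
fft_freq <- function(n) {
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
  head(k, n) / n
}

apply_fft_filter <- function(arr, H) {
  out <- Re(stats::fft(stats::fft(arr) * H, inverse = TRUE)) / length(arr)
  out
}

# separable Gaussian blur via the frequency domain (periodic boundaries;
# cardiac activity sits well inside the grid so wrap-around is negligible)
fft_gaussian_blur <- function(arr, sigma_vox) {
  d <- dim(arr)
  Hx <- exp(-2 * pi^2 * sigma_vox^2 * fft_freq(d[1])^2)
  Hy <- exp(-2 * pi^2 * sigma_vox^2 * fft_freq(d[2])^2)
  Hz <- exp(-2 * pi^2 * sigma_vox^2 * fft_freq(d[3])^2)
  H <- outer(outer(Hx, Hy), Hz)
  apply_fft_filter(arr, H)
}

# radially symmetric 3D Butterworth low-pass, cutoff in cycles/voxel
fft_butterworth <- function(arr, order, cutoff) {
  d <- dim(arr)
  fx <- fft_freq(d[1]); fy <- fft_freq(d[2]); fz <- fft_freq(d[3])
  fr2 <- outer(outer(fx^2, fy^2, "+"), fz^2, "+")
  H <- 1 / sqrt(1 + (sqrt(fr2) / cutoff)^(2 * order))
  apply_fft_filter(arr, H)
}

#' Truth RV cavity volume as a function of the sphere radius
#'
#' Voxel-counted cavity volume for a spec whose RV mid-surface radius is
#' replaced by `r_mid` (geometry only; no degradation).  Used to invert a
#' target cavity volume into a sphere radius when sampling cohorts.
#'
#' @param spec A [phantom_spec()].
#' @param r_mid Candidate mid-surface radius (mm).
#' @return Cavity volume in ml.
#' @keywords internal
cavity_volume_for_radius <- function(spec, r_mid) {
  g <- phantom_grid(spec)
  a <- spec$lv_semi_axes
  h <- spec$lv_wall / 2
  z_valve <- spec$lv_center[3] + spec$lv_valve_frac * max(a)
  P <- spec$lv_center + spec$rv_center_offset
  r2 <- (g$x - P[1])^2 + (g$y - P[2])^2 + (g$z - P[3])^2
  keep <- grid_rho2(g, spec$lv_center, a + h) >= 1 & g$z <= z_valve
  r_endo <- r_mid - spec$rv_wall / 2
  sum(keep & r2 < r_endo^2) * spec$spacing^3 / 1000
}

#' Invert a target cavity volume into an RV sphere radius
#'
#' @param spec A [phantom_spec()] (its `rv_radius` is ignored).
#' @param target_ml Desired truth cavity volume (ml).
#' @return Mid-surface radius in mm.
#' @keywords internal
rv_radius_for_volume <- function(spec, target_ml, interval = c(12, 80)) {
  f <- function(r) cavity_volume_for_radius(spec, r) - target_ml
  stats::uniroot(f, interval = interval, tol = 1e-3)$root
}

#' Generate a pair of phantoms with identical geometry
#'
#' Emulates a repeatability experiment (two acquisitions of the same
#' anatomy): the two volumes share one geometry and differ only in their
#' Poisson noise realisation.
#'
#' @param spec A [phantom_spec()].
#' @param seed1,seed2 Distinct integer seeds for the two noise draws.
#' @return List with `volume1`, `volume2`, `truth`, `spec`.
#' @export
generate_repeat_pair <- function(spec, seed1, seed2) {
  if (identical(as.integer(seed1), as.integer(seed2)))
    stop("the two noise seeds must differ")
  s1 <- spec; s1$seed <- as.integer(seed1)
  s2 <- spec; s2$seed <- as.integer(seed2)
  p1 <- generate_phantom(s1)
  p2 <- generate_phantom(s2)
  list(volume1 = p1$volume, volume2 = p2$volume, truth = p1$truth,
       spec = spec)
}

#' Sample a cohort of phantoms
#'
#' Draws phantom anatomies with truth cavity volumes uniform on
#' `volume_range` ml and RV intensity fractions uniform on
#' `fraction_range`, with a perfusion defect present with probability
#' 1/3 (location and severity uniform).  Heart size scales allometrically
#' with the target cavity volume: the LV semi-axes are multiplied by
#' `(V / 110)^(1/3)` relative to the reference anatomy, and the RV sphere
#' radius is then solved so that the voxelised truth cavity volume equals
#' the target.  Per-phantom noise seeds are derived deterministically
#' from `master_seed`.
#'
#' @param n Number of phantoms (>= 1).
#' @param master_seed Integer seed controlling both the anatomy draws and
#'   the derived per-phantom noise seeds.
#' @param volume_range,fraction_range Sampling ranges.
#' @param defect_prob Probability of a perfusion defect.
#' @param ... Further arguments passed to [phantom_spec()] (e.g.
#'   `noise = FALSE`, `fwhm_mm = 0` for pristine cohorts).
#' @return List of `n` elements, each as returned by
#'   [generate_phantom()].
#' @export
generate_cohort <- function(n, master_seed = 1L,
                            volume_range = c(40, 220),
                            fraction_range = c(0.2, 0.6),
                            defect_prob = 1 / 3, ...) {
  if (n < 1) stop("cohort size must be >= 1")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(master_seed))
  vols <- stats::runif(n, volume_range[1], volume_range[2])
  fracs <- stats::runif(n, fraction_range[1], fraction_range[2])
  has_defect <- stats::runif(n) < defect_prob
  loc <- sample(c("basal", "apical"), n, replace = TRUE)
  sev <- sample(c("mild", "moderate", "severe"), n, replace = TRUE)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  lapply(seq_len(n), function(i) {
    s <- (vols[i] / 110)^(1 / 3)
    spec <- phantom_spec(lv_semi_axes = s * c(25, 25, 45),
                         rv_fraction = fracs[i],
                         defect = if (has_defect[i])
                           list(location = loc[i], severity = sev[i]),
                         seed = as.integer(master_seed) + 7919L * i,
                         ...)
    spec$rv_radius <- rv_radius_for_volume(spec, vols[i])
    generate_phantom(spec)
  })
}
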