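# synthetic single-profile helpers: a triangular bump of height `h`
# peaking at radius `peak`, half-width `hw`, sampled every `step` mm
bump_profiles <- function(h, peak, hw = 10, step = 3.2, rmax = 80) {
  radii <- seq(0, rmax, by = step)
  s <- pmax(0, h * (1 - abs(radii - peak) / hw))
  structure(list(origin = c(0, 0, 0), step = step, radii = radii,
                 dirs = matrix(c(1, 0, 0), 1), samples = matrix(s, 1),
                 theta = pi / 2, phi = 0,
                 index = cbind(i = 1L, j = 1L)),
            class = "radial_profiles")
}

test_that("initial sphere placement follows the LV model", {
  lv <- list(model = ellipsoid_model(c(0, 0, 0), c(20, 25, 40)))
  s <- init_rv_sphere(lv)
  expect_equal(s$center, c(-20, 0, -8))
  expect_equal(s$radius, 30)

  lv2 <- list(model = ellipsoid_model(c(10, 5, 2), c(25, 25, 45)))
  expect_equal(init_rv_sphere(lv2)$radius, 37.5)

  o <- init_rv_sphere(lv, center = c(1, 2, 3), radius = 17)
  expect_equal(o$center, c(1, 2, 3))
  expect_equal(o$radius, 17)
})

test_that("adaptive threshold reproduces the worked values", {
  expect_close(eq5_threshold(0.5, 0.5), 0.40, 1e-12)
  expect_close(eq5_threshold(0.25, 0.5), 0.8 / 0.9 * 0.25, 1e-12)
  expect_close(eq5_threshold(0.25, 0.5), 0.22222222, 1e-7)
  expect_close(eq5_threshold(0.4, 0.5), 0.8 / 0.96 * 0.4, 1e-12)
  expect_close(eq5_threshold(0.4, 0.5), 0.33333333, 1e-7)

  # the threshold always sits below the accepted maximum, so the
  # above-threshold run around it is never empty
  g <- expand.grid(cp = seq(0.25, 1, by = 0.01), cm = 0.5)
  expect_true(all(eq5_threshold(g$cp, g$cm) < g$cp))
})

test_that("profile validity conditions mirror the selection rules", {
  sph <- sphere_model(c(0, 0, 0), 40)
  # bump of height 0.4 peaking 4.8 mm outside the surface: valid
  sel <- select_valid_profiles(bump_profiles(0.4, 44.8), sph, voxel = 6.4)
  expect_true(sel$valid)
  expect_close(sel$C_profile, 0.4, 1e-9)
  # 10 mm away: invalid (distance condition)
  expect_false(select_valid_profiles(bump_profiles(0.4, 50.4), sph,
                                     voxel = 6.4)$valid)
  # at the surface but too faint: invalid (count condition)
  expect_false(select_valid_profiles(bump_profiles(0.2, 40), sph,
                                     voxel = 6.4)$valid)
})

test_that("delineation finds crossings, midpoints and far-off flags", {
  sph <- sphere_model(c(0, 0, 0), 40)
  prof <- bump_profiles(0.4, 40)
  sel <- select_valid_profiles(prof, sph, voxel = 6.4)
  del <- delineate_profiles(prof, sel, sph, voxel = 6.4)
  expect_true(del$valid)
  # symmetric triangular bump centred on the sphere: mid at the centre
  expect_close(del$mid_r, 40, prof$step)
  expect_close((del$epi_r + del$endo_r) / 2, del$mid_r, 1e-9)
  expect_true(del$endo_r <= del$mid_r && del$mid_r <= del$epi_r)
  expect_false(del$far_off_epi || del$far_off_endo)

  # epicardial crossing far outside the surface: flagged far-off
  prof2 <- bump_profiles(0.4, 56, hw = 14)
  sel2 <- select_valid_profiles(prof2, sph, voxel = 6.4, floor_value = 0)
  sel2$valid <- TRUE; sel2$peak_index <- which.max(prof2$samples[1, ])
  sel2$C_profile <- max(prof2$samples[1, ])
  del2 <- delineate_profiles(prof2, sel2, sph, voxel = 6.4)
  expect_true(del2$far_off_epi)
})

test_that("sphere fit recovers an isolated spherical shell", {
  # shell |r - 35| <= 6.4 of intensity 0.4 around a known centre
  n <- 64; sp <- 6.4
  ax <- (seq_len(n) - 1) * sp
  ctr <- c(201, 198, 203)
  r <- sqrt(outer(outer((ax - ctr[1])^2, (ax - ctr[2])^2, "+"),
                  (ax - ctr[3])^2, "+"))
  v <- scalar_volume(array(0.4 * (abs(r - 35) <= 6.4), c(n, n, n)), sp)
  init <- sphere_model(ctr + c(4, -4, 3), 30)
  fit <- fit_rv_model(v, init)
  expect_lt(sqrt(sum((fit$model$center - ctr)^2)), 2)
  expect_lt(abs(fit$model$radius - 35), 2)
  expect_true(fit$converged)
})

test_that("full-pipeline RV fit is accurate and deterministic", {
  fx <- fx_pristine()
  rv <- fx$seg$rv
  expect_lt(sqrt(sum((rv$model$center - fx$ph$truth$rv_center)^2)), 3)
  expect_lt(abs(rv$model$radius - fx$ph$truth$rv_radius), 2)

  # identical inputs give bit-identical results (no randomness)
  again <- suppressWarnings(segment_rv(fx$seg$lv$volume, fx$seg$lv))
  expect_identical(again$mask_myocardium, rv$mask_myocardium)
  expect_identical(again$cavity_volume_ml, rv$cavity_volume_ml)
})

test_that("noise repeatability and the basin of attraction", {
  fx <- fx_noisy()
  lv <- fx$seg$lv
  spec <- fx$ph$spec
  other <- generate_phantom(local({s <- spec; s$seed <- 8L; s}))
  lv2 <- suppressWarnings(segment_lv(other$volume))
  rv2 <- suppressWarnings(segment_rv(lv2$volume, lv2))
  expect_lt(abs(rv2$model$radius - fx$seg$rv$model$radius), 1.5)

  # initialisation displaced 10 mm converges to the same model
  init0 <- init_rv_sphere(lv)
  moved <- suppressWarnings(segment_rv(
    lv$volume, lv, init_center = init0$center + c(-6, 6, 5),
    init_radius = init0$radius))
  expect_lt(sqrt(sum((moved$model$center - fx$seg$rv$model$center)^2)), 1)
  expect_lt(abs(moved$model$radius - fx$seg$rv$model$radius), 1)
})

test_that("dense refinement covers 38400 profiles and replaces gaps", {
  fx <- fx_pristine()
  del <- fx$seg$rv$delineation
  expect_equal(nrow(del), 120 * 320)

  # free-wall centre directions are delineated, not replaced
  free_wall <- abs(del$phi - pi) < pi / 6 &
    abs(del$theta - pi / 2) < pi / 6
  expect_equal(sum(del$replaced[free_wall]), 0)

  # a severe basal defect is bridged by model replacement: the surface
  # radius over the defect stays near the sphere radius
  ph <- generate_phantom(phantom_spec(
    defect = list(location = "basal", severity = "severe"),
    noise = FALSE, fwhm_mm = 0, butterworth = FALSE))
  seg <- suppressWarnings(segment_ventricles(ph$volume))
  deld <- seg$rv$delineation
  expect_gt(sum(deld$replaced), sum(del$replaced))
  expect_true(all(is.finite(deld$mid_r)))
  expect_lt(max(abs(deld$mid_r[deld$replaced] -
                      seg$rv$refreshed$radius)), 1)
})

test_that("RV valve plane follows the LV valve plane", {
  lv <- fx_pristine()$seg$lv
  v <- rv_valve_plane(lv)
  expect_equal(v$normal, c(0, 0, 1))
  expect_close(v$point[3], lv$valve_plane$point[3], 1e-6)
  # the shared point sits on the LV epicardial surface
  rho <- rvspect:::ellipsoid_rho2(lv$epi, v$point)
  expect_close(rho, 1, 0.05)

  # tilting the LV valve plane tilts the RV plane identically
  lv_t <- lv
  lv_t$valve_plane$normal <- c(0, sin(10 * pi / 180), cos(10 * pi / 180))
  v_t <- rv_valve_plane(lv_t)
  expect_equal(v_t$normal, lv_t$valve_plane$normal, tolerance = 1e-9)
})

test_that("polynomial mid-surface reproduces analytic shapes", {
  ag <- rvspect:::angular_grid(40, 80)
  mk_refined <- function(r) {
    del <- tibble::tibble(
      long_index = ag$index[, "i"], lat_index = ag$index[, "j"],
      theta = ag$theta, phi = ag$phi, valid = TRUE,
      C_profile = 0.4, endo_r = r - 5, mid_r = r, epi_r = r + 5,
      far_off_endo = FALSE, far_off_epi = FALSE, replaced = FALSE)
    list(delineation = del, refreshed = sphere_model(c(0, 0, 0), mean(r)),
         dirs = ag$dirs, origin = c(0, 0, 0))
  }
  s_const <- build_mid_surface(mk_refined(rep(35, nrow(ag$dirs))), lv = NULL)
  expect_lt(max(abs(rv_surface_radius(s_const, ag$theta, ag$phi) - 35)),
            1e-4)

  r_var <- 35 + 3 * cos(ag$theta)
  s_var <- build_mid_surface(mk_refined(r_var), lv = NULL)
  resid <- rv_surface_radius(s_var, ag$theta, ag$phi) - r_var
  expect_lt(sqrt(mean(resid^2)), 0.1)

  # under-determined fit
  small <- mk_refined(rep(35, nrow(ag$dirs)))
  small$delineation <- small$delineation[1:10, ]
  small$dirs <- small$dirs[1:10, , drop = FALSE]
  expect_error(build_mid_surface(small, lv = NULL), "under-determined")
})

test_that("mask construction matches analytic cap volumes", {
  v <- scalar_volume(array(1, dim = c(64, 64, 64)), spacing = 4)
  ctr <- c(126, 126, 126)
  ag <- rvspect:::angular_grid(40, 80)
  del <- tibble::tibble(
    long_index = ag$index[, "i"], lat_index = ag$index[, "j"],
    theta = ag$theta, phi = ag$phi, valid = TRUE, C_profile = 0.4,
    endo_r = 31, mid_r = 36, epi_r = 41,
    far_off_endo = FALSE, far_off_epi = FALSE, replaced = FALSE)
  refined <- list(delineation = del,
                  refreshed = sphere_model(ctr, 36),
                  dirs = ag$dirs, origin = ctr)
  surf <- build_mid_surface(refined, lv = NULL)
  # plane through the sphere centre, which falls between voxel layers
  valve <- list(point = ctr, normal = c(0, 0, 1))

  # cavity: half-ball of the 30 mm endocardial surface (wall 12)
  m <- build_masks(surf, valve, v, lv = NULL, wall_thickness = 12)
  expect_close(m$cavity_volume_ml / (2 / 3 * pi * 3^3), 1, 0.05)

  # moving the valve plane basal strictly grows the cavity
  m2 <- build_masks(surf, list(point = ctr + c(0, 0, 8.4),
                               normal = c(0, 0, 1)), v, NULL, 12)
  expect_gt(m2$cavity_volume_ml, m$cavity_volume_ml)

  # zero wall: empty myocardium
  m3 <- build_masks(surf, valve, v, NULL, wall_thickness = 0)
  expect_equal(sum(m3$mask_myocardium), 0)
})

test_that("RV outputs are invariant to count scaling", {
  fx <- fx_noisy()
  lv <- fx$seg$lv
  vol10 <- scalar_volume(lv$volume$data * 10, lv$volume$spacing)
  lv10 <- lv
  lv10$volume <- vol10
  lv10$max_count <- lv$max_count * 10
  rv10 <- suppressWarnings(segment_rv(vol10, lv10))
  expect_identical(rv10$mask_myocardium, fx$seg$rv$mask_myocardium)
  expect_equal(rv10$cavity_volume_ml, fx$seg$rv$cavity_volume_ml)
})

test_that("masks stay apical of the valve plane and clear of the LV", {
  fx <- fx_pristine()
  rv <- fx$seg$rv; lv <- fx$seg$lv
  w <- which(rv$mask_cavity, arr.ind = TRUE)
  z <- (w[, 3] - 1) * lv$volume$spacing[3]
  expect_true(all(z <= rv$valve_plane$point[3] + 1e-9))
  expect_false(any(rv$mask_myocardium & lv$mask))
  expect_false(any(rv$mask_cavity & lv$mask))
  expect_equal(rv$cavity_volume_ml,
               sum(rv$mask_cavity) * prod(lv$volume$spacing) / 1000)
})
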