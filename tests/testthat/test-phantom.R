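test_that("pristine phantom support equals the truth geometry", {
  ph <- generate_phantom(phantom_spec(noise = FALSE, fwhm_mm = 0,
                                      butterworth = FALSE))
  support <- ph$volume$data > 0
  expect_identical(support, ph$truth$lv_myo | ph$truth$rv_myo)
  # truth masks are disjoint
  expect_false(any(ph$truth$lv_myo & ph$truth$rv_myo))
  expect_false(any(ph$truth$rv_myo & ph$truth$rv_cavity))
})

test_that("truth cavity volume matches the analytic half-sphere", {
  # RV sphere far from the LV, valve plane through the sphere centre
  # (placed mid-way between voxel layers): endocardial radius 35 mm
  sp <- phantom_spec(rv_center_offset = c(-130, 0, -10),
                     lv_valve_frac = -10 / 45, rv_radius = 41.4,
                     noise = FALSE, fwhm_mm = 0, butterworth = FALSE)
  ph <- generate_phantom(sp)
  expect_close(ph$truth$cavity_volume_ml / (2 / 3 * pi * 3.5^3), 1, 0.03)
})

test_that("phantom generation is deterministic given the seed", {
  p1 <- generate_phantom(phantom_spec(seed = 5L))
  p2 <- generate_phantom(phantom_spec(seed = 5L))
  expect_identical(p1$volume$data, p2$volume$data)
  p3 <- generate_phantom(phantom_spec(seed = 6L))
  expect_false(identical(p1$volume$data, p3$volume$data))
})

test_that("blur conserves counts and truth is degradation-invariant", {
  a <- array(0, c(32, 32, 32)); a[10:20, 12:18, 14:16] <- 3
  b <- rvspect:::fft_gaussian_blur(a, 1.4)
  expect_close(sum(b) / sum(a), 1, 0.005)

  clean <- generate_phantom(phantom_spec(noise = FALSE, fwhm_mm = 0,
                                         butterworth = FALSE))
  dirty <- generate_phantom(phantom_spec(seed = 2L))
  expect_identical(clean$truth$rv_cavity, dirty$truth$rv_cavity)
  expect_equal(clean$truth$cavity_volume_ml, dirty$truth$cavity_volume_ml)
})

test_that("repeat pairs share geometry and differ only in noise", {
  spec <- phantom_spec()
  pair <- generate_repeat_pair(spec, 1L, 2L)
  expect_false(identical(pair$volume1$data, pair$volume2$data))
  expect_equal(pair$truth$cavity_volume_ml,
               generate_phantom(spec)$truth$cavity_volume_ml)
  expect_error(generate_repeat_pair(spec, 3L, 3L), "differ")

  quiet <- phantom_spec(noise = FALSE)
  pq <- generate_repeat_pair(quiet, 1L, 2L)
  expect_identical(pq$volume1$data, pq$volume2$data)
})

test_that("paired noise differences scale like a Poisson process", {
  # mean absolute difference of two independent Poisson draws at rate
  # lambda is 2*lambda*exp(-2*lambda)*(I0+I1)(2*lambda) ~ 2*sqrt(lambda/pi)
  # for large lambda; check the sqrt scaling across two count levels
  mad_at <- function(counts) {
    s1 <- phantom_spec(counts_lvmax = counts, seed = 1L,
                       butterworth = FALSE)
    s2 <- phantom_spec(counts_lvmax = counts, seed = 2L,
                       butterworth = FALSE)
    p1 <- generate_phantom(s1); p2 <- generate_phantom(s2)
    sel <- p1$truth$lv_myo
    mean(abs(p1$volume$data[sel] - p2$volume$data[sel]))
  }
  ratio <- mad_at(400) / mad_at(100)
  expect_close(ratio, 2, 0.25)
})

test_that("cohort sampling hits the stated volume range deterministically", {
  co <- generate_cohort(31, master_seed = 9L, noise = FALSE, fwhm_mm = 0,
                        butterworth = FALSE)
  vols <- vapply(co, function(p) p$truth$cavity_volume_ml, numeric(1))
  expect_length(vols, 31)
  expect_true(all(vols >= 39 & vols <= 221))
  co2 <- generate_cohort(2, master_seed = 17L)
  co3 <- generate_cohort(2, master_seed = 17L)
  expect_identical(co2[[2]]$volume$data, co3[[2]]$volume$data)
  expect_error(generate_cohort(0), ">= 1")
})

test_that("degenerate RV placement is rejected", {
  expect_error(
    generate_phantom(phantom_spec(rv_center_offset = c(5, 0, 0),
                                  rv_radius = 8, rv_wall = 4,
                                  noise = FALSE, fwhm_mm = 0,
                                  butterworth = FALSE)),
    "inside the LV")
})

test_that("perfusion defects carve the stated severity out of the wall", {
  base <- phantom_spec(noise = FALSE, fwhm_mm = 0, butterworth = FALSE)
  sev <- phantom_spec(defect = list(location = "basal",
                                    severity = "severe"),
                      noise = FALSE, fwhm_mm = 0, butterworth = FALSE)
  p0 <- generate_phantom(base); p1 <- generate_phantom(sev)
  # severe defect zeroes part of the free wall but leaves truth intact
  expect_identical(p0$truth$rv_myo, p1$truth$rv_myo)
  expect_lt(sum(p1$volume$data[p1$truth$rv_myo] > 0),
            sum(p0$volume$data[p0$truth$rv_myo] > 0))
})
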