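# Shared, lazily built fixtures.  Heavy objects (phantoms, segmentations,
# cohorts) are built once per test run and reused across files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# pristine phantom: no blur, no noise, no post-filter
fx_pristine <- function() fixture("pristine", function() {
  ph <- generate_phantom(phantom_spec(noise = FALSE, fwhm_mm = 0,
                                      butterworth = FALSE))
  seg <- suppressWarnings(segment_ventricles(ph$volume))
  list(ph = ph, seg = seg)
})

# fully degraded phantom at the default study conditions
fx_noisy <- function() fixture("noisy", function() {
  ph <- generate_phantom(phantom_spec(seed = 7L))
  seg <- suppressWarnings(segment_ventricles(ph$volume))
  list(ph = ph, seg = seg)
})

# the scaled-down evaluation cohort: 20 degraded phantoms
fx_cohort <- function() fixture("cohort", function() {
  cohort <- generate_cohort(20, master_seed = 1L)
  list(cohort = cohort, scores = evaluate_segmentation_cohort(cohort))
})

# paired-noise repeatability experiment on 20 anatomies
fx_repeat <- function() fixture("repeat", function() {
  repeatability_experiment(20, master_seed = 1L)
})

expect_close <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol)
}
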