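# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# miniature atlas + cloud fixtures (fast)
fixture_small <- function() memo("small", make_fixtures(seed = 42))

small_resolution <- function() {
  atlas_resolution(lv_endo = c(12, 7), epi = c(14, 8), rv_endo = c(10, 6),
                   n_ring = 8)
}

# quadrature oracle for the volume of an ellipsoidal cavity truncated at
# z = f * c: slice-area integration, independent of the triangulation path
ellipsoid_cavity_volume_oracle <- function(a, b, c, f, n = 20000) {
  z <- seq(-c, f * c, length.out = n)
  area <- pi * a * b * pmax(0, 1 - (z / c)^2)
  sum((area[-1] + area[-n]) / 2 * diff(z)) / 1000 # mL
}

# brute-force nearest-neighbour distances (double loop)
brute_nn <- function(A, B) {
  apply(A, 1, function(p) min(sqrt(colSums((t(B) - p)^2))))
}

# the scaled-down simulation cohort shared by the cohort-level checks:
# runs the full pipeline once (atlas -> unload -> mesh -> FE -> projection
# -> surrogate) at the coarse preset scale
fixture_cohort_run <- function() memo("cohort_run", {
  run_pipeline(pipeline_config("coarse"),
               outdir = file.path(tempdir(), "shapemech_accept"),
               seed = 2024, verbose = FALSE)
})
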