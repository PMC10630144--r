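# shared fixtures, built once per test session

.cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .cache)) assign(key, builder(), envir = .cache)
  get(key, envir = .cache)
}

# small optics for cheap geometry tests
tiny_optics <- function() optical_config(pupil_grid = 32, psf_size = 16)

desk <- function() cache_get("desk", function() desk_setup())

desk_uncoupled <- function()
  cache_get("desk0", function() desk_setup(coupling_strength = 0))

# the trained three-network ensemble used by estimator, controller and
# acceptance tests; trained once per session (a few minutes)
desk_ensemble <- function() cache_get("ensemble", function() {
  message("training the desk-scale network ensemble (one-off) ...")
  train_desk_ensemble(desk(), seed = 1)
})

# render noisy biplane crops of a fixed wavefront for estimator tests
make_crops <- function(coeffs, basis, optics, n = 50, photons = 3000,
                       background = 10, seed = 1, z_max = 800) {
  phase <- compose_wavefront(coeffs, basis)
  pup <- pupil_function(optics)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    em <- emitter_state(
      x = runif(1, -0.5, 0.5) * optics$pixel_size,
      y = runif(1, -0.5, 0.5) * optics$pixel_size,
      z = runif(1, -z_max, z_max), photons = photons)
    crop <- render_psf(pup, phase, em, optics)
    lapply(crop, function(im)
      matrix(rpois(length(im), im + background), nrow(im)) - background)
  })
}

# the full repeated-compensation experiment shared by the acceptance
# criteria (11 levels x 15 repeats at the default acquisition statistics)
acceptance_experiment <- function() cache_get("acceptance", function() {
  message("running the 11-level x 15-repeat compensation experiment ...")
  s <- desk()
  cfg <- loop_config(focal_shift_constants = s$focal_shift_constants)
  run_convergence_experiment(desk_ensemble(), s$basis, s$optics, s$acq,
                             cfg, levels = seq(0.25, 2.75, 0.25),
                             repeats = 15, seed = 20)
})
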