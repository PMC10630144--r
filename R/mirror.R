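#' Simulated deformable mirror
#'
#' Holds the commanded mirror-mode amplitudes and maps them to the
#' realized wavefront through (i) a saturating stroke nonlinearity
#' `realized = stroke * tanh(commanded / stroke)` per mode, (ii) a
#' cross-coupling matrix in coefficient space, and (iii) optional seeded
#' actuation noise. With identity coupling, unit gain, infinite stroke and
#' zero noise the mirror is ideal.
#'
#' @param basis mode basis the mirror actuates in.
#' @param coupling commanded-to-realized coupling matrix (default
#'   identity).
#' @param response_gain scalar gain on the commanded amplitudes.
#' @param stroke tanh saturation scale (radians/mode, default 4);
#'   `Inf` disables the nonlinearity.
#' @param stroke_limit hard clip on commanded amplitudes (radians); a
#'   command beyond it is clipped with a warning.
#' @param actuation_noise standard deviation (radians/mode) of a random
#'   perturbation drawn at every update.
#' @param noise_seed seed for actuation noise draws.
#' @return object of class `dlao_mirror`.
#' @export
mirror_model <- function(basis, coupling = NULL, response_gain = 1,
                         stroke = 4, stroke_limit = 2 * stroke,
                         actuation_noise = 0, noise_seed = 1) {
  k <- basis$n_modes
  if (is.null(coupling)) coupling <- diag(k)
  stopifnot(all(dim(coupling) == k), response_gain > 0, stroke > 0)
  structure(list(basis = basis, commanded = rep(0, k), coupling = coupling,
                 response_gain = response_gain, stroke = stroke,
                 stroke_limit = stroke_limit,
                 actuation_noise = actuation_noise,
                 noise_seed = noise_seed, n_updates = 0L),
            class = "dlao_mirror")
}

#' Apply a coefficient update to the mirror
#'
#' @param mirror [mirror_model()] object.
#' @param delta coefficient change (radians/mode); must be finite.
#' @return updated mirror.
#' @export
apply_mirror_update <- function(mirror, delta) {
  if (any(!is.finite(delta))) stop("mirror delta must be finite")
  cmd <- mirror$commanded + delta
  if (any(abs(cmd) > mirror$stroke_limit)) {
    warning("commanded amplitude clipped at the mirror stroke limit")
    cmd <- pmin(pmax(cmd, -mirror$stroke_limit), mirror$stroke_limit)
  }
  mirror$commanded <- cmd
  mirror$n_updates <- mirror$n_updates + 1L
  mirror
}

#' Realized mirror coefficients and wavefront
#'
#' @param mirror [mirror_model()] object.
#' @return list with `coefficients` (realized amplitudes) and `phase`
#'   (pupil matrix).
#' @export
mirror_realized <- function(mirror) {
  cmd <- mirror$response_gain * mirror$commanded
  if (is.finite(mirror$stroke))
    cmd <- mirror$stroke * tanh(cmd / mirror$stroke)
  realized <- as.vector(mirror$coupling %*% cmd)
  if (mirror$actuation_noise > 0 && mirror$n_updates > 0) {
    realized <- realized + with_preserved_seed(
      derive_seed(mirror$noise_seed, mirror$n_updates),
      stats::rnorm(length(cmd), 0, mirror$actuation_noise))
  }
  list(coefficients = realized,
       phase = compose_wavefront(realized, mirror$basis))
}

#' Focal-shift compensation for radially symmetric mode changes
#'
#' Amplitude changes of radially symmetric (spherical-like) mirror modes
#' shift the apparent focal plane. The compensating stage offset is a
#' linear combination of the applied deltas, with empirical constants per
#' mode (the physical system uses -0.3 um and -0.2 um per unit amplitude
#' for its two spherical-like modes).
#'
#' @param delta coefficient change applied to the mirror.
#' @param constants named numeric vector: names are basis mode indices,
#'   values um per unit amplitude.
#' @return stage offset in um (to be added to the stage position; the
#'   simulated stage shifts all subsequent emitter axial positions by the
#'   negated accumulated offset).
#' @export
compensate_focal_shift <- function(delta, constants) {
  if (length(constants) == 0) return(0)
  idx <- as.integer(names(constants))
  if (any(is.na(idx)) || any(idx < 1) || any(idx > length(delta)))
    stop("focal-shift constants must be named by valid mode indices")
  sum(constants * delta[idx])
}
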