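#' Optical configuration of the simulated microscope
#'
#' Defines the scalar-diffraction forward model: emission wavelength,
#' numerical aperture, refractive indices on the immersion and sample side,
#' camera sampling and the axial offsets of the two biplane detection
#' planes. All lengths are in nanometres, all phases in radians.
#'
#' The pupil is sampled on a `pupil_grid` x `pupil_grid` Fourier grid whose
#' spatial-frequency step is `1/(pupil_grid * pixel_size)`, so that a plain
#' FFT of the pupil field yields the camera-plane PSF at the camera pixel
#' pitch. Rendered images are central `psf_size` crops of that grid.
#'
#' @param wavelength emission wavelength (nm). Default 690, the approximate
#'   emission peak of far-red dyes such as Alexa Fluor 647 within a
#'   731/137 band-pass.
#' @param na numerical aperture of the objective.
#' @param n_immersion refractive index of the immersion medium.
#' @param n_sample refractive index of the sample medium.
#' @param pixel_size camera pixel pitch referred to the sample plane (nm).
#' @param pupil_grid pupil-plane sampling (pixels per side, even, >= 16).
#' @param psf_size side of rendered PSF crops (pixels, even, >= 16).
#' @param plane_offsets axial offsets (nm) of the two biplane detection
#'   planes, symmetric about nominal focus by default.
#' @return An object of class `dlao_optics` with precomputed pupil-plane
#'   frequency grids, the pupil support mask and axial wavevector maps.
#' @examples
#' opt <- optical_config(pupil_grid = 32, psf_size = 16)
#' sum(opt$support)  # pupil support pixels
#' @export
optical_config <- function(wavelength = 690, na = 1.35, n_immersion = 1.406,
                           n_sample = 1.35, pixel_size = 119,
                           pupil_grid = 64, psf_size = 32,
                           plane_offsets = c(-300, 300)) {
  stopifnot(wavelength > 0, pixel_size > 0)
  if (na >= n_immersion)
    stop("numerical aperture must be smaller than the immersion index")
  if (na > n_sample)
    stop("numerical aperture exceeds the sample-medium index; ",
         "rays beyond the critical angle are not modelled")
  for (g in c(pupil_grid, psf_size)) {
    if (g < 16 || g %% 2 != 0)
      stop("pupil_grid and psf_size must be even and >= 16")
  }
  if (psf_size > pupil_grid)
    stop("psf_size cannot exceed pupil_grid")
  if (length(plane_offsets) != 2)
    stop("plane_offsets must give exactly two detection planes")

  n <- pupil_grid
  f <- (seq_len(n) - 1 - n / 2) / (n * pixel_size)  # cycles / nm
  kx <- matrix(f, n, n, byrow = TRUE)   # column -> x
  ky <- matrix(f, n, n)                 # row -> y
  kr2 <- kx^2 + ky^2
  support <- kr2 <= (na / wavelength)^2
  kz_imm <- sqrt(pmax((n_immersion / wavelength)^2 - kr2, 0))
  kz_sam <- sqrt(pmax((n_sample / wavelength)^2 - kr2, 0))

  obj <- list(wavelength = wavelength, na = na, n_immersion = n_immersion,
              n_sample = n_sample, pixel_size = pixel_size,
              pupil_grid = pupil_grid, psf_size = psf_size,
              plane_offsets = plane_offsets,
              kx = kx, ky = ky, kr2 = kr2, support = support,
              n_support = sum(support), kz_imm = kz_imm, kz_sam = kz_sam)
  class(obj) <- "dlao_optics"
  obj
}

#' @export
print.dlao_optics <- function(x, ...) {
  cat("Simulated microscope optics\n")
  cat(sprintf("  wavelength %g nm, NA %g, n_imm %g, n_sample %g\n",
              x$wavelength, x$na, x$n_immersion, x$n_sample))
  cat(sprintf("  pixel %g nm, pupil grid %d, PSF crop %d\n",
              x$pixel_size, x$pupil_grid, x$psf_size))
  cat(sprintf("  biplane offsets %s nm (%d support pixels)\n",
              paste(x$plane_offsets, collapse = " / "), x$n_support))
  invisible(x)
}

#' Root-mean-square wavefront error
#'
#' RMS of a pupil-phase image over the pupil support, in radians. The phase
#' is taken exactly as given: no piston or tilt term is removed.
#'
#' @param phase pupil-phase matrix (radians) on the optics grid, or a
#'   numeric vector already restricted to support pixels.
#' @param optics a [optical_config()] object supplying the support mask
#'   (ignored when `phase` is a vector).
#' @return W_rms in radians.
#' @export
wrms <- function(phase, optics) {
  if (is.matrix(phase)) {
    if (optics$n_support == 0L) stop("empty pupil support")
    phase <- phase[optics$support]
  }
  if (length(phase) == 0L) stop("empty pupil support")
  sqrt(mean(phase^2))
}

#' Defocus phase for an axial displacement
#'
#' Angular-spectrum defocus term on the immersion side:
#' `phi(k) = 2*pi*z*sqrt((n_immersion/lambda)^2 - |k|^2)` on the pupil
#' support, zero elsewhere.
#'
#' @param z axial displacement (nm); |z| must be at most 5 um for the
#'   default sampling to remain alias-free.
#' @param optics [optical_config()] object.
#' @return pupil-phase matrix (radians).
#' @export
defocus_phase <- function(z, optics) {
  if (abs(z) > 5000)
    stop("|z| > 5 um exceeds the sampling validity guard")
  phase <- 2 * pi * z * optics$kz_imm
  phase[!optics$support] <- 0
  phase
}

#' Depth-dependent index-mismatch aberration
#'
#' Radially symmetric wavefront error accrued by imaging at `depth` nm into
#' a medium of index `n_sample` with an objective corrected for
#' `n_immersion`:
#' `phi(k) = 2*pi*depth*(sqrt((n_sample/lambda)^2-|k|^2) -
#' sqrt((n_immersion/lambda)^2-|k|^2))`. Spatial frequencies that are
#' evanescent on the sample side contribute zero.
#'
#' @param depth imaging depth (nm, >= 0).
#' @param optics [optical_config()] object.
#' @return pupil-phase matrix (radians).
#' @export
index_mismatch_phase <- function(depth, optics) {
  stopifnot(depth >= 0)
  phase <- 2 * pi * depth * (optics$kz_sam - optics$kz_imm)
  phase[!optics$support] <- 0
  phase
}

#' Pupil function container
#'
#' @param optics [optical_config()] object.
#' @param magnitude non-negative pupil magnitude; default the flat
#'   (uniform) circular pupil.
#' @param phase pupil phase (radians); default zero.
#' @return object of class `dlao_pupil`.
#' @export
pupil_function <- function(optics, magnitude = NULL, phase = NULL) {
  n <- optics$pupil_grid
  if (is.null(magnitude)) magnitude <- matrix(as.numeric(optics$support), n, n)
  if (is.null(phase)) phase <- matrix(0, n, n)
  stopifnot(all(dim(magnitude) == n), all(dim(phase) == n))
  if (any(magnitude < 0)) stop("pupil magnitude must be non-negative")
  magnitude[!optics$support] <- 0
  phase[!optics$support] <- 0
  structure(list(magnitude = magnitude, phase = phase,
                 support = optics$support),
            class = "dlao_pupil")
}

# centered FFT: pupil arrays are stored with the zero frequency at
# (n/2+1, n/2+1); the returned image has the emitter-origin PSF centered at
# the same pixel.
fft_centered <- function(field) {
  n <- nrow(field)
  sh <- c((n / 2 + 1):n, 1:(n / 2))
  img <- stats::fft(field[sh, sh])
  img[sh, sh]
}

#' Render the biplane emission pattern of a point emitter
#'
#' Scalar-diffraction forward model. For each detection plane the pupil
#' field `magnitude * exp(i*(pupil phase + aberration + defocus(z + plane
#' offset) + tilt(x, y)))` is Fourier transformed; the squared modulus is
#' normalized so that its sum over the full (untruncated) Fourier grid is
#' one, multiplied by half the emitter photons (a 50/50 beam splitter
#' divides the light between planes), cropped to `psf_size` and offset by
#' the per-pixel background.
#'
#' @param pupil [pupil_function()] object (instrument pupil).
#' @param aberration additional pupil-phase matrix (radians), e.g. a
#'   composed mirror wavefront; `NULL` for none.
#' @param emitter list with `x`, `y`, `z` (nm), `photons`, `background`
#'   (see [emitter_state()]).
#' @param optics [optical_config()] object.
#' @param crop if `FALSE`, return the full `pupil_grid` images (used for
#'   energy accounting).
#' @return list of two `psf_size` x `psf_size` matrices of expected photon
#'   counts, one per detection plane.
#' @export
render_psf <- function(pupil, aberration = NULL, emitter, optics,
                       crop = TRUE) {
  n <- optics$pupil_grid
  half_field <- n / 2 * optics$pixel_size
  if (abs(emitter$x) > half_field || abs(emitter$y) > half_field)
    stop("emitter lies outside the rendered field")
  if (is.null(aberration)) aberration <- 0
  base_phase <- pupil$phase + aberration +
    2 * pi * (optics$kx * emitter$x + optics$ky * emitter$y)
  norm0 <- sum(pupil$magnitude^2) * n^2
  out <- vector("list", 2L)
  for (p in 1:2) {
    ph <- base_phase + defocus_phase(emitter$z + optics$plane_offsets[p],
                                     optics)
    field <- pupil$magnitude * exp(1i * ph)
    img <- Mod(fft_centered(field))^2 / norm0
    img <- img * (emitter$photons / 2)
    if (crop) {
      s <- optics$psf_size
      i0 <- n / 2 - s / 2 + 1
      img <- img[i0:(i0 + s - 1), i0:(i0 + s - 1)]
    }
    out[[p]] <- img + emitter$background
  }
  out
}

#' Point-emitter state
#'
#' @param x,y lateral position (nm, relative to the image center; x right,
#'   y down).
#' @param z axial position (nm, relative to nominal focus).
#' @param photons expected total detected photons (both planes together).
#' @param background expected background photons per pixel per plane.
#' @export
emitter_state <- function(x = 0, y = 0, z = 0, photons = 1000,
                          background = 0) {
  stopifnot(photons >= 0, background >= 0)
  list(x = x, y = y, z = z, photons = photons, background = background)
}

#' Render a through-focus bead stack
#'
#' Noiseless expected-value z-stack of a centered bead, the input of the
#' phase-retrieval and metric-AO baselines. The stack is rendered in a
#' single detection plane at zero offset (the bead scan moves the stage,
#' not the beam splitter).
#'
#' @param pupil [pupil_function()] object.
#' @param aberration additional pupil-phase matrix or `NULL`.
#' @param optics [optical_config()] object.
#' @param z_range range (nm) of bead positions, default -1500..1500.
#' @param z_step step (nm), default 100 (31 slices for the default range).
#' @param photons expected photons per slice.
#' @param background expected background photons per pixel.
#' @return object of class `dlao_psf_stack`: list with `images` (array
#'   z x rows x cols) and `z_positions` (nm).
#' @export
render_bead_stack <- function(pupil, aberration = NULL, optics,
                              z_range = c(-1500, 1500), z_step = 100,
                              photons = 1, background = 0) {
  stopifnot(z_step > 0)
  zs <- seq(z_range[1], z_range[2], by = z_step)
  opt1 <- optics
  opt1$plane_offsets <- c(0, 0)
  s <- optics$psf_size
  images <- array(0, dim = c(length(zs), s, s))
  for (i in seq_along(zs)) {
    em <- emitter_state(z = zs[i], photons = 2 * photons,
                        background = background)
    images[i, , ] <- render_psf(pupil, aberration, em, opt1)[[1]]
  }
  structure(list(images = images, z_positions = zs),
            class = "dlao_psf_stack")
}
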