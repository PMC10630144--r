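#' Metric-based AO configuration
#'
#' Parameters of the iterative trial-then-evaluate baseline: for each
#' mirror mode a set of amplitudes is applied, an image-quality metric
#' (Gaussian-masked center peak signal) is recorded, and the optimal
#' amplitude is taken from a quadratic fit; the sweep over all modes is
#' repeated for several iterations.
#'
#' @param n_amplitudes amplitudes sampled per mode (odd, default 11).
#' @param amplitude_span sweep interval (radians) around the current
#'   amplitude.
#' @param n_iterations full sweeps over all modes (default 5).
#' @param mask_sigma Gaussian mask width (pixels).
#' @export
metric_ao_config <- function(n_amplitudes = 11, amplitude_span = c(-1, 1),
                             n_iterations = 5, mask_sigma = 6) {
  stopifnot(n_amplitudes >= 3, n_amplitudes %% 2 == 1, n_iterations >= 1,
            mask_sigma > 0)
  structure(list(n_amplitudes = n_amplitudes,
                 amplitude_span = amplitude_span,
                 n_iterations = n_iterations, mask_sigma = mask_sigma),
            class = "dlao_metric_ao_config")
}

#' Radial-symmetry center of an emission pattern
#'
#' Sub-pixel symmetry center by the radial-symmetry method: the center is
#' the least-squares intersection of lines through the mid-points of
#' pixel quads along their local gradient directions, weighted by
#' gradient magnitude and inverse distance.
#'
#' @param image numeric matrix (at least 8 x 8, non-constant).
#' @return `c(x, y)` in (column, row) pixel coordinates.
#' @export
radial_symmetry_center <- function(image) {
  if (nrow(image) < 8 || ncol(image) < 8)
    stop("image must be at least 8 x 8")
  if (max(image) == min(image)) stop("constant image has no center")
  n <- nrow(image); m <- ncol(image)
  # cross-derivatives on the dual (half-pixel) grid
  a <- image[1:(n - 1), 1:(m - 1)]
  b <- image[1:(n - 1), 2:m]
  cc <- image[2:n, 1:(m - 1)]
  d <- image[2:n, 2:m]
  du <- b - cc   # along (+x, -y) diagonal
  dv <- d - a    # along (+x, +y) diagonal
  # smooth 3x3 to tame noise
  du <- blur2d(du, 0.7)
  dv <- blur2d(dv, 0.7)
  gx <- (du + dv) / 2
  gy <- (dv - du) / 2
  g2 <- gx^2 + gy^2
  xm <- matrix(seq_len(m - 1) + 0.5, n - 1, m - 1, byrow = TRUE)
  ym <- matrix(seq_len(n - 1) + 0.5, n - 1, m - 1)
  # centroid-based proximity weighting
  tot <- sum(image - min(image))
  xc0 <- sum((image - min(image)) * matrix(seq_len(m), n, m,
                                           byrow = TRUE)) / tot
  yc0 <- sum((image - min(image)) * matrix(seq_len(n), n, m)) / tot
  dcen <- sqrt((xm - xc0)^2 + (ym - yc0)^2)
  w <- g2 / pmax(dcen, 0.5)
  keep <- g2 > 0
  gx <- gx[keep]; gy <- gy[keep]; xm <- xm[keep]; ym <- ym[keep]
  w <- w[keep]
  # line through (xm, ym) with direction (gx, gy): gy*x - gx*y = gy*xm - gx*ym
  A <- cbind(gy, -gx) * sqrt(w)
  rhs <- (gy * xm - gx * ym) * sqrt(w)
  fit <- qr.coef(qr(A), rhs)
  c(x = fit[1], y = fit[2])
}

#' Gaussian-masked center peak signal
#'
#' Multiplies the emission pattern by a symmetric 2D Gaussian placed at
#' the given center and sums the masked image; linear in the image.
#'
#' @param image numeric matrix.
#' @param center `c(x, y)` mask position (pixel coordinates).
#' @param sigma Gaussian mask width (pixels).
#' @return scalar signal.
#' @export
masked_peak_signal <- function(image, center, sigma = 2) {
  n <- nrow(image); m <- ncol(image)
  if (center[1] < 1 || center[1] > m || center[2] < 1 || center[2] > n)
    stop("mask center lies outside the image")
  xg <- matrix(seq_len(m), n, m, byrow = TRUE)
  yg <- matrix(seq_len(n), n, m)
  mask <- exp(-((xg - center[1])^2 + (yg - center[2])^2) / (2 * sigma^2))
  sum(image * mask)
}

#' Vertex of a quadratic fit through metric samples
#'
#' Least-squares parabola through the (amplitude, signal) samples; the
#' vertex is the estimated optimal amplitude. When the fitted curvature
#' is non-negative (no interior maximum) the sampled argmax is returned
#' with a warning. The vertex is clamped to the sampled interval.
#'
#' @param amplitudes distinct sample positions (>= 3).
#' @param signals metric values.
#' @return optimal amplitude (scalar).
#' @export
quadratic_optimum <- function(amplitudes, signals) {
  if (length(amplitudes) < 3) stop("need at least 3 samples")
  if (anyDuplicated(amplitudes)) stop("amplitudes must be distinct")
  fit <- stats::lm.fit(cbind(1, amplitudes, amplitudes^2),
                       as.numeric(signals))
  co <- fit$coefficients
  if (!is.finite(co[3]) || co[3] >= 0) {
    warning("quadratic fit has no maximum; returning the sampled argmax")
    return(amplitudes[which.max(signals)])
  }
  v <- -co[2] / (2 * co[3])
  min(max(v, min(amplitudes)), max(amplitudes))
}

#' Simulated bead scene for metric-based AO
#'
#' Returns a closure that renders an in-focus bead image (single
#' detection plane) under the scene's fixed aberration plus any commanded
#' mirror phase, optionally with Poisson noise.
#'
#' @param aberration fixed sample/system pupil phase (radians) or `NULL`.
#' @param optics [optical_config()] object.
#' @param photons expected bead photons per exposure.
#' @param background expected background photons per pixel.
#' @param noise draw Poisson noise per evaluation.
#' @param z bead axial position (nm).
#' @return function `(command_phase) -> image`.
#' @export
make_bead_scene <- function(aberration = NULL, optics, photons = 2e4,
                            background = 0, noise = FALSE, z = 0) {
  pup <- pupil_function(optics)
  opt1 <- optics
  opt1$plane_offsets <- c(0, 0)
  if (is.null(aberration)) aberration <- matrix(0, optics$pupil_grid,
                                                optics$pupil_grid)
  function(command_phase) {
    ab <- aberration + command_phase
    im <- render_psf(pup, ab,
                     emitter_state(z = z, photons = 2 * photons,
                                   background = background),
                     opt1)[[1]]
    if (noise) im <- matrix(stats::rpois(length(im), im), nrow(im))
    im
  }
}

#' Run iterative metric-based adaptive optics
#'
#' Sequentially sweeps every basis mode over `n_amplitudes` amplitudes
#' around the current correction, evaluates the Gaussian-masked peak
#' signal (re-centering the mask on each image via
#' [radial_symmetry_center()]), applies the quadratic-fit optimum
#' immediately, and repeats the full sweep `n_iterations` times.
#'
#' @param scene function `(command_phase) -> image`, e.g. from
#'   [make_bead_scene()].
#' @param basis mode basis the mirror sweeps.
#' @param config [metric_ao_config()] object.
#' @return list with `correction` (final coefficient vector), `history`
#'   (data.frame of per-mode optima by iteration) and `n_evaluations`.
#' @export
run_metric_ao <- function(scene, basis, config = metric_ao_config()) {
  k <- basis$n_modes
  state <- rep(0, k)
  grid0 <- seq(config$amplitude_span[1], config$amplitude_span[2],
               length.out = config$n_amplitudes)
  hist <- list()
  n_eval <- 0L
  for (it in seq_len(config$n_iterations)) {
    for (mode in seq_len(k)) {
      amps <- state[mode] + grid0
      sig <- vapply(amps, function(a) {
        trial <- state
        trial[mode] <- a
        im <- scene(compose_wavefront(trial, basis))
        n_eval <<- n_eval + 1L
        ctr <- radial_symmetry_center(im)
        ctr[1] <- min(max(ctr[1], 1), ncol(im))
        ctr[2] <- min(max(ctr[2], 1), nrow(im))
        masked_peak_signal(im, ctr, config$mask_sigma)
      }, 0)
      state[mode] <- suppressWarnings(quadratic_optimum(amps, sig))
      hist[[length(hist) + 1]] <- data.frame(iteration = it, mode = mode,
                                             optimum = state[mode])
    }
  }
  list(correction = state, history = do.call(rbind, hist),
       n_evaluations = n_eval)
}
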