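#' Training-set configuration
#'
#' @param n_samples number of training pairs.
#' @param amplitude_range interval of total W_rms (radians) of the drawn
#'   distortions; must lie within `[0, 3.5]`.
#' @param photon_range interval of per-emitter photon counts (uniform).
#' @param background_range interval of background photons/pixel (uniform).
#' @param z_range interval of axial positions (nm, uniform).
#' @param xy_range interval of lateral emitter offsets (pixels, uniform)
#'   around the crop center before recentering.
#' @param recenter if `TRUE` (default), each noisy crop is recentered on
#'   the smoothed peak of the summed planes — the same centering the
#'   subregion segmentation applies — so the training distribution
#'   matches what the estimator sees at inference, including the large
#'   peak-to-emitter displacements of heavily aberrated patterns.
#' @param recenter_sigma smoothing width (pixels) of the recentering
#'   peak search; keep equal to the acquisition `detection_sigma`.
#' @param contaminant_rate expected number (Poisson) of additional
#'   emitters rendered into each training window. Real subregions are
#'   never pristine: at the default acquisition density (13 emitters on a
#'   128-px frame) the 64-px rendering window around a detection contains
#'   on average ~3 other emitters, whose light the estimator must learn
#'   to ignore. Bright contaminants (above `contaminant_bright`) are
#'   placed at least `contaminant_exclusion` pixels away, since a
#'   detected close pair would have been discarded by the isolation rule.
#' @param contaminant_photons exponential mean of contaminant photons.
#' @param contaminant_bright,contaminant_exclusion see above.
#' @param baseline_wavefront static instrument-residual pupil phase added
#'   to every sample (and excluded from the labels), or `NULL`.
#' @param seed RNG seed.
#' @export
training_config <- function(n_samples = 20000, amplitude_range = c(0, 3),
                            photon_range = c(1500, 8000),
                            background_range = c(5, 20),
                            z_range = c(-1000, 1000),
                            xy_range = c(-0.5, 0.5), recenter = TRUE,
                            recenter_sigma = 2, contaminant_rate = 3.2,
                            contaminant_photons = 2500,
                            contaminant_bright = 1200,
                            contaminant_exclusion = 14,
                            baseline_wavefront = NULL, seed = 1) {
  stopifnot(n_samples >= 1, amplitude_range[1] >= 0,
            amplitude_range[2] <= 3.5,
            amplitude_range[1] <= amplitude_range[2],
            contaminant_rate >= 0)
  structure(list(n_samples = n_samples, amplitude_range = amplitude_range,
                 photon_range = photon_range,
                 background_range = background_range, z_range = z_range,
                 xy_range = xy_range, recenter = recenter,
                 recenter_sigma = recenter_sigma,
                 contaminant_rate = contaminant_rate,
                 contaminant_photons = contaminant_photons,
                 contaminant_bright = contaminant_bright,
                 contaminant_exclusion = contaminant_exclusion,
                 baseline_wavefront = baseline_wavefront, seed = seed),
            class = "dlao_training_config")
}

#' Generate a simulated training set
#'
#' Each sample draws a coefficient direction uniformly on the mode sphere
#' and a total W_rms uniformly in `amplitude_range`, composes the
#' wavefront over the mirror-mode basis (adding the static baseline if
#' configured), renders the biplane emission pattern of an emitter with
#' random axial position, sub-pixel lateral offset, photon count and
#' background, and applies Poisson noise followed by exact background
#' subtraction. The label is the coefficient vector (baseline excluded),
#' scaled so its composed wavefront has exactly the drawn W_rms.
#'
#' @param basis mode basis ([build_zernike_basis()] or
#'   [build_mirror_basis()]).
#' @param tconfig [training_config()] object.
#' @param optics [optical_config()] object.
#' @param pupil instrument pupil; default flat.
#' @return list with `X` (packed, normalized inputs, one column per
#'   sample), `Y` (labels, one column per sample) and the generating
#'   configuration.
#' @export
generate_training_set <- function(basis, tconfig, optics, pupil = NULL) {
  if (is.null(pupil)) pupil <- pupil_function(optics)
  n <- tconfig$n_samples
  k <- basis$n_modes
  s <- optics$psf_size
  with_preserved_seed(tconfig$seed, {
    X <- matrix(0, 2 * s * s, n)
    Y <- matrix(0, k, n)
    for (i in seq_len(n)) {
      amp <- stats::runif(1, tconfig$amplitude_range[1],
                          tconfig$amplitude_range[2])
      co <- if (amp > 0) {
        dir <- stats::rnorm(k)
        scale_to_wrms(dir, amp, basis)
      } else rep(0, k)
      phase <- compose_wavefront(co, basis)
      if (!is.null(tconfig$baseline_wavefront))
        phase <- phase + tconfig$baseline_wavefront
      bgv <- stats::runif(1, tconfig$background_range[1],
                          tconfig$background_range[2])
      em <- emitter_state(
        x = stats::runif(1, tconfig$xy_range[1], tconfig$xy_range[2]) *
          optics$pixel_size,
        y = stats::runif(1, tconfig$xy_range[1], tconfig$xy_range[2]) *
          optics$pixel_size,
        z = stats::runif(1, tconfig$z_range[1], tconfig$z_range[2]),
        photons = stats::runif(1, tconfig$photon_range[1],
                               tconfig$photon_range[2]))
      if (isTRUE(tconfig$recenter)) {
        # render the full grid, noise it, then crop around the smoothed
        # peak exactly as segment_subregions() centers its crops
        full <- render_psf(pupil, phase, em, optics, crop = FALSE)
        n_cont <- if (tconfig$contaminant_rate > 0)
          stats::rpois(1, tconfig$contaminant_rate) else 0L
        if (n_cont > 0) {
          half <- optics$pupil_grid / 2 - 2
          for (ci in seq_len(n_cont)) {
            cph <- stats::rexp(1, 1 / tconfig$contaminant_photons)
            repeat {
              cx <- stats::runif(1, -half, half)
              cy <- stats::runif(1, -half, half)
              if (cph < tconfig$contaminant_bright ||
                  sqrt(cx^2 + cy^2) >= tconfig$contaminant_exclusion)
                break
            }
            cem <- emitter_state(x = cx * optics$pixel_size,
                                 y = cy * optics$pixel_size,
                                 z = stats::runif(1, tconfig$z_range[1],
                                                  tconfig$z_range[2]),
                                 photons = cph)
            cimg <- render_psf(pupil, phase, cem, optics, crop = FALSE)
            full <- Map(`+`, full, cimg)
          }
        }
        noisy <- lapply(full, function(im)
          matrix(stats::rpois(length(im), im + bgv), nrow(im)) - bgv)
        sm <- blur2d(noisy[[1]] + noisy[[2]], tconfig$recenter_sigma)
        n_full <- nrow(sm)
        h <- s / 2
        # search near the main emitter (the detection this crop mimics)
        lo <- max(h + 1, n_full / 2 - 8); hi <- min(n_full - h,
                                                    n_full / 2 + 8)
        win <- sm[lo:hi, lo:hi]
        pk <- arrayInd(which.max(win), dim(win)) + lo - 1
        rr <- (pk[1] - h):(pk[1] + h - 1)
        cc <- (pk[2] - h):(pk[2] + h - 1)
        crop <- lapply(noisy, function(im) im[rr, cc])
      } else {
        crop <- render_psf(pupil, phase, em, optics)
        crop <- lapply(crop, function(im)
          matrix(stats::rpois(length(im), im + bgv), nrow(im)) - bgv)
      }
      X[, i] <- pack_crops(list(crop))
      Y[, i] <- co
    }
    list(X = X, Y = Y, basis_n_modes = k, config = tconfig)
  })
}

#' Three-range network ensemble
#'
#' Bundles coefficient-regression networks trained on nested amplitude
#' ranges. Inference uncertainty grows with the training range, so the
#' closed loop switches to the smallest-range member consistent with the
#' current estimate.
#'
#' @param networks list of trained [build_network()] objects, ordered from
#'   smallest to largest training range.
#' @param ranges list of `c(lo, hi)` W_rms intervals (radians), strictly
#'   increasing in `hi`.
#' @return object of class `dlao_ensemble`.
#' @export
network_ensemble <- function(networks, ranges) {
  stopifnot(length(networks) == length(ranges), length(networks) >= 1)
  hi <- vapply(ranges, `[`, 0, 2)
  if (is.unsorted(hi, strictly = TRUE))
    stop("ensemble ranges must be strictly increasing")
  nm <- unique(vapply(networks, function(n) as.numeric(n$n_modes), 0))
  if (length(nm) != 1) stop("ensemble networks disagree on n_modes")
  structure(list(networks = networks, ranges = ranges, n_modes = nm),
            class = "dlao_ensemble")
}

#' @export
print.dlao_ensemble <- function(x, ...) {
  cat(sprintf("Network ensemble: %d members, %d modes\n",
              length(x$networks), x$n_modes))
  for (i in seq_along(x$networks))
    cat(sprintf("  [%d] range %.2f-%.2f rad\n", i, x$ranges[[i]][1],
                x$ranges[[i]][2]))
  invisible(x)
}

#' Estimate the shared wavefront from segmented subregions
#'
#' Runs the selected ensemble member on every subregion and aggregates the
#' per-subregion coefficient outputs into a per-mode mean and standard
#' error. At least two subregions are required; with fewer the update must
#' be skipped.
#'
#' @param subregions list from [segment_subregions()] (or a list of raw
#'   biplane crop pairs).
#' @param ensemble [network_ensemble()] object (or a single `dlao_net`).
#' @param network_id which ensemble member to use (default the largest
#'   range).
#' @return list of class `dlao_estimate`: `mean`, `stderr` (per mode),
#'   `n_subregions`, `network_id`, `per_subregion` matrix.
#' @export
estimate_wavefront <- function(subregions, ensemble, network_id = NULL) {
  if (length(subregions) < 2)
    stop(structure(class = c("dlao_insufficient_detections", "error",
                             "condition"),
                   list(message = "insufficient detections: at least two subregions are required",
                        call = sys.call())))
  if (inherits(ensemble, "dlao_net")) {
    net <- ensemble
    network_id <- 1L
  } else {
    if (is.null(network_id)) network_id <- length(ensemble$networks)
    net <- ensemble$networks[[network_id]]
  }
  crops <- lapply(subregions, function(s)
    if (!is.null(s$images)) s$images else s)
  est <- predict(net, crops)
  m <- colMeans(est)
  se <- apply(est, 2, stats::sd) / sqrt(nrow(est))
  structure(list(mean = m, stderr = se, n_subregions = nrow(est),
                 network_id = network_id, per_subregion = est),
            class = "dlao_estimate")
}

#' Network response to individual mirror-mode changes
#'
#' Applies `+amplitude` and `-amplitude` of each basis mode in turn,
#' renders clean high-signal subregions, and reports the estimator's
#' response matrix with columns `(est_+ - est_-) / (2 * amplitude)`. A
#' perfectly one-to-one estimator yields the identity.
#'
#' @param estimator a trained `dlao_net`, a [network_ensemble()] (its
#'   largest-range member whose range covers `amplitude` is used), or a
#'   function `(crops) -> matrix` for oracle checks.
#' @param basis mode basis the responses are probed in.
#' @param optics [optical_config()] object.
#' @param amplitude probe amplitude (radians).
#' @param n_crops emission patterns per probe.
#' @param photons,background emitter signal level for the probes.
#' @param seed RNG seed for probe emitters and noise.
#' @return list with `response` (n_modes x n_modes matrix),
#'   `diagonal_dominant` (per column: diagonal entry exceeds every
#'   off-diagonal magnitude in that column).
#' @export
characterize_response <- function(estimator, basis, optics, amplitude = 0.5,
                                  n_crops = 25, photons = 5000,
                                  background = 10, seed = 1) {
  k <- basis$n_modes
  probe <- function(co, sd_seed) {
    phase <- compose_wavefront(co, basis)
    with_preserved_seed(sd_seed, {
      crops <- lapply(seq_len(n_crops), function(i) {
        em <- emitter_state(
          x = stats::runif(1, -0.5, 0.5) * optics$pixel_size,
          y = stats::runif(1, -0.5, 0.5) * optics$pixel_size,
          z = stats::runif(1, -400, 400), photons = photons)
        crop <- render_psf(pupil_function(optics), phase, em, optics)
        lapply(crop, function(im)
          matrix(stats::rpois(length(im), im + background), nrow(im)) -
            background)
      })
      if (is.function(estimator)) {
        # function estimators receive the probe truth as an attribute,
        # enabling perfect-oracle controller checks
        attr(crops, "truth") <- co
        colMeans(estimator(crops))
      } else colMeans(predict(pick_net(estimator, amplitude), crops))
    })
  }
  resp <- matrix(0, k, k)
  for (m in seq_len(k)) {
    co <- rep(0, k)
    co[m] <- amplitude
    ep <- probe(co, derive_seed(seed, m, 1))
    co[m] <- -amplitude
    en <- probe(co, derive_seed(seed, m, 2))
    resp[, m] <- (ep - en) / (2 * amplitude)
  }
  dd <- vapply(seq_len(k), function(m) {
    resp[m, m] > max(abs(resp[-m, m]))
  }, TRUE)
  list(response = resp, diagonal_dominant = dd)
}

pick_net <- function(estimator, amplitude) {
  if (inherits(estimator, "dlao_net")) return(estimator)
  hi <- vapply(estimator$ranges, `[`, 0, 2)
  id <- which(hi >= amplitude)[1]
  if (is.na(id)) id <- length(estimator$networks)
  estimator$networks[[id]]
}
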