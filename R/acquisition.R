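#' Acquisition / blinking-simulation configuration
#'
#' Parameters of the synthetic single-molecule acquisition. The defaults
#' reproduce the simulated characterization protocol: 128 x 128 pixel
#' frames at 119 nm pixel pitch, on average 13 emitters per frame drawn
#' from a Poisson distribution with axial positions uniform between -1 and
#' 1 um, per-emitter photon counts exponential with mean 2,500, 10
#' background photons per pixel, and an intensity threshold of 1,500
#' photons on segmented subregions.
#'
#' @param frame_size frame side (pixels).
#' @param mean_emitters expected emitters per frame (Poisson mean).
#' @param z_range axial sampling interval (nm, uniform).
#' @param mean_photons exponential mean of per-emitter photons.
#' @param background expected background photons per pixel per plane.
#' @param frames_per_cycle frames acquired between mirror updates (the
#'   physical system uses 20-100; default 20).
#' @param photon_threshold minimum background-subtracted photons summed
#'   over both plane crops for a subregion to be kept.
#' @param subregion_size crop side (pixels, even).
#' @param isolation_radius minimum center-to-center distance (pixels)
#'   between detections; closer pairs are both discarded.
#' @param detection_sigma Gaussian smoothing width (pixels) of the peak
#'   detector.
#' @param detection_threshold minimum smoothed peak height (photons/pixel,
#'   after background subtraction) for a local maximum to count.
#' @return object of class `dlao_acquisition`.
#' @export
acquisition_config <- function(frame_size = 128, mean_emitters = 13,
                               z_range = c(-1000, 1000),
                               mean_photons = 2500, background = 10,
                               frames_per_cycle = 20,
                               photon_threshold = 1500,
                               subregion_size = 32, isolation_radius = 16,
                               detection_sigma = 2,
                               detection_threshold = 5) {
  stopifnot(frame_size > 0, mean_emitters > 0, mean_photons > 0,
            background >= 0, frames_per_cycle > 0, photon_threshold > 0,
            subregion_size > 0, isolation_radius > 0)
  if (subregion_size %% 2 != 0) stop("subregion_size must be even")
  if (isolation_radius < subregion_size / 2)
    stop("isolation_radius must be at least subregion_size / 2")
  structure(list(frame_size = frame_size, mean_emitters = mean_emitters,
                 z_range = z_range, mean_photons = mean_photons,
                 background = background,
                 frames_per_cycle = frames_per_cycle,
                 photon_threshold = photon_threshold,
                 subregion_size = subregion_size,
                 isolation_radius = isolation_radius,
                 detection_sigma = detection_sigma,
                 detection_threshold = detection_threshold),
            class = "dlao_acquisition")
}

#' Draw a random emitter population for one frame
#'
#' Count ~ Poisson(`mean_emitters`); lateral positions uniform over the
#' frame; axial positions uniform over `z_range`; photons exponential with
#' mean `mean_photons`. Uses the session RNG: seed with [set.seed()] for
#' reproducibility.
#'
#' @param config [acquisition_config()] object.
#' @return data.frame with columns `x`, `y` (continuous pixel coordinates),
#'   `z` (nm), `photons`.
#' @export
sample_emitters <- function(config) {
  n <- stats::rpois(1, config$mean_emitters)
  data.frame(
    x = stats::runif(n, 0.5, config$frame_size + 0.5),
    y = stats::runif(n, 0.5, config$frame_size + 0.5),
    z = stats::runif(n, config$z_range[1], config$z_range[2]),
    photons = stats::rexp(n, 1 / config$mean_photons))
}

# add a rendered biplane crop into a pair of frame matrices, clipping at
# the frame border; cx, cy integer center pixel of the crop's PSF origin
add_crop <- function(planes, crop, cx, cy, frame_size, crop_size) {
  h <- crop_size / 2
  r0 <- cy - h; c0 <- cx - h  # crop pixel (h+1, h+1) lands on (cy, cx)
  rr <- max(1, r0 + 1):min(frame_size, r0 + crop_size)
  cc <- max(1, c0 + 1):min(frame_size, c0 + crop_size)
  if (length(rr) == 0 || length(cc) == 0) return(planes)
  for (p in 1:2)
    planes[[p]][rr, cc] <- planes[[p]][rr, cc] +
      crop[[p]][rr - r0, cc - c0]
  planes
}

#' Simulate single-molecule blinking frames
#'
#' Each frame is an independent Poisson realization of the summed biplane
#' emission patterns of a random emitter population under a shared
#' wavefront distortion, plus uniform background. The generating emitters
#' are recorded as ground truth.
#'
#' @param true_wavefront pupil-phase matrix (radians) shared by all
#'   emitters, or `NULL` for an unaberrated system.
#' @param n_frames number of frames.
#' @param config [acquisition_config()] object.
#' @param optics [optical_config()] object.
#' @param pupil instrument [pupil_function()]; default flat.
#' @param stage_z stage defocus offset (nm) added to every emitter's
#'   axial position (used by focal-shift compensation).
#' @param noise if `FALSE`, return expected-value frames (no Poisson
#'   draw).
#' @return list of frames; each frame is a list with `pixels` (list of two
#'   matrices) and `truth` (emitter data.frame).
#' @export
simulate_frames <- function(true_wavefront, n_frames, config, optics,
                            pupil = NULL, stage_z = 0, noise = TRUE) {
  if (is.null(pupil)) pupil <- pupil_function(optics)
  fs <- config$frame_size
  s <- optics$psf_size
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    em <- sample_emitters(config)
    planes <- list(matrix(0, fs, fs), matrix(0, fs, fs))
    if (nrow(em) > 0) for (i in seq_len(nrow(em))) {
      cx <- round(em$x[i]); cy <- round(em$y[i])
      crop <- render_psf(pupil, true_wavefront,
                         emitter_state(x = (em$x[i] - cx) * optics$pixel_size,
                                       y = (em$y[i] - cy) * optics$pixel_size,
                                       z = em$z[i] + stage_z,
                                       photons = em$photons[i]),
                         optics)
      planes <- add_crop(planes, crop, cx, cy, fs, s)
    }
    for (p in 1:2) {
      mu <- planes[[p]] + config$background
      planes[[p]] <- if (noise)
        matrix(stats::rpois(fs * fs, mu), fs, fs) else mu
    }
    frames[[f]] <- list(pixels = planes, truth = em)
  }
  frames
}

#' Temporal-median background estimate
#'
#' Per-pixel median over a temporal window of frames, per detection plane.
#' With sparse transient emitters the median is a robust estimate of the
#' (possibly structured) background.
#'
#' @param frames list of frames from [simulate_frames()].
#' @param window odd window length; at most `length(frames)` frames (the
#'   most recent `window`) are used.
#' @return list of two background matrices.
#' @export
temporal_median_background <- function(frames, window = length(frames)) {
  if (window %% 2 == 0) stop("median window must be odd")
  if (window > length(frames))
    stop("window exceeds the number of available frames")
  take <- frames[seq(length(frames) - window + 1, length(frames))]
  lapply(1:2, function(p) {
    st <- vapply(take, function(f) f$pixels[[p]], take[[1]]$pixels[[p]])
    .temporal_median(st)
  })
}

#' Segment single-molecule subregions from a frame
#'
#' Detection runs on the background-subtracted sum of both planes after
#' Gaussian smoothing: local maxima above `detection_threshold` become
#' candidate centers; candidates closer than `isolation_radius` to another
#' candidate are discarded (both of them), as are candidates whose crop
#' would cross the frame border and crops whose summed background-
#' subtracted photons fall below `photon_threshold`.
#'
#' @param frame one frame from [simulate_frames()].
#' @param background list of two background matrices (e.g. from
#'   [temporal_median_background()]), or a scalar.
#' @param config [acquisition_config()] object.
#' @return list of subregions: each has `images` (list of two
#'   background-subtracted crops), `center` (c(x, y) integer pixels) and
#'   `total_photons`. May be empty.
#' @export
segment_subregions <- function(frame, background, config) {
  if (is.numeric(background) && length(background) == 1)
    background <- list(matrix(background, nrow(frame$pixels[[1]]),
                              ncol(frame$pixels[[1]])),
                       matrix(background, nrow(frame$pixels[[2]]),
                              ncol(frame$pixels[[2]])))
  sub1 <- frame$pixels[[1]] - background[[1]]
  sub2 <- frame$pixels[[2]] - background[[2]]
  combined <- sub1 + sub2
  sm <- blur2d(combined, config$detection_sigma)
  fs <- nrow(sm)
  # strict local maxima over the 8-neighborhood
  pad <- matrix(-Inf, fs + 2, fs + 2)
  pad[2:(fs + 1), 2:(fs + 1)] <- sm
  ismax <- sm >= config$detection_threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ismax <- ismax & (sm > pad[(2 + di):(fs + 1 + di),
                               (2 + dj):(fs + 1 + dj)])
  }
  peaks <- which(ismax, arr.ind = TRUE)  # row = y, col = x
  if (nrow(peaks) == 0) return(list())
  # isolation rule: drop every member of a close pair
  keep <- rep(TRUE, nrow(peaks))
  if (nrow(peaks) > 1) {
    d <- as.matrix(stats::dist(peaks))
    diag(d) <- Inf
    keep <- apply(d, 1, min) >= config$isolation_radius
  }
  peaks <- peaks[keep, , drop = FALSE]
  s <- config$subregion_size
  h <- s / 2
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    cy <- peaks[i, 1]; cx <- peaks[i, 2]
    # the peak lands on crop pixel (h + 1, h + 1), matching where
    # render_psf puts a centered emitter
    r0 <- cy - h - 1; c0 <- cx - h - 1
    if (r0 < 0 || c0 < 0 || r0 + s > fs || c0 + s > fs) next
    rr <- (r0 + 1):(r0 + s); cc <- (c0 + 1):(c0 + s)
    im1 <- sub1[rr, cc]; im2 <- sub2[rr, cc]
    tot <- sum(im1) + sum(im2)
    if (tot < config$photon_threshold) next
    out[[length(out) + 1]] <- list(images = list(im1, im2),
                                   center = c(x = cx, y = cy),
                                   total_photons = tot)
  }
  out
}
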