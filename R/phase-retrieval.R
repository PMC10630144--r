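#' Gerchberg-Saxton phase retrieval from a bead z-stack
#'
#' Alternating-projection retrieval of the pupil phase from through-focus
#' intensity images of a centered bead. In image space the field magnitude
#' is replaced by the measured square-root intensity at each z (defocus
#' applied and removed via the angular-spectrum term); in pupil space the
#' support constraint is enforced and the magnitude reset to the flat
#' circular pupil (known apodization), keeping only the phase. The
#' recovered piston is indeterminate and set to zero mean over the
#' support.
#'
#' @param stack [render_bead_stack()] object (intensities may be noisy;
#'   at least 3 slices with known z positions).
#' @param optics [optical_config()] object.
#' @param n_iter number of iterations (default 100).
#' @param tol early-exit tolerance on the per-iteration change of the
#'   error metric.
#' @param restarts additional attempts from seeded random low-order
#'   initial phases if an attempt stagnates away from a good fit;
#'   alternating projections can stall in local minima for mixed
#'   aberrations. The best attempt (smallest intensity residual) is
#'   returned.
#' @param restart_tol intensity-residual threshold below which an
#'   attempt counts as converged and no restart is tried.
#' @return object of class `dlao_pupil` with attributes
#'   `convergence` (per-iteration relative residual between modeled and
#'   measured intensities) and `iterations`.
#' @export
# flood-fill 2-pi unwrapping over the pupil support (4-connectivity,
# growing outward from the center pixel); retrieved phases are wrapped to
# (-pi, pi] by construction while physical aberrations can exceed that
unwrap_pupil_phase <- function(phase, support) {
  n <- nrow(phase)
  un <- matrix(NA_real_, n, n)
  idx <- which(support, arr.ind = TRUE)
  start <- idx[which.min((idx[, 1] - n / 2 - 1)^2 +
                           (idx[, 2] - n / 2 - 1)^2), ]
  un[start[1], start[2]] <- phase[start[1], start[2]]
  frontier <- matrix(start, 1)
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  while (nrow(frontier) > 0) {
    nxt <- NULL
    for (f in seq_len(nrow(frontier))) {
      p <- frontier[f, ]
      ref <- un[p[1], p[2]]
      for (o in 1:4) {
        q <- p + offs[o, ]
        if (q[1] < 1 || q[1] > n || q[2] < 1 || q[2] > n) next
        if (!support[q[1], q[2]] || !is.na(un[q[1], q[2]])) next
        raw <- phase[q[1], q[2]]
        un[q[1], q[2]] <- raw + 2 * pi * round((ref - raw) / (2 * pi))
        nxt <- rbind(nxt, q)
      }
    }
    frontier <- if (is.null(nxt)) matrix(0, 0, 2) else nxt
  }
  un[is.na(un)] <- 0
  un
}

phase_retrieve <- function(stack, optics, n_iter = 100, tol = 1e-9,
                           restarts = 3, restart_tol = 1e-8) {
  zs <- stack$z_positions
  if (length(zs) < 3) stop("phase retrieval needs at least 3 z-slices")
  n <- optics$pupil_grid
  s <- dim(stack$images)[2]
  sup <- optics$support
  mag0 <- matrix(as.numeric(sup), n, n)
  i0 <- n / 2 - s / 2 + 1
  idx <- i0:(i0 + s - 1)
  # normalized measured amplitudes embedded in the full grid
  amps <- lapply(seq_along(zs), function(i) {
    im <- pmax(stack$images[i, , ], 0)
    im <- im / sum(im)
    full <- matrix(0, n, n)
    full[idx, idx] <- sqrt(im)
    full
  })
  defoc <- lapply(zs, function(z) exp(1i * defocus_phase(z, optics)))
  sh <- c((n / 2 + 1):n, 1:(n / 2))
  fw <- function(x) { y <- stats::fft(x[sh, sh]); y[sh, sh] }
  bw <- function(x) { y <- stats::fft(x[sh, sh], inverse = TRUE); y[sh, sh] }

  run_gs <- function(init_phase) {
    pupil <- mag0 * exp(1i * init_phase)
    err <- numeric(0)
    best <- list(phase = init_phase, err = Inf)
    phase <- init_phase
    for (it in seq_len(n_iter)) {
      acc <- matrix(0 + 0i, n, n)
      e <- 0
      for (i in seq_along(zs)) {
        field <- fw(pupil * defoc[[i]])
        inten <- Mod(field)^2
        inten <- inten / sum(inten)
        e <- e + sum((inten[idx, idx] - amps[[i]][idx, idx]^2)^2)
        ph <- field / pmax(Mod(field), 1e-30)
        acc <- acc + bw(amps[[i]] * ph) * Conj(defoc[[i]])
      }
      phase <- Arg(acc)
      phase[!sup] <- 0
      phase[sup] <- phase[sup] - mean(phase[sup])
      pupil <- mag0 * exp(1i * phase)
      err <- c(err, e)
      if (e < best$err) best <- list(phase = phase, err = e)
      if (it > 1 && abs(err[it - 1] - err[it]) < tol * max(err[1], 1e-30))
        break
    }
    list(phase = phase, err = err, best = best)
  }

  att <- run_gs(matrix(0, n, n))
  attempt <- 1
  # alternating projections can stall in a local minimum for mixed
  # aberrations; retry from seeded random low-order phases and keep the
  # best intensity fit
  while (att$best$err > restart_tol && attempt <= restarts) {
    rnd <- with_preserved_seed(derive_seed(1300, attempt), {
      rho <- sqrt(optics$kr2) / (optics$na / optics$wavelength)
      theta <- atan2(optics$ky, optics$kx)
      stats::rnorm(1, 0, 0.6) * (2 * rho^2 - 1) +
        stats::rnorm(1, 0, 0.6) * rho^2 * cos(2 * theta) +
        stats::rnorm(1, 0, 0.6) * rho^2 * sin(2 * theta) +
        stats::rnorm(1, 0, 0.4) * (6 * rho^4 - 6 * rho^2 + 1)
    })
    rnd[!sup] <- 0
    cand <- run_gs(rnd)
    if (cand$best$err < att$best$err) att <- cand
    attempt <- attempt + 1
  }
  err <- att$err
  phase <- att$phase
  final_e <- err[length(err)]
  if (final_e > 1e-16 && final_e > att$best$err * (1 + 1e-6) &&
      final_e - att$best$err > 1e-12 * max(err[1], 1e-30)) {
    warning("phase retrieval did not converge monotonically; ",
            "returning the best iterate")
    phase <- att$best$phase
  }
  phase <- unwrap_pupil_phase(phase, sup)
  phase[sup] <- phase[sup] - mean(phase[sup])
  out <- pupil_function(optics, magnitude = mag0, phase = phase)
  attr(out, "convergence") <- err
  attr(out, "iterations") <- length(err)
  out
}

#' Measure mirror deformation modes by differential phase retrieval
#'
#' For each mode of the simulated mirror, bead stacks are rendered at
#' positive and negative unit commanded amplitude, the pupil phase is
#' retrieved from each, and the mode is taken as half the difference of
#' the two retrieved phases — cancelling any static baseline aberration
#' common to both acquisitions.
#'
#' @param mirror [mirror_model()] object (its basis and coupling define
#'   what a unit commanded amplitude realizes).
#' @param optics [optical_config()] object.
#' @param baseline static pupil-phase matrix present in both
#'   acquisitions, or `NULL`.
#' @param n_iter phase-retrieval iterations per stack.
#' @param z_range,z_step bead-scan protocol (defaults: -1.5 to 1.5 um in
#'   100 nm steps, 31 slices).
#' @return `dlao_basis` whose modes are the recovered pupil images (not
#'   re-normalized: a faithful mirror yields unit-W_rms modes).
#' @export
measure_mirror_modes <- function(mirror, optics, baseline = NULL,
                                 n_iter = 100, z_range = c(-1500, 1500),
                                 z_step = 100) {
  basis <- mirror$basis
  k <- basis$n_modes
  pup <- pupil_function(optics)
  sup <- optics$support
  M <- matrix(0, sum(sup), k)
  for (m in seq_len(k)) {
    rec <- list()
    for (sgn in c(1, -1)) {
      mir <- mirror
      mir$commanded <- rep(0, k)
      mir <- apply_mirror_update(mir, sgn * replace(rep(0, k), m, 1))
      ab <- mirror_realized(mir)$phase
      if (!is.null(baseline)) ab <- ab + baseline
      stack <- render_bead_stack(pup, ab, optics, z_range = z_range,
                                 z_step = z_step)
      ret <- phase_retrieve(stack, optics, n_iter = n_iter)
      rec[[if (sgn > 0) "pos" else "neg"]] <- ret$phase
    }
    diff <- (rec$pos - rec$neg) / 2
    M[, m] <- diff[sup]
  }
  new_basis(M, optics, wyant = basis$wyant, names = basis$mode_names,
            coupling = NULL)
}
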