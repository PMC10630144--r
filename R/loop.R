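#' Closed-loop configuration
#'
#' @param max_updates cap on mirror updates per run (the physical system
#'   typically needs 3-20).
#' @param gain fraction of the posterior residual applied per update
#'   (in `(0, 1]`; 1 applies the proposed update directly).
#' @param stop_threshold posterior residual magnitude (radians) below
#'   which the loop may stop.
#' @param stop_consecutive number of consecutive cycles below the
#'   threshold required to stop.
#' @param process_noise,stderr_floor Kalman filter parameters (see
#'   [kalman_state()]).
#' @param focal_shift_constants named vector for
#'   [compensate_focal_shift()]; `NULL` disables stage compensation.
#' @param background how the acquisition-side background is estimated
#'   each cycle: `"median"` (temporal median over the cycle's frames) or
#'   `"known"` (the configured constant).
#' @return object of class `dlao_loop_config`.
#' @export
loop_config <- function(max_updates = 20, gain = 1, stop_threshold = 0.1,
                        stop_consecutive = 2, process_noise = 0.05^2,
                        stderr_floor = 0.02,
                        focal_shift_constants = NULL,
                        background = c("median", "known")) {
  stopifnot(max_updates >= 1, gain > 0, gain <= 1)
  background <- match.arg(background)
  structure(list(max_updates = max_updates, gain = gain,
                 stop_threshold = stop_threshold,
                 stop_consecutive = stop_consecutive,
                 process_noise = process_noise,
                 stderr_floor = stderr_floor,
                 focal_shift_constants = focal_shift_constants,
                 background = background),
            class = "dlao_loop_config")
}

#' Select the ensemble member for the next cycle
#'
#' Transitions are driven by the inference uncertainty: the loop moves to
#' the smallest-range network whose range contains the current estimate
#' magnitude plus twice its uncertainty, and moves up when the current
#' range is exceeded. At an exact range boundary the lower-range network
#' wins.
#'
#' @param estimate a `dlao_estimate`, or any list with `mean` and either
#'   `stderr` or `variance`.
#' @param ensemble [network_ensemble()] object.
#' @return integer network id.
#' @export
select_network <- function(estimate, ensemble) {
  mag <- sqrt(sum(estimate$mean^2))
  unc <- if (!is.null(estimate$stderr)) sqrt(sum(estimate$stderr^2))
  else if (!is.null(estimate$variance)) sqrt(sum(estimate$variance))
  else 0
  need <- mag + 2 * unc
  hi <- vapply(ensemble$ranges, `[`, 0, 2)
  id <- which(need <= hi)[1]
  if (is.na(id)) id <- length(ensemble$networks)
  as.integer(id)
}

#' Oracle wavefront estimator
#'
#' A stand-in estimator that reads the true residual wavefront from the
#' simulation and decomposes it onto the basis — used to isolate
#' controller behaviour from network error.
#'
#' @param basis mode basis.
#' @param stderr reported per-mode standard error.
#' @export
oracle_estimator <- function(basis, stderr = 1e-3) {
  structure(list(basis = basis, stderr = stderr,
                 ranges = list(c(0, Inf)), n_modes = basis$n_modes),
            class = c("dlao_oracle", "dlao_ensemble"))
}

#' Run the closed compensation loop
#'
#' Each cycle: blinking frames are simulated under the current residual
#' wavefront (true distortion plus realized mirror shape), the background
#' is estimated and subtracted, single-molecule subregions are segmented,
#' the selected network estimates the residual mode amplitudes, the
#' per-mode Kalman filter fuses the measurement with the propagated
#' posterior, and the negated posterior (scaled by the loop gain) is
#' applied to the mirror, optionally with focal-shift stage compensation.
#' Cycles with fewer than two usable subregions skip the update. The loop
#' stops early once the posterior magnitude stays below `stop_threshold`
#' for `stop_consecutive` cycles.
#'
#' @param true_coeffs coefficient vector of the induced distortion on the
#'   mirror basis.
#' @param ensemble [network_ensemble()] (or [oracle_estimator()]).
#' @param mirror [mirror_model()] object (starting state).
#' @param optics,acq optics and acquisition configurations.
#' @param config [loop_config()] object.
#' @param seed integer seed; the entire loop is deterministic given it.
#' @param injections optional dynamic-distortion schedule: list with
#'   `cycles` (integer vector) and `level` (W_rms, radians); at each
#'   scheduled cycle a random distortion of exactly that level is added
#'   to the truth before the cycle runs.
#' @return object of class `dlao_trace`: data.frame with one row per
#'   cycle (update 0 = pre-loop state) and columns `update`,
#'   `residual_wrms` (true residual after that many updates),
#'   `n_subregions`, `network_id`, `est_mag`, `post_mag`, `skipped`,
#'   `injected`, `stage_um`; the commanded and estimated coefficient
#'   histories are attached as attributes.
#' @export
run_closed_loop <- function(true_coeffs, ensemble, mirror, optics, acq,
                            config = loop_config(), seed = 1,
                            injections = NULL) {
  basis <- mirror$basis
  k <- basis$n_modes
  stopifnot(length(true_coeffs) == k)
  oracle <- inherits(ensemble, "dlao_oracle")
  with_preserved_seed(seed, {
    truth <- true_coeffs
    kal <- kalman_state(k, process_noise = config$process_noise,
                        stderr_floor = config$stderr_floor)
    net_id <- if (oracle) 1L else length(ensemble$networks)
    last_delta <- NULL
    stage_um <- 0
    below <- 0L
    real <- mirror_realized(mirror)
    residual_phase <- compose_wavefront(truth, basis) + real$phase
    rows <- list(data.frame(update = 0,
                            residual_wrms = wrms(residual_phase, optics),
                            n_subregions = NA, network_id = NA,
                            est_mag = NA, post_mag = NA, skipped = FALSE,
                            injected = FALSE, stage_um = 0))
    cmd_hist <- list(mirror$commanded)
    est_hist <- list(rep(NA_real_, k))
    for (t in seq_len(config$max_updates)) {
      injected <- FALSE
      if (!is.null(injections) && injections$level > 0 &&
          t %in% injections$cycles) {
        dir <- stats::rnorm(k)
        truth <- truth + scale_to_wrms(dir, injections$level, basis)
        injected <- TRUE
        real <- mirror_realized(mirror)
        residual_phase <- compose_wavefront(truth, basis) + real$phase
      }
      if (oracle) {
        est <- list(mean = decompose_wavefront(residual_phase,
                                               basis)$coefficients,
                    stderr = rep(ensemble$stderr, k))
        n_subs <- Inf
      } else {
        frames <- simulate_frames(residual_phase, acq$frames_per_cycle,
                                  acq, optics, stage_z = -1000 * stage_um)
        bg <- if (config$background == "median") {
          w <- acq$frames_per_cycle
          if (w %% 2 == 0) w <- w - 1
          temporal_median_background(frames, w)
        } else acq$background
        subs <- do.call(c, lapply(frames, segment_subregions,
                                  background = bg, config = acq))
        n_subs <- length(subs)
        if (n_subs < 2) {
          real <- mirror_realized(mirror)
          residual_phase <- compose_wavefront(truth, basis) + real$phase
          rows[[t + 1]] <- data.frame(
            update = t, residual_wrms = wrms(residual_phase, optics),
            n_subregions = n_subs, network_id = net_id, est_mag = NA,
            post_mag = NA, skipped = TRUE, injected = injected,
            stage_um = stage_um)
          cmd_hist[[t + 1]] <- mirror$commanded
          est_hist[[t + 1]] <- rep(NA_real_, k)
          next
        }
        est <- estimate_wavefront(subs, ensemble, net_id)
        # re-infer the same subregions with the range-matched network:
        # the first estimate of a cycle may come from a wider-range (less
        # precise) member than the measured magnitude warrants
        for (pass in 1:2) {
          sel <- select_network(est, ensemble)
          if (sel == est$network_id) break
          est <- estimate_wavefront(subs, ensemble, sel)
        }
        net_id <- est$network_id
      }
      kal <- kalman_update(kal, est, applied_delta = last_delta)
      delta <- -config$gain * kal$mean
      mirror <- apply_mirror_update(mirror, delta)
      if (!is.null(config$focal_shift_constants))
        stage_um <- stage_um +
          compensate_focal_shift(delta, config$focal_shift_constants)
      last_delta <- delta
      real <- mirror_realized(mirror)
      residual_phase <- compose_wavefront(truth, basis) + real$phase
      post_mag <- sqrt(sum(kal$mean^2))
      if (!oracle)
        net_id <- select_network(list(mean = kal$mean,
                                      variance = kal$variance), ensemble)
      rows[[t + 1]] <- data.frame(
        update = t, residual_wrms = wrms(residual_phase, optics),
        n_subregions = if (is.finite(n_subs)) n_subs else NA,
        network_id = net_id, est_mag = sqrt(sum(est$mean^2)),
        post_mag = post_mag, skipped = FALSE, injected = injected,
        stage_um = stage_um)
      cmd_hist[[t + 1]] <- mirror$commanded
      est_hist[[t + 1]] <- est$mean
      # stop on the measured residual magnitude at this cycle (the
      # posterior before the correction is applied)
      if (post_mag < config$stop_threshold) below <- below + 1L
      else below <- 0L
      if (below >= config$stop_consecutive) break
    }
    tr <- do.call(rbind, rows)
    attr(tr, "commanded") <- do.call(rbind, cmd_hist)
    attr(tr, "estimates") <- do.call(rbind, est_hist)
    attr(tr, "induced_wrms") <- rows[[1]]$residual_wrms
    attr(tr, "seed") <- seed
    class(tr) <- c("dlao_trace", "data.frame")
    tr
  })
}

#' @export
print.dlao_trace <- function(x, ...) {
  cat(sprintf("Closed-loop trace: induced %.3f rad, %d updates, final residual %.3f rad\n",
              attr(x, "induced_wrms"), max(x$update),
              x$residual_wrms[nrow(x)]))
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Run a closed loop with scheduled random distortion injections
#'
#' Emulates compensation of sudden wavefront changes during continuous
#' acquisition: at each scheduled cycle a random distortion of the target
#' level (default 0.75 rad W_rms) is added to the true wavefront and the
#' loop keeps running autonomously.
#'
#' @inheritParams run_closed_loop
#' @param schedule integer cycles at which distortions are injected.
#' @param level W_rms (radians) of each injected distortion.
#' @export
inject_dynamic_distortions <- function(true_coeffs, ensemble, mirror,
                                       optics, acq,
                                       config = loop_config(),
                                       schedule, level = 0.75, seed = 1) {
  run_closed_loop(true_coeffs, ensemble, mirror, optics, acq, config,
                  seed = seed,
                  injections = list(cycles = schedule, level = level))
}
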