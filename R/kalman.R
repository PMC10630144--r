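#' Per-mode Kalman filter state
#'
#' The closed loop tracks the residual wavefront distortion with one
#' independent scalar Kalman filter per mirror mode. The state mean is the
#' posterior residual amplitude (radians), the variance its posterior
#' uncertainty; a per-update process noise absorbs mirror nonlinearity and
#' slow drift.
#'
#' @param n_modes number of modes.
#' @param prior_mean,prior_var initial state; the default prior is
#'   effectively uninformative, so the first posterior equals the first
#'   measurement. `Inf` prior variances are supported (exactly
#'   uninformative).
#' @param process_noise variance added per predict step (default
#'   `(0.05 rad)^2`).
#' @param stderr_floor lower bound (rad) substituted for degenerate
#'   measurement standard errors.
#' @return object of class `dlao_kalman`.
#' @export
kalman_state <- function(n_modes, prior_mean = rep(0, n_modes),
                         prior_var = rep(1e6, n_modes),
                         process_noise = 0.05^2, stderr_floor = 0.02) {
  stopifnot(all(prior_var > 0), length(prior_mean) == n_modes,
            length(prior_var) == n_modes)
  structure(list(mean = prior_mean, variance = prior_var,
                 process_noise = process_noise,
                 stderr_floor = stderr_floor, n_modes = n_modes),
            class = "dlao_kalman")
}

#' Kalman predict-and-update step
#'
#' Predict: the posterior mean is shifted by the mirror delta applied
#' since the last measurement and the variance inflated by the process
#' noise. Update: the new wavefront measurement is fused per mode with
#' measurement variance `stderr^2` (floored at the configured minimum).
#' With zero process noise a sequence of measurements reduces to their
#' inverse-variance-weighted mean.
#'
#' @param state [kalman_state()] object.
#' @param measurement a `dlao_estimate` (from [estimate_wavefront()]) or a
#'   list with `mean` and `stderr` vectors.
#' @param applied_delta mirror coefficient change applied between the
#'   previous and this measurement (default none).
#' @param predict if `FALSE`, skip the predict step (used for the first
#'   measurement of a loop).
#' @return updated `dlao_kalman`.
#' @export
kalman_update <- function(state, measurement, applied_delta = NULL,
                          predict = TRUE) {
  y <- measurement$mean
  se <- measurement$stderr
  if (length(y) != state$n_modes || length(se) != state$n_modes)
    stop("measurement dimension does not match the Kalman state")
  if (any(!is.finite(se))) stop("measurement stderr must be finite")
  se <- pmax(se, state$stderr_floor)
  m <- state$mean
  v <- state$variance
  if (predict) {
    if (!is.null(applied_delta)) m <- m + applied_delta
    v <- v + state$process_noise
  }
  r <- se^2
  gain <- ifelse(is.infinite(v), 1, v / (v + r))
  state$mean <- m + gain * (y - m)
  state$variance <- ifelse(is.infinite(v), r, (1 - gain) * v)
  state
}
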