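#' 3D normalized cross-correlation between PSF stacks
#'
#' Pearson correlation over all voxels after mean removal; invariant to
#' affine intensity rescaling of either stack.
#'
#' @param stack_a,stack_b [render_bead_stack()] objects or plain arrays of
#'   identical shape.
#' @return scalar in `[-1, 1]`.
#' @export
ncc3d <- function(stack_a, stack_b) {
  a <- if (inherits(stack_a, "dlao_psf_stack")) stack_a$images else stack_a
  b <- if (inherits(stack_b, "dlao_psf_stack")) stack_b$images else stack_b
  if (!all(dim(a) == dim(b))) stop("stacks must have identical shapes")
  a <- as.vector(a) - mean(a)
  b <- as.vector(b) - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-variance stack")
  sum(a * b) / (na * nb)
}

#' Build a differentiable biplane PSF model for Fisher analysis
#'
#' @param pupil [pupil_function()] object.
#' @param aberration pupil-phase matrix or `NULL`.
#' @param optics [optical_config()] object.
#' @param photons expected total photons (both planes).
#' @return function `(x, y, z) -> list of plane images` of expected
#'   photons (no background).
#' @export
make_psf_model <- function(pupil, aberration = NULL, optics,
                           photons = 1000) {
  force(pupil); force(aberration); force(optics); force(photons)
  function(x, y, z)
    render_psf(pupil, aberration,
               emitter_state(x = x, y = y, z = z, photons = photons),
               optics)
}

#' Poisson Fisher information and CRLB for 3D localization
#'
#' For expected counts `mu = model + background` per pixel, the Fisher
#' matrix over theta = (x, y, z) is
#' `I[i,j] = sum_pixels d(mu)/d(theta_i) * d(mu)/d(theta_j) / mu`,
#' summed over both detection planes (information is additive over
#' independent pixels and planes). Derivatives are central differences;
#' pixels with `mu` below `mu_floor` are excluded. The CRLB precision is
#' `sqrt(diag(I^-1))`.
#'
#' @param psf_model function from [make_psf_model()] (or any
#'   `(x, y, z) -> list of images` of expected photons).
#' @param background expected background photons per pixel.
#' @param z_grid axial positions (nm) to evaluate.
#' @param x,y lateral evaluation point (nm).
#' @param step_xy,step_z central-difference steps (nm).
#' @param mu_floor exclusion threshold for near-empty pixels.
#' @return data.frame with columns `z`, `I_x`, `I_y`, `I_z` (information,
#'   nm^-2) and `crlb_x`, `crlb_y`, `crlb_z` (nm).
#' @export
fisher_information <- function(psf_model, background = 10,
                               z_grid = seq(-1500, 1500, 100), x = 0,
                               y = 0, step_xy = 5, step_z = 10,
                               mu_floor = 1e-6) {
  rows <- lapply(z_grid, function(z) {
    mu <- psf_model(x, y, z)
    d <- list(
      x = Map(function(p, m) (p - m) / (2 * step_xy),
              psf_model(x + step_xy, y, z), psf_model(x - step_xy, y, z)),
      y = Map(function(p, m) (p - m) / (2 * step_xy),
              psf_model(x, y + step_xy, z), psf_model(x, y - step_xy, z)),
      z = Map(function(p, m) (p - m) / (2 * step_z),
              psf_model(x, y, z + step_z), psf_model(x, y, z - step_z)))
    info <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"),
                                            c("x", "y", "z")))
    for (p in seq_along(mu)) {
      m <- mu[[p]] + background
      keep <- m > mu_floor
      for (i in 1:3) for (j in i:3) {
        v <- sum(d[[i]][[p]][keep] * d[[j]][[p]][keep] / m[keep])
        info[i, j] <- info[i, j] + v
        if (j > i) info[j, i] <- info[i, j]
      }
    }
    if (any(diag(info) <= 0) || rcond(info) < 1e-14) {
      bad <- c("x", "y", "z")[diag(info) <= min(diag(info)) + 1e-30][1]
      stop("singular Fisher information matrix (degenerate axis: ", bad,
           ")")
    }
    cr <- sqrt(diag(solve(info)))
    data.frame(z = z, I_x = info[1, 1], I_y = info[2, 2],
               I_z = info[3, 3], crlb_x = cr[1], crlb_y = cr[2],
               crlb_z = cr[3])
  })
  do.call(rbind, rows)
}

#' Convergence statistics over repeated compensation runs
#'
#' Aggregates closed-loop traces grouped by induced distortion level into
#' per-level mean and standard deviation of the true residual versus
#' update index (residuals are carried forward after an early stop), and
#' the mean fraction of the induced level removed by the first mirror
#' update. A pure function of its inputs.
#'
#' @param traces list of [run_closed_loop()] traces.
#' @param levels induced W_rms per trace (defaults to each trace's
#'   recorded induced level).
#' @param horizon update index up to which residuals are tabulated.
#' @return object of class `dlao_convergence`: list with `by_level`
#'   (data.frame: level, update, mean, sd, n), `one_update_fraction`
#'   (mean over traces), `per_trace` (data.frame with induced, first and
#'   final residuals).
#' @export
convergence_statistics <- function(traces, levels = NULL, horizon = 20) {
  if (is.null(levels))
    levels <- vapply(traces, function(tr) attr(tr, "induced_wrms"), 0)
  stopifnot(length(levels) == length(traces))
  res_at <- function(tr, u) {
    i <- findInterval(u, tr$update)
    tr$residual_wrms[max(i, 1)]
  }
  per_trace <- data.frame(
    level = levels,
    induced = vapply(traces, function(tr) tr$residual_wrms[1], 0),
    after1 = vapply(traces, res_at, 0, u = 1),
    final = vapply(traces, res_at, 0, u = horizon))
  per_trace$reduction1 <- 1 - per_trace$after1 / per_trace$induced
  grid <- expand.grid(level = sort(unique(levels)), update = 0:horizon)
  by_level <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- which(levels == grid$level[i])
    vals <- vapply(traces[sel], res_at, 0, u = grid$update[i])
    data.frame(level = grid$level[i], update = grid$update[i],
               mean = mean(vals),
               sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
               n = length(vals))
  }))
  structure(list(by_level = by_level,
                 one_update_fraction = mean(per_trace$reduction1),
                 per_trace = per_trace),
            class = "dlao_convergence")
}

#' @export
print.dlao_convergence <- function(x, ...) {
  cat(sprintf(
    "Convergence over %d runs: %.1f%% of the induced level removed by the first update\n",
    nrow(x$per_trace), 100 * x$one_update_fraction))
  fin <- stats::aggregate(final ~ level, x$per_trace, stats::median)
  cat("median final residual by level (rad):\n")
  print(fin, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Repeated compensation experiment over a grid of distortion levels
#'
#' For each level and repeat, draws a random coefficient direction scaled
#' to the level, runs the closed loop from a flat mirror, and aggregates
#' the traces with [convergence_statistics()]. This reproduces the
#' simulated characterization protocol (11 levels from 0.25 to 2.75 rad,
#' 15 repeats each, N = 165 runs).
#'
#' @param ensemble,optics,acq,config see [run_closed_loop()].
#' @param basis mode basis of the simulated mirror.
#' @param levels induced W_rms grid (radians).
#' @param repeats runs per level.
#' @param seed master seed; each run derives its own stream.
#' @param mirror_factory function `() -> dlao_mirror` giving the starting
#'   mirror for each run (default: ideal-coupling mirror on `basis` with
#'   the standard stroke nonlinearity).
#' @param progress print one character per run.
#' @return list with `traces`, `levels_per_trace` and `summary`
#'   (a `dlao_convergence`).
#' @export
run_convergence_experiment <- function(ensemble, basis, optics, acq,
                                       config = loop_config(),
                                       levels = seq(0.25, 2.75, 0.25),
                                       repeats = 15, seed = 1,
                                       mirror_factory = NULL,
                                       progress = FALSE) {
  if (is.null(mirror_factory))
    mirror_factory <- function() mirror_model(basis)
  traces <- list()
  lv <- numeric(0)
  for (li in seq_along(levels)) {
    for (r in seq_len(repeats)) {
      run_seed <- derive_seed(seed, li, r)
      co <- with_preserved_seed(derive_seed(run_seed, 7),
                                stats::rnorm(basis$n_modes))
      co <- scale_to_wrms(co, levels[li], basis)
      tr <- run_closed_loop(co, ensemble, mirror_factory(), optics, acq,
                            config, seed = run_seed)
      traces[[length(traces) + 1]] <- tr
      lv <- c(lv, levels[li])
      if (progress) cat(".")
    }
    if (progress) cat(" level", levels[li], "done\n")
  }
  list(traces = traces, levels_per_trace = lv,
       summary = convergence_statistics(traces, lv,
                                        horizon = config$max_updates))
}
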