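#' Desk-scale preset: optics, basis and acquisition
#'
#' A self-contained configuration small enough to train and run a full
#' closed-loop study on one CPU core while keeping the acquisition
#' statistics of the simulated characterization protocol. The mode basis
#' uses six Zernike-derived mirror modes (both astigmatisms, both comas,
#' primary spherical and one trefoil); tip, tilt and defocus are excluded
#' because they are degenerate with the unknown emitter position.
#'
#' @param coupling_strength mirror-mode cross-coupling of the synthetic
#'   mirror basis (0 = pure Zernike modes).
#' @param seed seed for the synthetic mirror-mode draw.
#' @return list with `optics`, `basis` (6 modes), `acq` and
#'   `focal_shift_constants` (the measured apparent-focus slope of the
#'   spherical mode in this model, -0.106 um per unit amplitude).
#' @export
desk_setup <- function(coupling_strength = 0.1, seed = 424) {
  optics <- optical_config()
  zern <- build_zernike_basis(6, optics, wyant_indices = 4:9)
  basis <- if (coupling_strength > 0)
    build_mirror_basis(zern, coupling_strength, seed = seed) else zern
  list(optics = optics, basis = basis, acq = acquisition_config(),
       focal_shift_constants = c("5" = -0.106))
}

#' Train the desk-scale three-network ensemble
#'
#' Trains the networks as a curriculum: the largest-range member is
#' trained from scratch (it alone handles the first, fully aberrated
#' update and gets the largest set), and each smaller-range member is
#' fine-tuned from the next-larger one on its own freshly simulated
#' range-restricted set. Training is deterministic given the seed.
#'
#' @param setup a [desk_setup()] list (or one with the same fields).
#' @param ranges list of training W_rms intervals, smallest first.
#' @param n_samples training pairs per network (smallest range first).
#' @param epochs per-network epochs; the smaller-range members need
#'   fewer since they start from the larger one's weights.
#' @param lr Adam step sizes per network.
#' @param seed master seed.
#' @param verbose print per-epoch losses.
#' @return `dlao_ensemble` of trained networks.
#' @export
train_desk_ensemble <- function(setup = desk_setup(),
                                ranges = list(c(0, 0.8), c(0, 1.8),
                                              c(0, 3.4)),
                                n_samples = c(12000, 12000, 24000),
                                epochs = c(12, 12, 22),
                                lr = c(1e-3, 1e-3, 2e-3),
                                seed = 1, verbose = FALSE) {
  k <- length(ranges)
  n_samples <- rep_len(n_samples, k)
  epochs <- rep_len(epochs, k)
  lr <- rep_len(lr, k)
  nets <- vector("list", k)
  prev <- NULL
  for (i in rev(seq_len(k))) {
    tc <- training_config(n_samples = n_samples[i],
                          amplitude_range = ranges[[i]],
                          seed = derive_seed(seed, 100 + i))
    ts <- generate_training_set(setup$basis, tc, setup$optics)
    net <- if (is.null(prev))
      build_network(n_modes = setup$basis$n_modes,
                    input_size = setup$optics$psf_size,
                    seed = derive_seed(seed, 200 + i))
    else prev
    nets[[i]] <- train_network(net, ts, epochs = epochs[i], lr = lr[i],
                               seed = derive_seed(seed, 300 + i),
                               verbose = verbose)
    prev <- nets[[i]]
  }
  network_ensemble(nets, ranges)
}
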