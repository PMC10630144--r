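#' Build an untrained coefficient-regression network
#'
#' A compact convolutional network mapping a biplane subregion (2 input
#' channels) to `n_modes` wavefront-mode amplitudes: stride-2 downsampling
#' convolutions with batch normalization and PReLU activations, two
#' residual blocks at intermediate resolutions, a "fully connecting"
#' valid convolution down to 1 x 1 spatial size and a final 1 x 1
#' convolution emitting the coefficient vector.
#'
#' @param n_modes output vector length (28 for the full mirror-mode basis;
#'   the desk-scale presets use 6).
#' @param input_size crop side in pixels; must be divisible by the total
#'   stride (16) of the downsampling stack.
#' @param channels widths of the four downsampling stages.
#' @param head width of the fully-connecting stage.
#' @param seed seed for the weight initialization.
#' @return object of class `dlao_net` (untrained).
#' @export
build_network <- function(n_modes = 28, input_size = 32,
                          channels = c(8, 16, 32, 48), head = 96,
                          seed = 1) {
  stopifnot(length(channels) == 4, n_modes >= 1)
  if (input_size %% 16 != 0)
    stop("input size ", input_size,
         " is not divisible by the network's total stride (16)")
  final_sp <- input_size / 16
  layers <- list()
  add <- function(l) layers[[length(layers) + 1]] <<- l
  conv <- function(cin, cout, k, stride, pad, hin) {
    fan_in <- cin * k * k
    W <- matrix(stats::rnorm(cout * fan_in, 0, sqrt(2 / fan_in)), cout)
    list(type = "conv", W = W, b = rep(0, cout), cin = cin, cout = cout,
         kh = k, kw = k, stride = stride, pad = pad, hin = hin, win = hin)
  }
  bn <- function(c, hw) list(type = "bn", gamma = rep(1, c),
                             beta = rep(0, c), run_mean = rep(0, c),
                             run_var = rep(1, c), channels = c, hw = hw)
  prelu <- function(c, hw) list(type = "prelu", alpha = rep(0.25, c),
                                channels = c, hw = hw)
  with_preserved_seed(seed, {
    s <- input_size
    add(conv(2, channels[1], 3, 2, 1, s)); s <- s / 2
    add(bn(channels[1], s^2)); add(prelu(channels[1], s^2))
    add(conv(channels[1], channels[2], 3, 2, 1, s)); s <- s / 2
    add(bn(channels[2], s^2)); add(prelu(channels[2], s^2))
    # residual block
    add(list(type = "skip_save"))
    add(conv(channels[2], channels[2], 3, 1, 1, s))
    add(bn(channels[2], s^2)); add(prelu(channels[2], s^2))
    add(conv(channels[2], channels[2], 3, 1, 1, s))
    add(bn(channels[2], s^2))
    add(list(type = "skip_add")); add(prelu(channels[2], s^2))
    add(conv(channels[2], channels[3], 3, 2, 1, s)); s <- s / 2
    add(bn(channels[3], s^2)); add(prelu(channels[3], s^2))
    # residual block
    add(list(type = "skip_save"))
    add(conv(channels[3], channels[3], 3, 1, 1, s))
    add(bn(channels[3], s^2)); add(prelu(channels[3], s^2))
    add(conv(channels[3], channels[3], 3, 1, 1, s))
    add(bn(channels[3], s^2))
    add(list(type = "skip_add")); add(prelu(channels[3], s^2))
    add(conv(channels[3], channels[4], 3, 2, 1, s)); s <- s / 2
    add(bn(channels[4], s^2)); add(prelu(channels[4], s^2))
    # fully connect: valid conv to 1 x 1, then 1 x 1 head
    add(conv(channels[4], head, final_sp, 1, 0, s))
    add(prelu(head, 1))
    add(conv(head, n_modes, 1, 1, 0, 1))
  })
  n_par <- sum(vapply(layers, function(l) {
    sum(vapply(l[c("W", "b", "gamma", "beta", "alpha")],
               function(p) if (is.numeric(p)) length(p) else 0L, 0))
  }, 0))
  structure(list(layers = layers, n_modes = as.integer(n_modes),
                 input_size = input_size, channels = channels,
                 head = head, n_parameters = n_par, trained = FALSE,
                 normalization = "crop / max(total photons, 1)",
                 train_loss = NULL, val_loss = NULL),
            class = "dlao_net")
}

#' @export
print.dlao_net <- function(x, ...) {
  cat(sprintf("Wavefront-regression CNN: %d x %d biplane input -> %d modes\n",
              x$input_size, x$input_size, x$n_modes))
  cat(sprintf("  %d parameters; %s\n", x$n_parameters,
              if (x$trained) sprintf("trained (final val RMSE %.4f rad/mode)",
                                     sqrt(utils::tail(x$val_loss, 1)))
              else "untrained"))
  invisible(x)
}

# pack a list of biplane crops into the (2*H*W) x B layout the CNN uses
# (row-major within channel), normalizing each crop by its total photons
pack_crops <- function(crops, normalize = TRUE) {
  X <- vapply(crops, function(cr) {
    v <- c(as.vector(t(cr[[1]])), as.vector(t(cr[[2]])))
    if (normalize) v <- v / max(sum(v), 1)
    v
  }, numeric(2 * length(crops[[1]][[1]])))
  matrix(X, ncol = length(crops))
}

#' Train a coefficient-regression network
#'
#' Mean-squared-error regression of the wavefront coefficient vectors with
#' the Adam optimizer; fully deterministic for a fixed seed.
#'
#' @param net [build_network()] object.
#' @param training_set output of [generate_training_set()].
#' @param epochs,batch_size,lr optimization schedule.
#' @param validation_fraction fraction of samples held out to track the
#'   validation loss (taken from the end of the set).
#' @param seed seed for batch shuffling.
#' @param verbose print per-epoch losses.
#' @return the trained `dlao_net` with `train_loss` / `val_loss` curves
#'   (MSE per coefficient).
#' @export
train_network <- function(net, training_set, epochs = 15, batch_size = 64,
                          lr = 2e-3, validation_fraction = 0.05, seed = 1,
                          verbose = FALSE) {
  X <- training_set$X; Y <- training_set$Y
  stopifnot(ncol(X) == ncol(Y), nrow(Y) == net$n_modes)
  n <- ncol(X)
  if (n < 2) stop("training set is empty or too small")
  n_val <- max(0L, floor(n * validation_fraction))
  if (n_val > 0) {
    vi <- seq(n - n_val + 1, n)
    Xval <- X[, vi, drop = FALSE]; Yval <- Y[, vi, drop = FALSE]
    X <- X[, -vi, drop = FALSE]; Y <- Y[, -vi, drop = FALSE]
  } else {
    Xval <- matrix(0, nrow(X), 0); Yval <- matrix(0, nrow(Y), 0)
  }
  fit <- .cnn_train(net$layers, X, Y, Xval, Yval, epochs, batch_size, lr,
                    0.9, 0.999, 1e-8, seed, verbose)
  net$layers <- fit$layers
  net$train_loss <- as.vector(fit$train_loss)
  net$val_loss <- as.vector(fit$val_loss)
  net$trained <- TRUE
  net
}

#' Predict mode coefficients for a batch of subregions
#'
#' @param object trained `dlao_net`.
#' @param crops list of biplane crops (each a list of two matrices), or a
#'   pre-packed input matrix.
#' @param ... unused.
#' @return matrix with one row per crop, `n_modes` columns.
#' @export
predict.dlao_net <- function(object, crops, ...) {
  X <- if (is.matrix(crops)) crops else pack_crops(crops)
  t(.cnn_forward(object$layers, X, FALSE))
}
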