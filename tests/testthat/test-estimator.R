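test_that("network construction satisfies the shape contract", {
  net <- build_network(n_modes = 28, input_size = 32, seed = 1)
  expect_s3_class(net, "dlao_net")
  expect_gt(net$n_parameters, 1000)
  expect_error(build_network(input_size = 30), "stride")
  # forward pass on zeros: finite 28-vector
  z <- matrix(0, 2 * 32 * 32, 1)
  out <- predict(net, z)
  expect_equal(dim(out), c(1L, 28L))
  expect_true(all(is.finite(out)))
  # batch of k inputs -> k x n_modes
  out5 <- predict(net, matrix(rnorm(2048 * 5), 2048, 5))
  expect_equal(dim(out5), c(5L, 28L))
})

test_that("training-set labels respect the amplitude range and round-trip
           through the optics", {
  s <- desk_uncoupled()
  tc <- training_config(n_samples = 40, amplitude_range = c(0.5, 1.5),
                        seed = 3)
  ts <- generate_training_set(s$basis, tc, s$optics)
  expect_equal(dim(ts$X), c(2 * 32 * 32, 40))
  lab_wrms <- apply(ts$Y, 2, function(co)
    wrms(compose_wavefront(co, s$basis), s$optics))
  expect_true(all(lab_wrms >= 0.5 - 1e-9 & lab_wrms <= 1.5 + 1e-9))
  # labels survive a compose/decompose round trip (with baseline)
  base <- compose_wavefront(c(0.2, 0, 0, 0, 0.1, 0), s$basis)
  tcb <- training_config(n_samples = 5, amplitude_range = c(0.5, 1),
                         baseline_wavefront = base, seed = 4)
  tsb <- generate_training_set(s$basis, tcb, s$optics)
  for (i in 1:5) {
    ph <- compose_wavefront(tsb$Y[, i], s$basis) + base
    rec <- decompose_wavefront(ph - base, s$basis)$coefficients
    expect_equal(rec, tsb$Y[, i], tolerance = 1e-8)
  }
  # degenerate range: zero labels
  ts0 <- generate_training_set(
    s$basis, training_config(n_samples = 8, amplitude_range = c(0, 0),
                             seed = 5), s$optics)
  expect_true(all(ts0$Y == 0))
  # determinism
  ts2 <- generate_training_set(s$basis, tc, s$optics)
  expect_identical(ts$X, ts2$X)
})

test_that("training is deterministic and fits a degenerate set", {
  s <- desk_uncoupled()
  tc <- training_config(n_samples = 400, amplitude_range = c(0, 0),
                        seed = 6)
  ts <- generate_training_set(s$basis, tc, s$optics)
  net <- build_network(n_modes = 6, seed = 2)
  t1 <- train_network(net, ts, epochs = 4, seed = 9)
  t2 <- train_network(net, ts, epochs = 4, seed = 9)
  expect_identical(t1$layers, t2$layers)
  # all-zero labels: with enough steps the net learns to predict ~0
  t3 <- train_network(net, ts, epochs = 60, lr = 5e-3, seed = 9)
  preds <- predict(t3, ts$X[, 1:100])
  expect_lt(sqrt(mean(preds^2)), 0.02)
})

test_that("estimate_wavefront aggregates per-subregion outputs", {
  net <- build_network(n_modes = 6, seed = 3)
  crop <- list(matrix(runif(1024), 32), matrix(runif(1024), 32))
  est <- estimate_wavefront(rep(list(crop), 10), net)
  expect_s3_class(est, "dlao_estimate")
  expect_equal(est$n_subregions, 10)
  expect_equal(est$stderr, rep(0, 6))            # identical inputs
  expect_equal(est$mean, predict(net, list(crop))[1, ],
               ignore_attr = TRUE)
  expect_error(estimate_wavefront(list(crop), net),
               class = "dlao_insufficient_detections")
})

test_that("characterize_response arithmetic: oracle gives the identity,
           constant estimators give zero", {
  s <- desk_uncoupled()
  oracle <- function(crops)
    matrix(attr(crops, "truth"), length(crops), 6, byrow = TRUE)
  resp <- characterize_response(oracle, s$basis, s$optics,
                                amplitude = 0.5, n_crops = 2)
  expect_equal(resp$response, diag(6), tolerance = 1e-12)
  expect_true(all(resp$diagonal_dominant))
  zero_resp <- characterize_response(
    function(crops) matrix(1, length(crops), 6),
    s$basis, s$optics, amplitude = 0.5, n_crops = 2)
  expect_equal(zero_resp$response, matrix(0, 6, 6))
})

test_that("the trained estimator recovers induced single-mode
           distortions", {
  s <- desk()
  ens <- desk_ensemble()
  net1 <- ens$networks[[1]]
  expect_lt(sqrt(tail(net1$val_loss, 1)), 0.15)  # per-mode RMSE target
  # parameter recovery: 0.5 rad single modes, 100 high-SNR crops
  for (mode in c(1, 3)) {
    co <- replace(rep(0, 6), mode, 0.5)
    crops <- make_crops(co, s$basis, s$optics, n = 100, photons = 5000,
                        seed = 70 + mode)
    est <- estimate_wavefront(crops, net1)
    expect_lt(abs(est$mean[mode] - 0.5), 0.1)
    expect_lt(sqrt(sum((est$mean - co)^2)), 0.2)
  }
})

test_that("the estimated amplitude responds monotonically and sharpens
           with photons", {
  s <- desk()
  ens <- desk_ensemble()
  levels <- seq(0.25, 1, length.out = 10)
  est_at <- function(lvl, photons, seed) {
    co <- replace(rep(0, 6), 2, lvl)
    crops <- make_crops(co, s$basis, s$optics, n = 40, photons = photons,
                        seed = seed)
    net <- ens$networks[[if (lvl <= 0.8) 1 else 2]]
    estimate_wavefront(crops, net)$mean[2]
  }
  ests <- vapply(seq_along(levels), function(i)
    est_at(levels[i], 4000, 80 + i), 0)
  expect_gt(cor(levels, ests, method = "spearman"), 0.95)
  # paired simulation: error at 10,000 photons < error at 1,000 photons
  co <- replace(rep(0, 6), 1, 0.5)
  err <- vapply(c(1000, 10000), function(ph) {
    e <- vapply(1:6, function(r) {
      crops <- make_crops(co, s$basis, s$optics, n = 30, photons = ph,
                          seed = 90 + r)
      sqrt(sum((estimate_wavefront(crops, ens$networks[[1]])$mean -
                  co)^2))
    }, 0)
    mean(e)
  }, 0)
  expect_lt(err[2], err[1])
})
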