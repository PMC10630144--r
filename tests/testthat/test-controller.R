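test_that("Kalman closed forms: uninformative prior, averaging, variance
           halving", {
  ks <- kalman_state(3, process_noise = 0)
  m <- list(mean = c(1, -2, 0.5), stderr = c(0.1, 0.2, 0.3))
  k1 <- kalman_update(ks, m)
  # effectively uninformative prior: posterior = measurement
  expect_equal(k1$mean, m$mean, tolerance = 1e-4)
  # a second equal-variance measurement: posterior = average, variance
  # halved
  m2 <- list(mean = c(2, 0, 1.5), stderr = m$stderr)
  k2 <- kalman_update(k1, m2)
  expect_equal(k2$mean, (m$mean + m2$mean) / 2, tolerance = 1e-4)
  expect_equal(k2$variance, m$stderr^2 / 2, tolerance = 1e-3)
  expect_error(kalman_update(ks, list(mean = 1:2, stderr = c(1, 1))),
               "dimension")
})

test_that("a measurement sequence with zero process noise equals the
           inverse-variance-weighted batch mean", {
  set.seed(7)
  n <- 6
  ys <- matrix(rnorm(n * 4), n, 4)
  ses <- matrix(runif(n * 4, 0.05, 0.4), n, 4)
  ks <- kalman_state(4, prior_var = rep(Inf, 4), process_noise = 0,
                     stderr_floor = 1e-6)
  for (i in seq_len(n))
    ks <- kalman_update(ks, list(mean = ys[i, ], stderr = ses[i, ]))
  w <- 1 / ses^2
  batch <- colSums(ys * w) / colSums(w)
  expect_equal(ks$mean, batch, tolerance = 1e-10)
  # posterior variance never exceeds prior or measurement variance
  expect_true(all(ks$variance <= apply(ses^2, 2, min) + 1e-12))
})

test_that("network selection follows the uncertainty-banded range rule", {
  ens <- structure(list(networks = vector("list", 3),
                        ranges = list(c(0, 0.8), c(0, 1.8), c(0, 3)),
                        n_modes = 6), class = "dlao_ensemble")
  est <- function(mag, se = 0) {
    m <- rep(0, 6); m[1] <- mag
    list(mean = m, stderr = rep(se / sqrt(6), 6))
  }
  expect_equal(select_network(est(2.5), ens), 3L)
  expect_equal(select_network(est(0.3, 0.05), ens), 1L)
  expect_equal(select_network(est(5), ens), 3L)       # beyond all ranges
  expect_equal(select_network(est(0.8), ens), 1L)     # boundary -> lower
  expect_equal(select_network(est(0.8 + 1e-9), ens), 2L)
})

test_that("mirror updates accumulate, clip at the stroke limit and obey
           the coupling algebra", {
  s <- desk_uncoupled()
  mir <- mirror_model(s$basis, stroke = Inf)
  mir0 <- apply_mirror_update(mir, rep(0, 6))
  expect_equal(mirror_realized(mir0)$coefficients, rep(0, 6))
  expect_equal(mirror_realized(mir0)$phase, matrix(0, 64, 64))
  # identity coupling, gain 1: a full correction cancels the truth
  truth <- c(0.5, -0.2, 0.3, 0.1, -0.4, 0.2)
  mir1 <- apply_mirror_update(mir, -truth)
  expect_equal(mirror_realized(mir1)$coefficients, -truth)
  # non-identity coupling: single full correction leaves (I - C) truth
  C <- diag(6) + matrix(0.03, 6, 6) - diag(rep(0.03, 6))
  mirc <- mirror_model(s$basis, coupling = C, stroke = Inf)
  mirc <- apply_mirror_update(mirc, -truth)
  resid <- truth + mirror_realized(mirc)$coefficients
  expect_equal(resid, as.vector((diag(6) - C) %*% truth),
               tolerance = 1e-12)
  # stroke clipping warns
  expect_warning(apply_mirror_update(mirror_model(s$basis, stroke = 1,
                                                  stroke_limit = 2),
                                     rep(5, 6)), "clip")
  # tanh nonlinearity undercorrects large commands
  mirt <- mirror_model(s$basis, stroke = 4)
  mirt <- apply_mirror_update(mirt, rep(2, 6))
  expect_true(all(mirror_realized(mirt)$coefficients <= 2))
  expect_equal(mirror_realized(mirt)$coefficients,
               rep(4 * tanh(0.5), 6))
})

test_that("focal-shift compensation is the configured linear form", {
  constants <- c("5" = -0.3, "15" = -0.2)
  delta <- rep(0, 20)
  expect_equal(compensate_focal_shift(delta, constants), 0)
  delta[5] <- 1
  expect_equal(compensate_focal_shift(delta, constants), -0.3)
  delta[15] <- 1
  expect_equal(compensate_focal_shift(delta, constants), -0.5)
  expect_error(compensate_focal_shift(rep(0, 3), constants), "indices")
})

test_that("with a perfect oracle and an ideal mirror the loop converges
           in exactly one update", {
  s <- desk_uncoupled()
  truth <- scale_to_wrms(c(1, -1, 0.5, 0.2, -0.3, 0.1), 1.2, s$basis)
  tr <- run_closed_loop(truth, oracle_estimator(s$basis),
                        mirror_model(s$basis, stroke = Inf), s$optics,
                        s$acq, loop_config(), seed = 2)
  expect_equal(tr$residual_wrms[1], 1.2, tolerance = 1e-9)
  expect_lt(tr$residual_wrms[2], 1e-6)
})

test_that("closed loops are deterministic and stable at zero distortion", {
  s <- desk()
  ens <- desk_ensemble()
  cfg <- loop_config(max_updates = 3, stop_consecutive = 99)
  t1 <- run_closed_loop(rep(0, 6), ens, mirror_model(s$basis), s$optics,
                        s$acq, cfg, seed = 31)
  t2 <- run_closed_loop(rep(0, 6), ens, mirror_model(s$basis), s$optics,
                        s$acq, cfg, seed = 31)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "commanded"), attr(t2, "commanded"))
  # null stability over a full-length run: no runaway from noise
  cfg20 <- loop_config(max_updates = 20, stop_consecutive = 99)
  tr <- run_closed_loop(rep(0, 6), ens, mirror_model(s$basis), s$optics,
                        s$acq, cfg20, seed = 32)
  expect_true(all(tr$residual_wrms < 0.15))
})

test_that("cycles without enough detections skip the update and the loop
           continues", {
  s <- desk()
  ens <- desk_ensemble()
  dark <- acquisition_config(mean_emitters = 1e-9)
  truth <- scale_to_wrms(rep(1, 6), 1, s$basis)
  tr <- run_closed_loop(truth, ens, mirror_model(s$basis), s$optics,
                        dark, loop_config(max_updates = 2), seed = 33)
  expect_true(all(tr$skipped[-1]))
  expect_equal(tr$residual_wrms, rep(1, 3), tolerance = 1e-9)
})

test_that("dynamic distortion injections perturb and the loop recovers", {
  s <- desk()
  ens <- desk_ensemble()
  cfg <- loop_config(max_updates = 9, stop_consecutive = 99,
                     focal_shift_constants = s$focal_shift_constants)
  tr <- inject_dynamic_distortions(rep(0, 6), ens, mirror_model(s$basis),
                                   s$optics, s$acq, cfg, schedule = 2,
                                   level = 0.75, seed = 34)
  expect_true(tr$injected[tr$update == 2])
  # the 0.75-rad injection is visible even after the same cycle's
  # correction (trace rows record the post-update residual) ...
  expect_gt(tr$residual_wrms[tr$update == 2],
            tr$residual_wrms[tr$update == 1] + 0.1)
  # ... and the loop pulls it back down within the recovery window
  expect_lt(min(tr$residual_wrms[tr$update > 2]), 0.3)
  # zero-level injections leave the loop identical to a plain run
  cfg2 <- loop_config(max_updates = 2, stop_consecutive = 99)
  a <- inject_dynamic_distortions(rep(0, 6), ens, mirror_model(s$basis),
                                  s$optics, s$acq, cfg2, schedule = 1:2,
                                  level = 0, seed = 35)
  b <- run_closed_loop(rep(0, 6), ens, mirror_model(s$basis), s$optics,
                       s$acq, cfg2, seed = 35)
  expect_equal(a$residual_wrms, b$residual_wrms)
})
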