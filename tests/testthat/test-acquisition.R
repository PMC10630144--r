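test_that("acquisition_config enforces its invariants", {
  expect_error(acquisition_config(subregion_size = 31), "even")
  expect_error(acquisition_config(isolation_radius = 10,
                                  subregion_size = 32), "isolation")
  expect_error(acquisition_config(mean_photons = -1))
})

test_that("emitter draws match the configured statistics", {
  acq <- acquisition_config()
  set.seed(11)
  draws <- replicate(10000, nrow(sample_emitters(acq)))
  # Poisson(13): the mean over 10,000 frames sits within 3 standard errors
  expect_gt(mean(draws), 13 - 3 * sqrt(13 / 10000))
  expect_lt(mean(draws), 13 + 3 * sqrt(13 / 10000))
  set.seed(12)
  ph <- unlist(replicate(200, sample_emitters(acq)$photons))
  n <- length(ph)
  expect_lt(abs(mean(ph) - 2500), 3 * 2500 / sqrt(n))
  z <- unlist(replicate(200, sample_emitters(acq)$z))
  expect_gte(min(z), -1000); expect_lte(max(z), 1000)
  # determinism
  set.seed(5); a <- sample_emitters(acq)
  set.seed(5); b <- sample_emitters(acq)
  expect_identical(a, b)
})

test_that("simulated frames carry Poisson background at the configured
           level", {
  acq <- acquisition_config(mean_emitters = 1e-9)
  opt <- optical_config()
  set.seed(21)
  fr <- simulate_frames(NULL, 6, acq, opt)
  px <- unlist(lapply(fr, function(f) f$pixels[[1]]))
  expect_equal(mean(px), 10, tolerance = 0.01)
  # index-of-dispersion check: variance ~ mean for Poisson counts
  expect_equal(var(px) / mean(px), 1, tolerance = 0.05)
  # zero-photon emitters leave a pure background frame
  acq2 <- acquisition_config(mean_photons = 1e-12)
  set.seed(22)
  f2 <- simulate_frames(NULL, 1, acq2, opt)[[1]]
  expect_lt(max(f2$pixels[[1]]), 30)  # no source structure above noise
  # noiseless mode returns expected values
  set.seed(23)
  f3 <- simulate_frames(NULL, 1, acq, opt, noise = FALSE)[[1]]
  expect_false(any(f3$pixels[[1]] < 10))
})

test_that("temporal median recovers the background under sparse
           emitters", {
  acq <- acquisition_config()
  opt <- optical_config()
  # constant frames: the median is that constant; window 1 returns the
  # frame itself
  fr <- list(list(pixels = list(matrix(7, 8, 8), matrix(3, 8, 8))))
  expect_equal(temporal_median_background(fr, 1)[[1]], matrix(7, 8, 8))
  expect_error(temporal_median_background(fr, 2), "odd")
  set.seed(31)
  frames <- simulate_frames(NULL, 101, acq, opt)
  bg <- temporal_median_background(frames, 101)
  expect_gte(mean(abs(bg[[1]] - 10) <= 1), 0.99)
})

test_that("segmentation finds isolated emitters and applies the photon
           and isolation rules", {
  opt <- optical_config()
  acq <- acquisition_config()
  pup <- pupil_function(opt)
  fs <- acq$frame_size
  inject <- function(emitters) {
    planes <- list(matrix(0, fs, fs), matrix(0, fs, fs))
    for (e in emitters) {
      crop <- render_psf(pup, NULL,
                         emitter_state(z = e$z, photons = e$photons), opt)
      planes <- dlao:::add_crop(planes, crop, e$x, e$y, fs, 32)
    }
    planes <- lapply(planes, function(p)
      matrix(rpois(fs * fs, p + 10), fs, fs))
    list(pixels = planes, truth = NULL)
  }
  set.seed(41)
  # one bright centered emitter -> exactly one subregion at the truth
  f1 <- inject(list(list(x = 64, y = 64, z = 0, photons = 5000)))
  s1 <- segment_subregions(f1, 10, acq)
  expect_length(s1, 1)
  expect_lte(max(abs(s1[[1]]$center - c(64, 64))), 1)
  expect_gte(s1[[1]]$total_photons, 1500)
  # 800 photons falls below the 1,500-photon intensity threshold
  f2 <- inject(list(list(x = 64, y = 64, z = 0, photons = 800)))
  expect_length(segment_subregions(f2, 10, acq), 0)
  # two resolved emitters closer than the isolation radius: both
  # rejected (closer pairs merge into a single smoothed peak and are
  # indistinguishable from one emitter at detection time)
  f3 <- inject(list(list(x = 58, y = 64, z = 0, photons = 5000),
                    list(x = 68, y = 64, z = 0, photons = 5000)))
  expect_length(segment_subregions(f3, 10, acq), 0)
  # border-clipped crop discarded
  f4 <- inject(list(list(x = 8, y = 64, z = 0, photons = 5000)))
  expect_length(segment_subregions(f4, 10, acq), 0)
})

test_that("detection recall exceeds 90% for isolated bright emitters and
           false positives stay rare", {
  opt <- optical_config()
  acq <- acquisition_config()
  set.seed(51)
  found <- 0; total <- 0
  for (i in 1:500) {
    f <- simulate_frames(NULL, 1, acq, opt)[[1]]
    subs <- segment_subregions(f, 10, acq)
    tr <- f$truth
    for (j in seq_len(nrow(tr))) {
      if (tr$photons[j] < 2500) next
      if (min(tr$x[j], tr$y[j]) < 17 || max(tr$x[j], tr$y[j]) > 112) next
      d <- sqrt((tr$x - tr$x[j])^2 + (tr$y - tr$y[j])^2)
      d[j] <- Inf
      if (min(d) < 24) next  # truly isolated (margin over the radius)
      total <- total + 1
      hit <- any(vapply(subs, function(s)
        sqrt(sum((s$center - c(tr$x[j], tr$y[j]))^2)) < 3, TRUE))
      found <- found + hit
    }
  }
  expect_gte(total, 100)  # enough isolated bright cases to judge recall
  expect_gte(found / total, 0.9)
  # pure-background frames: at most 0.01 false detections per frame
  acq0 <- acquisition_config(mean_emitters = 1e-9)
  set.seed(52)
  fp <- sum(vapply(1:150, function(i) {
    f <- simulate_frames(NULL, 1, acq0, opt)[[1]]
    length(segment_subregions(f, 10, acq0))
  }, 0))
  expect_lte(fp / 150, 0.01)
})

test_that("the acquisition chain is deterministic under a fixed seed", {
  opt <- optical_config()
  acq <- acquisition_config()
  run <- function() {
    set.seed(61)
    fr <- simulate_frames(NULL, 3, acq, opt)
    bg <- temporal_median_background(fr, 3)
    lapply(fr, segment_subregions, background = bg, config = acq)
  }
  expect_identical(run(), run())
})
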