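test_that("optical_config validates its invariants", {
  expect_error(optical_config(na = 1.5, n_immersion = 1.406), "immersion")
  expect_error(optical_config(na = 1.4, n_sample = 1.33), "critical angle")
  expect_error(optical_config(pupil_grid = 15), "even")
  expect_error(optical_config(psf_size = 15, pupil_grid = 32), "even")
  expect_error(optical_config(psf_size = 64, pupil_grid = 32), "exceed")
  opt <- optical_config()
  expect_true(opt$n_support > 0)
  expect_equal(dim(opt$support), c(64, 64))
})

test_that("wrms equals the direct RMS over support pixels", {
  opt <- tiny_optics()
  expect_equal(wrms(matrix(0, 32, 32), opt), 0)
  const <- matrix(-1.3, 32, 32)
  expect_equal(wrms(const, opt), 1.3)
  set.seed(7)
  ph <- matrix(rnorm(32 * 32), 32, 32)
  expect_equal(wrms(ph, opt), sqrt(mean(ph[opt$support]^2)))
  # scaling linearity
  expect_equal(wrms(-2.5 * ph, opt), 2.5 * wrms(ph, opt))
})

test_that("defocus phase follows the angular-spectrum closed form", {
  opt <- optical_config()
  expect_equal(defocus_phase(0, opt), matrix(0, 64, 64))
  dp <- defocus_phase(500, opt)
  # odd symmetry in z
  expect_equal(defocus_phase(-500, opt), -dp)
  # closed form at the pupil center (k = 0)
  expect_equal(dp[33, 33], 2 * pi * 500 * opt$n_immersion / opt$wavelength)
  expect_error(defocus_phase(6000, opt), "5 um")
})

test_that("index-mismatch phase is null when indices match and purely
           radial otherwise", {
  opt <- optical_config()
  expect_equal(index_mismatch_phase(0, opt), matrix(0, 64, 64))
  matched <- optical_config(n_sample = 1.406)
  expect_equal(index_mismatch_phase(50000, matched),
               matrix(0, 64, 64))
  # a deep index-mismatch wavefront projects only onto radially
  # symmetric modes (defocus, spherical), never onto odd/azimuthal ones
  b <- build_zernike_basis(10, opt)
  co <- decompose_wavefront(index_mismatch_phase(134000, opt),
                            b)$coefficients
  radial <- b$wyant %in% c(3, 8)  # defocus, primary spherical
  expect_true(all(abs(co[!radial]) < 1e-8))
  expect_true(any(abs(co[radial]) > 1))
})

test_that("rendered PSFs conserve photons and obey basic symmetries", {
  opt <- optical_config()
  pup <- pupil_function(opt)
  for (z in c(0, 600, 1000)) {
    ims <- render_psf(pup, NULL, emitter_state(z = z, photons = 1000),
                      opt, crop = FALSE)
    expect_equal(sum(ims[[1]]) + sum(ims[[2]]), 1000,
                 tolerance = 0.01)
  }
  a <- render_psf(pup, NULL, emitter_state(photons = 1000), opt)[[1]]
  # symmetric under 180 degree rotation about the center pixel (17, 17);
  # on an even grid the first row/column has no rotated counterpart
  sub <- a[2:32, 2:32]
  expect_lt(max(abs(sub - sub[31:1, 31:1])) / max(a), 1e-6)
  # centrally peaked
  expect_equal(which(a == max(a)), which.max(a))
  expect_equal(arrayInd(which.max(a), dim(a)), matrix(c(17L, 17L), 1))
  # background offset
  ab <- render_psf(pup, NULL, emitter_state(photons = 0, background = 3),
                   opt)[[1]]
  expect_equal(ab, matrix(3, 32, 32))
  expect_error(render_psf(pup, NULL, emitter_state(x = 1e5), opt),
               "outside")
})

test_that("a one-pixel emitter shift translates the image by one column", {
  opt <- optical_config()
  pup <- pupil_function(opt)
  a <- render_psf(pup, NULL, emitter_state(photons = 1000), opt)[[1]]
  b <- render_psf(pup, NULL,
                  emitter_state(x = opt$pixel_size, photons = 1000),
                  opt)[[1]]
  expect_lt(max(abs(b[, 2:32] - a[, 1:31])) / max(a), 1e-6)
})

test_that("adding a piston constant to the pupil phase leaves the PSF
           unchanged", {
  opt <- tiny_optics()
  pup <- pupil_function(opt)
  b <- build_zernike_basis(4, opt)
  ab <- compose_wavefront(c(0.5, -0.2, 0.3, 0.1), b)
  em <- emitter_state(z = 300, photons = 2000)
  im1 <- render_psf(pup, ab, em, opt)
  piston <- matrix(1.234, 32, 32)
  im2 <- render_psf(pup, ab + piston, em, opt)
  expect_lt(max(abs(im1[[1]] - im2[[1]])), 1e-9)
  expect_lt(max(abs(im1[[2]] - im2[[2]])), 1e-9)
})

test_that("pure astigmatism elongates the two biplane images along
           orthogonal axes", {
  opt <- optical_config()
  pup <- pupil_function(opt)
  b <- build_zernike_basis(6, opt, wyant_indices = 4:9)
  ab <- compose_wavefront(c(1, 0, 0, 0, 0, 0), b)  # vertical astigmatism
  principal_axis <- function(im) {
    im <- im - min(im)
    xg <- matrix(seq_len(ncol(im)), nrow(im), ncol(im), byrow = TRUE)
    yg <- matrix(seq_len(nrow(im)), nrow(im), ncol(im))
    w <- im / sum(im)
    mx <- sum(w * xg); my <- sum(w * yg)
    cov <- matrix(c(sum(w * (xg - mx)^2), sum(w * (xg - mx) * (yg - my)),
                    sum(w * (xg - mx) * (yg - my)), sum(w * (yg - my)^2)),
                  2)
    eigen(cov)$vectors[, 1]
  }
  ims_p <- render_psf(pup, ab, emitter_state(z = 400, photons = 5000), opt)
  ims_m <- render_psf(pup, ab, emitter_state(z = -400, photons = 5000),
                      opt)
  ims_0 <- render_psf(pup, ab, emitter_state(z = 0, photons = 5000), opt)
  # opposite net defocus flips the elongation axis by 90 degrees: the
  # same detection plane at z = +400 vs z = -400 (net defocus +700 vs
  # -700 nm) ...
  v_p <- principal_axis(ims_p[[2]])
  v_m <- principal_axis(ims_m[[2]])
  expect_lt(abs(sum(v_p * v_m)), 0.2)
  # ... and the two detection planes of an in-focus emitter (-300 vs
  # +300 nm), the textbook biplane astigmatism signature
  expect_lt(abs(sum(principal_axis(ims_0[[1]]) *
                      principal_axis(ims_0[[2]]))), 0.2)
  # same-sign net defocus keeps the axis (plane 1 vs plane 2 at z = +400:
  # +100 and +700 nm)
  expect_gt(abs(sum(v_p * principal_axis(ims_p[[1]]))), 0.85)
})

test_that("render_psf matches a direct-summation diffraction integral", {
  # independent oracle: brute-force DFT on a tiny grid
  opt <- optical_config(pupil_grid = 16, psf_size = 16)
  pup <- pupil_function(opt)
  em <- emitter_state(x = 50, y = -30, z = 200, photons = 800)
  fast <- render_psf(pup, NULL, em, opt, crop = FALSE)
  n <- 16
  ph <- pup$phase + 2 * pi * (opt$kx * em$x + opt$ky * em$y) +
    defocus_phase(em$z + opt$plane_offsets[1], opt)
  field <- pup$magnitude * exp(1i * ph)
  slow <- matrix(0, n, n)
  idx <- seq_len(n) - 1 - n / 2
  for (u in seq_len(n)) for (v in seq_len(n)) {
    s <- 0
    for (a in seq_len(n)) for (bb in seq_len(n))
      s <- s + field[a, bb] *
        exp(-2i * pi * (idx[a] * idx[u] + idx[bb] * idx[v]) / n)
    slow[u, v] <- Mod(s)^2
  }
  slow <- slow / (sum(pup$magnitude^2) * n^2) * em$photons / 2
  expect_lt(max(abs(slow - fast[[1]])) / max(slow), 1e-6)
})

test_that("bead stacks follow the through-focus scan protocol", {
  opt <- optical_config(pupil_grid = 32, psf_size = 32)
  pup <- pupil_function(opt)
  st <- render_bead_stack(pup, NULL, opt)
  expect_equal(dim(st$images)[1], 31)   # -1.5 to 1.5 um in 100 nm steps
  expect_equal(st$z_positions, seq(-1500, 1500, 100))
  # unaberrated: the z = 0 slice holds the global peak
  peaks <- apply(st$images, 1, max)
  expect_equal(which.max(peaks), 16L)
  expect_equal(ncc3d(st, st), 1.0)
})
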