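#' @useDynLib dlao, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Wyant (fringe) index -> radial order n, azimuthal frequency m, parity.
# Group q = floor(sqrt(j)); within a group m runs from q down to 0, cosine
# before sine. j = 0 is piston.
wyant_nm <- function(j) {
  q <- floor(sqrt(j))
  r <- j - q^2
  m <- q - floor(r / 2)
  list(n = 2 * q - m, m = m, cosine = (r %% 2) == 0)
}

zernike_radial <- function(n, m, rho) {
  out <- 0
  for (s in 0:((n - m) / 2)) {
    out <- out + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) *
         factorial((n - m) / 2 - s)) * rho^(n - 2 * s)
  }
  out
}

wyant_mode_names <- function(js) {
  known <- c("piston", "tilt_x", "tilt_y", "defocus", "astig_v", "astig_o",
             "coma_x", "coma_y", "spherical", "trefoil_x", "trefoil_y",
             "astig2_v", "astig2_o", "coma2_x", "coma2_y", "spherical2")
  vapply(js, function(j) {
    if (j + 1 <= length(known)) known[j + 1] else {
      nm <- wyant_nm(j)
      sprintf("Z%d_%d%s", nm$n, nm$m,
              if (nm$m > 0) (if (nm$cosine) "c" else "s") else "")
    }
  }, character(1))
}

#' Zernike mode basis on the pupil support
#'
#' Samples Zernike circle polynomials in Wyant (fringe) order on the pupil
#' support, drops piston, orthonormalizes the sampled modes by modified
#' Gram-Schmidt under the support-mean inner product and scales each to
#' unit W_rms, so a coefficient of 1 on any single mode produces exactly
#' 1 radian of RMS wavefront error.
#'
#' @param n_modes number of modes (default 28).
#' @param optics [optical_config()] object.
#' @param wyant_indices which Wyant indices to use (default `1:n_modes`,
#'   i.e. everything after piston). The desk-scale presets use indices
#'   4:9 (both astigmatisms, both comas, primary spherical, one trefoil),
#'   excluding tip/tilt/defocus which are degenerate with the emitter
#'   position.
#' @return object of class `dlao_basis`.
#' @export
build_zernike_basis <- function(n_modes = 28, optics,
                                wyant_indices = seq_len(n_modes)) {
  stopifnot(n_modes >= 1, length(wyant_indices) == n_modes)
  if (any(wyant_indices < 1))
    stop("piston (Wyant index 0) is excluded from wavefront bases")
  if (max(wyant_indices) > 120)
    stop("Wyant indices above 120 are not implemented")
  sup <- optics$support
  rho <- sqrt(optics$kr2[sup]) / (optics$na / optics$wavelength)
  rho <- pmin(rho, 1)
  theta <- atan2(optics$ky[sup], optics$kx[sup])
  m_raw <- vapply(wyant_indices, function(j) {
    nm <- wyant_nm(j)
    rad <- zernike_radial(nm$n, nm$m, rho)
    if (nm$m == 0) rad
    else if (nm$cosine) rad * cos(nm$m * theta)
    else rad * sin(nm$m * theta)
  }, numeric(sum(sup)))
  # modified Gram-Schmidt under <a,b> = mean(a*b) over support
  M <- m_raw
  k <- ncol(M)
  for (i in seq_len(k)) {
    v <- M[, i]
    if (i > 1) for (j in seq_len(i - 1)) {
      v <- v - mean(v * M[, j]) * M[, j]
    }
    nrm <- sqrt(mean(v^2))
    if (nrm < 1e-10)
      stop("mode ", wyant_indices[i], " is numerically degenerate ",
           "on this pupil sampling")
    M[, i] <- v / nrm
  }
  new_basis(M, optics, wyant = wyant_indices,
            names = wyant_mode_names(wyant_indices),
            coupling = diag(n_modes))
}

new_basis <- function(M, optics, wyant = NULL, names = NULL,
                      coupling = NULL, orthonormal = NULL) {
  n_modes <- ncol(M)
  G <- crossprod(M) / nrow(M)
  if (is.null(orthonormal))
    orthonormal <- max(abs(G - diag(n_modes))) < 1e-8
  obj <- list(M = M, n_modes = n_modes, support = optics$support,
              pupil_grid = optics$pupil_grid, wyant = wyant,
              mode_names = names, coupling = coupling,
              orthonormal = orthonormal, gram = G)
  class(obj) <- "dlao_basis"
  obj
}

#' @export
print.dlao_basis <- function(x, ...) {
  cat(sprintf("Wavefront mode basis: %d modes on %d support pixels%s\n",
              x$n_modes, nrow(x$M),
              if (x$orthonormal) " (orthonormal)" else ""))
  if (!is.null(x$mode_names))
    cat("  ", paste(x$mode_names, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one basis mode as a full pupil image
#' @param basis [build_zernike_basis()] object.
#' @param k mode index.
#' @return pupil-phase matrix (radians).
#' @export
basis_mode <- function(basis, k) {
  n <- basis$pupil_grid
  img <- matrix(0, n, n)
  img[basis$support] <- basis$M[, k]
  img
}

#' Synthetic mirror deformation-mode basis
#'
#' Deformable mirrors realize wavefront shapes that resemble, but do not
#' equal, Zernike polynomials: each native mirror mode is a cross-coupled
#' mixture of its parent Zernike and its neighbours. Since measured mirror
#' deformations of a physical mirror are instrument specific, this
#' constructor builds a synthetic surrogate: it mixes the supplied Zernike
#' modes with a seeded near-identity matrix (off-diagonal entries uniform
#' on `[-1, 1]`, scaled by `coupling_strength / sqrt(n_modes - 1)`) and
#' renormalizes each mixed mode to unit W_rms. The mixing matrix is stored
#' in `$coupling`.
#'
#' @param zernike a [build_zernike_basis()] basis.
#' @param coupling_strength in `[0, 0.5)`; 0 returns the input modes.
#' @param seed integer seed for the mixing draw.
#' @return object of class `dlao_basis` (generally non-orthogonal).
#' @export
build_mirror_basis <- function(zernike, coupling_strength = 0.1, seed = 1) {
  if (coupling_strength < 0 || coupling_strength >= 0.5)
    stop("coupling_strength must lie in [0, 0.5)")
  k <- zernike$n_modes
  if (coupling_strength == 0) {
    optics_like <- list(support = zernike$support,
                        pupil_grid = zernike$pupil_grid)
    return(new_basis(zernike$M, optics_like, wyant = zernike$wyant,
                     names = zernike$mode_names, coupling = diag(k)))
  }
  C <- diag(k)
  if (coupling_strength > 0 && k > 1) {
    rng <- with_preserved_seed(seed, matrix(stats::runif(k * k, -1, 1), k, k))
    off <- rng * coupling_strength / sqrt(k - 1)
    diag(off) <- 0
    C <- C + off
  }
  M <- zernike$M %*% C
  nrm <- sqrt(colMeans(M^2))
  M <- sweep(M, 2, nrm, "/")
  C <- sweep(C, 2, nrm, "/")
  optics_like <- list(support = zernike$support,
                      pupil_grid = zernike$pupil_grid)
  b <- new_basis(M, optics_like, wyant = zernike$wyant,
                 names = zernike$mode_names, coupling = C)
  b
}

#' Compose a wavefront from mode coefficients
#'
#' `phase = sum_k c_k * mode_k` on the pupil support (exactly linear in
#' the coefficients).
#'
#' @param coeffs numeric coefficient vector (radians of W_rms per unit
#'   mode).
#' @param basis [build_zernike_basis()] / [build_mirror_basis()] object.
#' @return pupil-phase matrix (radians).
#' @export
compose_wavefront <- function(coeffs, basis) {
  if (length(coeffs) != basis$n_modes)
    stop("coefficient length ", length(coeffs),
         " does not match basis with ", basis$n_modes, " modes")
  if (any(!is.finite(coeffs))) stop("coefficients must be finite")
  n <- basis$pupil_grid
  img <- matrix(0, n, n)
  img[basis$support] <- as.vector(basis$M %*% coeffs)
  img
}

#' Decompose a wavefront onto a mode basis
#'
#' Least-squares projection of a pupil-phase image onto the basis modes;
#' for an orthonormal basis this reduces to support-mean inner products.
#' `compose_wavefront(coefficients) + residual` reconstructs the input.
#'
#' @param phase pupil-phase matrix on the basis' support.
#' @param basis [build_zernike_basis()] object.
#' @return list with `coefficients`, `residual_wrms` (radians) and
#'   `residual` (full-pupil matrix).
#' @export
decompose_wavefront <- function(phase, basis) {
  v <- phase[basis$support]
  if (basis$orthonormal) {
    co <- as.vector(crossprod(basis$M, v)) / nrow(basis$M)
  } else {
    co <- as.vector(qr.coef(qr(basis$M), v))
  }
  res <- v - as.vector(basis$M %*% co)
  n <- basis$pupil_grid
  rimg <- matrix(0, n, n)
  rimg[basis$support] <- res
  list(coefficients = co, residual_wrms = sqrt(mean(res^2)),
       residual = rimg)
}

#' Scale coefficients so the composed wavefront has an exact W_rms
#'
#' For an orthonormal basis this is plain vector normalization; for a
#' coupled mirror basis the realized W_rms is computed through the basis
#' Gram matrix.
#'
#' @param direction coefficient direction (any non-zero vector).
#' @param level target W_rms (radians).
#' @param basis [build_zernike_basis()] object.
#' @return coefficient vector with `wrms(compose_wavefront(.)) == level`.
#' @export
scale_to_wrms <- function(direction, level, basis) {
  w2 <- as.numeric(crossprod(direction, basis$gram %*% direction))
  if (w2 <= 0) stop("direction has zero wavefront norm")
  direction * (level / sqrt(w2))
}
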