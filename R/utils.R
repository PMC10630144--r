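# internal helpers

# run expr under a fixed seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a child seed (< 2^31) from a base seed and a stream label;
# the Lehmer multiplier keeps every product below 2^53 so the arithmetic
# stays exact in doubles
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  x <- 1
  for (p in parts) {
    x <- (x * 16807 + as.numeric(p) + 1) %% 2147483647
    x <- (x * 16807) %% 2147483647
  }
  as.integer(x)
}

gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur of a matrix via banded multiplication
blur2d <- function(img, sigma) {
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1) / 2
  n <- nrow(img); m <- ncol(img)
  pad <- function(x, d) {
    # reflect edges
    idx <- c(pmin(pmax(seq(1 - r, d + r), 1), d))
    idx
  }
  ri <- pad(NULL, n); ci <- pad(NULL, m)
  big <- img[ri, ci]
  out <- matrix(0, n + 2 * r, m)
  for (j in seq_along(k))
    out <- out + k[j] * big[, j:(j + m - 1)]
  res <- matrix(0, n, m)
  for (j in seq_along(k))
    res <- res + k[j] * out[j:(j + n - 1), ]
  res
}
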