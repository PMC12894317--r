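# Internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Min-max rescale to [0, 1]; a (near-)constant input maps to the zero map so
# that structure-free maps carry no signal downstream.
#' @keywords internal
#' @noRd
rescale01 <- function(x, eps = 1e-12) {
  rng <- range(x)
  if (!all(is.finite(rng))) stop("non-finite values in map")
  if (diff(rng) < eps) {
    x[] <- 0
    return(x)
  }
  (x - rng[1]) / diff(rng)
}

# Sampled Gaussian and its first/second derivatives on integer taps.
# Order 0 is normalized to unit sum; derivative kernels share that
# normalization factor so responses stay consistent across orders.
#' @keywords internal
#' @noRd
gauss_kernel <- function(sigma, order = 0L) {
  stopifnot(sigma >= 0.5, order %in% 0:2)
  r <- ceiling(3.5 * sigma)
  t <- seq(-r, r)
  g <- exp(-t^2 / (2 * sigma^2))
  norm <- sum(g)
  g <- g / norm
  switch(as.character(order),
    "0" = g,
    "1" = g * (-t / sigma^2),      # antisymmetric: zero-sum by construction
    "2" = {
      k <- g * ((t^2 - sigma^2) / sigma^4)
      k - mean(k)                  # exact zero sum: constants cannot leak
    }
  )
}

# Separable 2-D convolution with replicate boundary handling.
# kx runs along x (columns), ky along y (rows); image is indexed [y, x].
#' @keywords internal
#' @noRd
sep_convolve <- function(img, kx, ky) {
  fx <- matrix(rev(kx), nrow = 1L)   # filter2 correlates; flip for convolution
  fy <- matrix(rev(ky), ncol = 1L)
  out <- EBImage::filter2(img, fx, boundary = "replicate")
  out <- EBImage::filter2(out, fy, boundary = "replicate")
  # EBImage may return an Image object; keep plain matrices internally
  as.matrix(out)
}

# Derive a reproducible sub-seed from a master seed and a stage label.
# Keeps results below 2^31 so set.seed() accepts them.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 10007 + h) %% .Machine$integer.max)
}
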