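# Periorbital image features: ROI cropping, Hessian ridge detection for
# wrinkles, FFT-based enhancement, and 0-100 wrinkle / pigmented-spot scores.

#' Crop a periorbital region of interest from an image
#'
#' Returns the axis-aligned bounding box of the region's defining landmark
#' set, expanded by a margin and clipped to the image. Regions follow the
#' periorbital layout: `"above_inner_corner"` is bounded by the eyebrow and
#' eyelid lines (the thin-skinned area where wrinkles above the inner eye
#' corner are measured), `"under_eye"` by the eyelid and under-eye lines, and
#' `"beside_eye"` (crow's-feet area) by the lateral canthus and the
#' facial-outline points.
#'
#' @param image numeric matrix indexed `[y + 1, x + 1]`.
#' @param landmarks named list of `c(x, y)` pixel coordinates (0-based).
#' @param region one of `"beside_eye"`, `"under_eye"`, `"above_inner_corner"`.
#' @param margin margin in pixels added on every side of the landmark box.
#' @return the image patch, with attribute `bbox` = `c(x0, x1, y0, y1)`
#'   (0-based, inclusive, before clipping to the canvas) recording where it
#'   was taken from.
#' @export
crop_periorbital_roi <- function(image, landmarks, region, margin = 0) {
  bb <- region_bbox(landmarks, region)
  if (bb[2] - bb[1] <= 0 || bb[4] - bb[3] <= 0) {
    stop("degenerate (zero-area) landmark polygon for region ", region)
  }
  bb <- bb + c(-margin, margin, -margin, margin)
  x0 <- max(0L, floor(bb[1]))
  x1 <- min(ncol(image) - 1L, ceiling(bb[2]))
  y0 <- max(0L, floor(bb[3]))
  y1 <- min(nrow(image) - 1L, ceiling(bb[4]))
  patch <- image[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
  attr(patch, "bbox") <- c(x0 = x0, x1 = x1, y0 = y0, y1 = y1)
  patch
}

#' Convert an image patch to grayscale
#'
#' Three-channel input is reduced with the standard Rec. 601 luminance
#' weights (0.299 R + 0.587 G + 0.114 B); single-channel input is returned
#' unchanged. Values stay on the input's intensity scale.
#'
#' @param patch numeric matrix, or `h x w x 3` array.
#' @return numeric matrix.
#' @export
to_grayscale <- function(patch) {
  if (length(patch) == 0) stop("empty patch")
  if (is.matrix(patch)) return(patch)
  if (length(dim(patch)) == 3 && dim(patch)[3] == 3) {
    return(0.299 * patch[, , 1] + 0.587 * patch[, , 2] + 0.114 * patch[, , 3])
  }
  stop("patch must be a matrix or an h x w x 3 array")
}

#' Ridge-detector parameters
#'
#' @param scales Gaussian smoothing scales sigma in pixels (each >= 1),
#'   sorted ascending. A wrinkle of width w is matched by sigma close to w/2.
#' @param threshold binarization threshold as a fraction of the response
#'   maximum, in (0, 1); used when turning a response map into wrinkle area.
#' @param beta blob-suppression weight of the eigenvalue-ratio term.
#' @return object of class `ridge_params`.
#' @export
ridge_params <- function(scales = c(1.5, 3), threshold = 0.2, beta = 0.5) {
  if (any(scales < 1)) stop("scales must be >= 1 px")
  if (is.unsorted(scales)) stop("scales must be sorted ascending")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  structure(list(scales = as.numeric(scales), threshold = as.numeric(threshold),
                 beta = as.numeric(beta)),
            class = "ridge_params")
}

#' Multi-scale Hessian ridge response for dark curvilinear structure
#'
#' For each smoothing scale sigma, the image is convolved with
#' derivative-of-Gaussian kernels to obtain the scale-normalized Hessian
#' (second derivatives multiplied by sigma^2), whose eigenvalues
#' `|lambda1| <= |lambda2|` classify local structure: a dark ridge (intensity
#' valley, as a wrinkle furrow) has `lambda2 > 0` large and `|lambda1|`
#' small. The response combines a blob-suppression term
#' `exp(-(lambda1/lambda2)^2 / (2 beta^2))` with a structure-magnitude term
#' `1 - exp(-S^2 / (2 c^2))`, where `S` is the Hessian Frobenius norm and
#' `c` is half its per-scale maximum; bright-ridge and blob-sign pixels are
#' zeroed. The final map is the pixel-wise maximum over scales, min-max
#' rescaled to `[0, 1]`. A constant image yields an identically zero map.
#'
#' @param gray numeric matrix (grayscale patch).
#' @param params a [ridge_params()].
#' @return response matrix in `[0, 1]`, same shape as `gray`.
#' @export
hessian_ridge_response <- function(gray, params = ridge_params()) {
  stopifnot(is.matrix(gray), inherits(params, "ridge_params"))
  smax <- max(params$scales)
  if (nrow(gray) < 2 * smax || ncol(gray) < 2 * smax) {
    stop("patch smaller than the kernel support of the largest scale")
  }
  out <- matrix(0, nrow(gray), ncol(gray))
  for (sg in params$scales) {
    g0 <- gauss_kernel(sg, 0L)
    g1 <- gauss_kernel(sg, 1L)
    g2 <- gauss_kernel(sg, 2L)
    Lxx <- sg^2 * sep_convolve(gray, g2, g0)
    Lyy <- sg^2 * sep_convolve(gray, g0, g2)
    Lxy <- sg^2 * sep_convolve(gray, g1, g1)
    half_diff <- sqrt(((Lxx - Lyy) / 2)^2 + Lxy^2)
    mean_l <- (Lxx + Lyy) / 2
    e_hi <- mean_l + half_diff
    e_lo <- mean_l - half_diff
    swap <- abs(e_lo) > abs(e_hi)
    l2 <- ifelse(swap, e_lo, e_hi)   # larger magnitude
    l1 <- ifelse(swap, e_hi, e_lo)
    S2 <- Lxx^2 + 2 * Lxy^2 + Lyy^2
    c2 <- (0.5 * sqrt(max(S2)))^2
    if (c2 < 1e-12) next             # structureless at this scale
    rb2 <- ifelse(abs(l2) > 1e-12, (l1 / l2)^2, 0)
    resp <- exp(-rb2 / (2 * params$beta^2)) * (1 - exp(-S2 / (2 * c2)))
    resp[l2 <= 0] <- 0               # keep dark ridges only
    out <- pmax(out, resp)
  }
  if (max(out) > 0) out <- out / max(out)
  out
}

#' Frequency-band parameters for wrinkle enhancement
#'
#' @param wavelengths length-2 range of retained spatial wavelengths in
#'   pixels (lower < upper). The lower cutoff (default 2 px) removes
#'   pixel-scale speckle. The upper cutoff must exceed the wrinkle *length*
#'   scale, not just its width: a coherent furrow carries envelope energy at
#'   long wavelengths along its axis, and cutting harmonics near the patch
#'   scale spreads broad halo artifacts over the map. Because the ridge
#'   response entering this step is already background-free, the default
#'   (128 px) deliberately sits above typical patch sizes, leaving
#'   low-frequency suppression off and the noise removal to the gate.
#' @param percentile magnitude-percentile gate in `[0, 1)`: in-band non-DC
#'   Fourier coefficients whose magnitude falls below this percentile of the
#'   in-band magnitudes are zeroed. This gate carries most of the noise
#'   suppression: coherent ridge energy concentrates in few strong
#'   coefficients while speckle spreads thinly, so the default keeps the top
#'   decile.
#' @return object of class `fft_band`.
#' @export
fft_band <- function(wavelengths = c(2, 128), percentile = 0.9) {
  if (length(wavelengths) != 2 || wavelengths[1] >= wavelengths[2]) {
    stop("band lower wavelength must be strictly below the upper")
  }
  if (wavelengths[1] <= 0) stop("wavelengths must be positive")
  if (percentile < 0 || percentile >= 1) stop("percentile must be in [0, 1)")
  structure(list(wavelengths = as.numeric(wavelengths),
                 percentile = as.numeric(percentile)),
            class = "fft_band")
}

#' FFT-based enhancement of a ridge-response map
#'
#' Amplifies the dominant periodic structure and suppresses noise: the map is
#' Fourier transformed, coefficients outside the configured radial frequency
#' band are zeroed, in-band coefficients below the magnitude-percentile gate
#' are zeroed, and the map is inverse transformed. The DC coefficient (mean
#' level) is always retained. The result is clipped to be non-negative and
#' min-max rescaled to `[0, 1]`; a constant result rescales to the zero map.
#'
#' @param map real-valued matrix.
#' @param band an [fft_band()].
#' @return enhanced matrix in `[0, 1]`, same shape.
#' @export
fft_enhance <- function(map, band = fft_band()) {
  stopifnot(is.matrix(map))
  if (!inherits(band, "fft_band")) stop("band must be an fft_band object")
  h <- nrow(map)
  w <- ncol(map)
  F <- stats::fft(map)
  fy <- (seq_len(h) - 1) / h
  fy <- ifelse(fy > 0.5, fy - 1, fy)
  fx <- (seq_len(w) - 1) / w
  fx <- ifelse(fx > 0.5, fx - 1, fx)
  rad <- sqrt(outer(fy^2, fx^2, "+"))
  keep <- rad >= 1 / band$wavelengths[2] & rad <= 1 / band$wavelengths[1]
  keep[1, 1] <- TRUE                       # retain the mean level
  F[!keep] <- 0
  inband <- keep
  inband[1, 1] <- FALSE
  if (any(inband) && band$percentile > 0) {
    mags <- Mod(F[inband])
    thr <- stats::quantile(mags, band$percentile, names = FALSE)
    weak <- inband & Mod(F) < thr
    F[weak] <- 0
  }
  out <- Re(stats::fft(F, inverse = TRUE)) / length(F)
  out[out < 0] <- 0
  rescale01(out)
}

#' Score calibration for raw area fractions
#'
#' Holds the reference bounds that map a raw structure-area fraction onto the
#' 0-100 reporting scale, together with a provenance tag naming the cohort
#' that produced them.
#'
#' @param lower,upper reference bounds on the raw-fraction scale
#'   (`lower < upper`).
#' @param kind `"wrinkle"` or `"spot"`.
#' @param region region the bounds apply to.
#' @param provenance free-text tag naming the calibration cohort.
#' @return object of class `score_calibration`.
#' @export
score_calibration <- function(lower, upper, kind = "wrinkle",
                              region = "beside_eye", provenance = "unspecified") {
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper) {
    stop("calibration requires finite bounds with lower < upper")
  }
  structure(list(lower = lower, upper = upper, kind = kind,
                 region = region, provenance = provenance),
            class = "score_calibration")
}

#' @keywords internal
#' @noRd
check_calibration <- function(calibration, kind) {
  if (!inherits(calibration, "score_calibration")) {
    stop("missing ", kind, " calibration: run calibrate_scores() first, ",
         "or construct bounds with score_calibration()")
  }
  calibration
}

# Affine map of a raw fraction from [lower, upper] onto [0, 100], clipped.
#' @keywords internal
#' @noRd
apply_calibration <- function(raw, calibration) {
  clamp((raw - calibration$lower) / (calibration$upper - calibration$lower) * 100,
        0, 100)
}

#' Raw wrinkle-area fraction of an enhanced response map
#'
#' Fraction of pixels whose enhanced response exceeds a fixed fraction of the
#' map maximum (an all-zero map has raw fraction 0).
#'
#' @param enhanced matrix in `[0, 1]`.
#' @param threshold binarization threshold as a fraction of the map maximum.
#' @return scalar raw fraction in `[0, 1]`.
#' @export
wrinkle_raw_fraction <- function(enhanced, threshold = 0.2) {
  m <- max(enhanced)
  if (m <= 0) return(0)
  mean(enhanced > threshold * m)
}

#' Wrinkle score on the 0-100 scale
#'
#' The area detected as wrinkles (raw fraction of above-threshold pixels in
#' the enhanced map) is mapped affinely from the calibration bounds onto
#' `[0, 100]` and clipped.
#'
#' @param enhanced enhanced response map from [fft_enhance()].
#' @param calibration a [score_calibration()] of kind `"wrinkle"`.
#' @param threshold binarization threshold (fraction of map maximum).
#' @return score in `[0, 100]`.
#' @export
wrinkle_score <- function(enhanced, calibration, threshold = 0.2) {
  calibration <- check_calibration(calibration, "wrinkle")
  apply_calibration(wrinkle_raw_fraction(enhanced, threshold), calibration)
}

#' Detect pigmented-spot pixels in a patch
#'
#' Estimates the background skin tone by large-kernel Gaussian smoothing,
#' marks pixels darker than the background by more than a contrast threshold,
#' and keeps connected components whose equivalent radius lies in a
#' blob-plausible range with a bounded elongation.
#'
#' @param patch grayscale or color patch on the 0-255 scale.
#' @param contrast minimum darkening below background, intensity units.
#' @param radius_range length-2 range of admissible equivalent radii (px).
#' @param background_sigma sigma of the background-estimation smoother (px).
#' @param max_aspect maximum bounding-box aspect ratio of a kept component.
#' @return logical matrix marking detected spot pixels.
#' @export
detect_spots <- function(patch, contrast = 15, radius_range = c(1.5, 8),
                         background_sigma = 12, max_aspect = 3) {
  gray <- to_grayscale(patch)
  # keep the smoothing kernel inside the patch
  background_sigma <- max(1, min(background_sigma, (min(dim(gray)) - 1) / 7))
  g <- gauss_kernel(background_sigma, 0L)
  bg <- sep_convolve(gray, g, g)
  dark <- (bg - gray) > contrast
  if (!any(dark)) return(dark)
  lab <- EBImage::bwlabel(dark * 1)
  lab <- as.matrix(lab)
  keep <- dark & FALSE
  amin <- pi * radius_range[1]^2
  amax <- pi * radius_range[2]^2
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k, arr.ind = TRUE)
    area <- nrow(idx)
    if (area < amin || area > amax) next
    spanr <- diff(range(idx[, 1])) + 1
    spanc <- diff(range(idx[, 2])) + 1
    if (max(spanr, spanc) / min(spanr, spanc) > max_aspect) next
    keep[idx] <- TRUE
  }
  keep
}

#' Pigmented-spot score on the 0-100 scale
#'
#' Blob-area fraction from [detect_spots()], calibrated onto `[0, 100]` as in
#' [wrinkle_score()]. This scorer stands in for device-measured spot indices:
#' it reproduces their interface (a 0-100 area-based severity score), not any
#' proprietary algorithm.
#'
#' @param patch grayscale or color patch on the 0-255 scale.
#' @param calibration a [score_calibration()] of kind `"spot"`.
#' @param ... passed to [detect_spots()].
#' @return score in `[0, 100]`.
#' @export
spot_score <- function(patch, calibration, ...) {
  calibration <- check_calibration(calibration, "spot")
  apply_calibration(mean(detect_spots(patch, ...)), calibration)
}

#' Calibrate score bounds from a cohort of raw fractions
#'
#' Sets the lower/upper reference bounds to the 1st and 99th percentiles of
#' raw area fractions over a calibration cohort, so that subsequent scores
#' span approximately `[0, 100]` on comparable material.
#'
#' @param raw_fractions numeric vector of raw fractions, one per patch
#'   (length >= 30).
#' @param kind,region,provenance stored in the resulting calibration.
#' @param probs the two percentile probabilities used as bounds.
#' @return a [score_calibration()].
#' @export
calibrate_scores <- function(raw_fractions, kind = "wrinkle",
                             region = "beside_eye", provenance = "unspecified",
                             probs = c(0.01, 0.99)) {
  if (length(raw_fractions) < 30) {
    stop("calibration needs at least 30 patches, got ", length(raw_fractions))
  }
  b <- stats::quantile(raw_fractions, probs, names = FALSE)
  if (diff(b) < 1e-12) {
    stop("degenerate calibration: raw fractions have (near-)zero spread")
  }
  score_calibration(b[1], b[2], kind = kind, region = region,
                    provenance = provenance)
}

#' Write / read a score calibration as JSON
#'
#' Bounds are serialized with full precision so that reloaded calibrations
#' reproduce scores bit-exactly.
#'
#' @param calibration a [score_calibration()].
#' @param path file path.
#' @return `write_calibration` returns the path invisibly; `read_calibration`
#'   returns the [score_calibration()].
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "score_calibration"))
  obj <- unclass(calibration)
  obj$lower <- sprintf("%.17g", obj$lower)
  obj$upper <- sprintf("%.17g", obj$upper)
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path)
  score_calibration(as.numeric(obj$lower), as.numeric(obj$upper),
                    kind = obj$kind, region = obj$region,
                    provenance = obj$provenance)
}
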