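# Landmark-based periorbital morphology: eye droopiness (Md) and temporal
# width (Mw), plus cohort-level normalization onto the 0-100 scale.

#' Construct a validated full-face landmark set
#'
#' Holds the named 2-D points morphometry needs: medial and lateral canthus
#' per side, and facial-outline polylines per side ordered by increasing y.
#' Coordinates are pixels, origin top-left, x right, y down, 0-based; heights
#' are measured image-up, `height = image_height - y`.
#'
#' @param points named list of `c(x, y)` coordinates. Canthi are named
#'   `medial_canthus_left`, `lateral_canthus_left`, `medial_canthus_right`,
#'   `lateral_canthus_right`; outline points `outline_left_1..k` and
#'   `outline_right_1..k` (k >= 2 per side for interpolation).
#' @param image_height height in pixels of the source image.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(points, image_height) {
  stopifnot(is.list(points), length(names(points)) == length(points))
  bad <- vapply(points, function(p) length(p) != 2 || any(!is.finite(p)), TRUE)
  if (any(bad)) {
    stop("non-finite or malformed coordinates for: ",
         paste(names(points)[bad], collapse = ", "))
  }
  if (!is.finite(image_height) || image_height <= 0) {
    stop("image_height must be a positive number")
  }
  structure(list(points = points, image_height = image_height),
            class = "landmark_set")
}

#' @keywords internal
#' @noRd
lm_point <- function(lm, name) {
  p <- lm$points[[name]]
  if (is.null(p)) stop("missing landmark: ", name)
  p
}

# Outline points of one side as a matrix ordered by y.
#' @keywords internal
#' @noRd
lm_outline <- function(lm, side) {
  nms <- grep(paste0("^outline_", side, "_[0-9]+$"), names(lm$points), value = TRUE)
  if (length(nms) < 2) {
    stop("missing landmark: need >= 2 outline_", side, "_* points")
  }
  ord <- order(as.integer(sub(".*_", "", nms)))
  pts <- do.call(rbind, lm$points[nms[ord]])
  pts[order(pts[, 2]), , drop = FALSE]
}

# Interpolated outline x at a given y (image-down pixel coordinate).
#' @keywords internal
#' @noRd
outline_x_at <- function(lm, side, y) {
  pts <- lm_outline(lm, side)
  stats::approx(pts[, 2], pts[, 1], xout = y, rule = 2)$y
}

#' Eye droopiness Md
#'
#' Height difference between the medial and the lateral canthus of one eye,
#' `Md = H1 - H2`, with heights measured image-up
#' (`H = image_height - y`). `Md` is positive when the lateral (outer) canthus
#' sits lower than the medial (inner) one — i.e. when the outer eye corner
#' droops — and grows as drooping progresses.
#'
#' @param landmarks a [landmark_set()].
#' @param side `"left"` or `"right"`.
#' @return raw droopiness in pixels.
#' @export
eye_droopiness <- function(landmarks, side = c("left", "right")) {
  stopifnot(inherits(landmarks, "landmark_set"))
  side <- match.arg(side)
  med <- lm_point(landmarks, paste0("medial_canthus_", side))
  lat <- lm_point(landmarks, paste0("lateral_canthus_", side))
  h1 <- landmarks$image_height - med[2]
  h2 <- landmarks$image_height - lat[2]
  h1 - h2
}

#' Temporal width Mw
#'
#' Ratio of the summed distances from each lateral canthus to its same-side
#' facial outline (`L2 + L3`) to the facial width `L1`:
#' `Mw = (L2 + L3) / L1`. Each canthus-to-outline distance is measured
#' horizontally at the canthus height against the outline polyline
#' interpolated at that height; the facial width is the Euclidean distance
#' between the two outline points interpolated at the mid-canthus height.
#' Normalizing by facial width makes the index invariant to overall face
#' size.
#'
#' @param landmarks a [landmark_set()].
#' @return raw temporal width (dimensionless).
#' @export
temporal_width <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  lat_l <- lm_point(landmarks, "lateral_canthus_left")
  lat_r <- lm_point(landmarks, "lateral_canthus_right")
  xl <- outline_x_at(landmarks, "left", lat_l[2])
  xr <- outline_x_at(landmarks, "right", lat_r[2])
  L2 <- abs(lat_l[1] - xl)
  L3 <- abs(lat_r[1] - xr)
  ymid <- (lat_l[2] + lat_r[2]) / 2
  pl <- c(outline_x_at(landmarks, "left", ymid), ymid)
  pr <- c(outline_x_at(landmarks, "right", ymid), ymid)
  L1 <- sqrt(sum((pl - pr)^2))
  if (L1 <= 0) stop("facial width L1 is zero; outline landmarks degenerate")
  (L2 + L3) / L1
}

#' Normalize raw morphology values onto the 0-100 scale
#'
#' Affine min-max map using percentile bounds over a reference cohort of raw
#' values (1st/99th by default, which resists outliers), clipped to
#' `[0, 100]`. With `probs = c(0, 1)` the map is strictly affine and
#' preserves Pearson correlations exactly.
#'
#' @param raw numeric vector of raw index values over a cohort (length
#'   >= 30), or any vector to transform when `bounds` is supplied.
#' @param probs percentile probabilities defining the bounds.
#' @param bounds optional precomputed `c(lower, upper)`; when given, `raw`
#'   is transformed with these bounds instead of refitting them.
#' @return numeric vector of scores in `[0, 100]`, with attribute `bounds`
#'   recording the bounds used (persist them like a score calibration).
#' @export
normalize_morphology <- function(raw, probs = c(0.01, 0.99), bounds = NULL) {
  if (is.null(bounds)) {
    if (length(raw) < 30) {
      stop("normalization needs >= 30 raw values to fit bounds, got ",
           length(raw))
    }
    bounds <- stats::quantile(raw, probs, names = FALSE)
  }
  if (diff(bounds) < 1e-12) {
    stop("degenerate normalization range: bounds coincide")
  }
  out <- clamp((raw - bounds[1]) / diff(bounds) * 100, 0, 100)
  attr(out, "bounds") <- bounds
  out
}
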