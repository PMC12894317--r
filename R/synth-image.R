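#' Specification for a synthetic periorbital image patch
#'
#' Describes one synthetic eye-region image: a noisy skin-toned background on
#' which dark curvilinear wrinkles (Gaussian cross-section) and dark elliptical
#' pigmented spots are drawn at known positions, together with a set of named
#' facial landmarks (canthi, eyebrow and eyelid lines, an under-eye line and
#' facial-outline points). The generator returns the ground truth alongside the
#' image, so detectors can be scored against known structure.
#'
#' Coordinates are in pixels, origin at the top-left corner, x to the right,
#' y downward, 0-based. The image matrix is indexed `img[y + 1, x + 1]`.
#'
#' @param canvas side length in pixels of the square canvas (>= 128).
#' @param base_intensity background skin intensity on the 0-255 scale.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param n_wrinkles number of wrinkles to draw (>= 0).
#' @param wrinkle_depth peak darkening of a wrinkle, in intensity units.
#' @param wrinkle_width nominal wrinkle width in pixels; the intensity profile
#'   across a wrinkle is Gaussian with standard deviation `wrinkle_width / 2`,
#'   and the ground-truth mask covers pixels within `wrinkle_width / 2` of the
#'   centerline.
#' @param n_spots number of pigmented spots (>= 0).
#' @param spot_radius length-2 numeric range of spot semi-major axes (px).
#' @param spot_depth peak darkening of a spot, in intensity units.
#' @param wrinkle_region,spot_region region the structures are placed in; one
#'   of `"beside_eye"`, `"under_eye"`, `"above_inner_corner"`.
#' @param layout list of landmark-layout parameters as fractions of the canvas:
#'   `medial_canthus`, `lateral_canthus` (x, y pairs), `eyebrow_arc` (arc
#'   height), `outline_x` (x position of the facial-outline points).
#' @param seed integer seed; identical spec + seed gives a bit-identical image.
#'
#' @return an object of class `face_image_spec`.
#' @seealso [generate_periorbital_image()]
#' @export
face_image_spec <- function(canvas = 160,
                            base_intensity = 185,
                            noise_sd = 4,
                            n_wrinkles = 3,
                            wrinkle_depth = 55,
                            wrinkle_width = 3,
                            n_spots = 4,
                            spot_radius = c(2.5, 5),
                            spot_depth = 55,
                            wrinkle_region = "beside_eye",
                            spot_region = "under_eye",
                            layout = list(),
                            seed = 1L) {
  if (length(canvas) != 1L || canvas < 128) {
    stop("canvas must be a single value >= 128 pixels")
  }
  if (n_wrinkles < 0 || n_spots < 0) stop("structure counts must be >= 0")
  if (length(spot_radius) != 2L || diff(spot_radius) < 0 || spot_radius[1] <= 0) {
    stop("spot_radius must be an increasing positive range")
  }
  regions <- c("beside_eye", "under_eye", "above_inner_corner")
  wrinkle_region <- match.arg(wrinkle_region, regions)
  spot_region <- match.arg(spot_region, regions)
  lay <- utils::modifyList(list(
    medial_canthus = c(0.26, 0.55),
    lateral_canthus = c(0.54, 0.53),
    eyebrow_arc = 0.06,
    outline_x = 0.90
  ), layout)
  spec <- structure(list(
    canvas = as.integer(canvas), base_intensity = base_intensity,
    noise_sd = noise_sd, n_wrinkles = as.integer(n_wrinkles),
    wrinkle_depth = wrinkle_depth, wrinkle_width = wrinkle_width,
    n_spots = as.integer(n_spots), spot_radius = spot_radius,
    spot_depth = spot_depth, wrinkle_region = wrinkle_region,
    spot_region = spot_region, layout = lay, seed = as.integer(seed)
  ), class = "face_image_spec")
  lm <- layout_landmarks(spec)
  xy <- do.call(rbind, lm)
  if (any(xy < 0) || any(xy > canvas - 1)) {
    stop("landmark layout places points outside the canvas")
  }
  spec
}

# Landmark positions for a spec, as a named list of c(x, y), 0-based pixels.
#' @keywords internal
#' @noRd
layout_landmarks <- function(spec) {
  n <- spec$canvas
  lay <- spec$layout
  lm <- list(
    medial_canthus = lay$medial_canthus * n,
    lateral_canthus = lay$lateral_canthus * n
  )
  tx <- seq(0.24, 0.58, length.out = 5)
  for (i in 1:5) {
    lm[[paste0("eyebrow_", i)]] <-
      c(tx[i] * n, (0.42 - lay$eyebrow_arc * sin(pi * (i - 1) / 4)) * n)
  }
  ex <- seq(0.26, 0.56, length.out = 5)
  for (i in 1:5) {
    lm[[paste0("eyelid_", i)]] <-
      c(ex[i] * n, (0.60 + 0.015 * sin(pi * (i - 1) / 4)) * n)
  }
  for (i in 1:5) {
    lm[[paste0("underlid_", i)]] <- c(ex[i] * n, 0.80 * n)
  }
  oy <- c(0.35, 0.55, 0.75)
  for (i in 1:3) {
    lm[[paste0("outline_", i)]] <-
      c((lay$outline_x - 0.015 * abs(i - 2)) * n, oy[i] * n)
  }
  lm
}

# Landmark names defining each croppable periorbital region.
#' @keywords internal
#' @noRd
region_landmark_names <- function(region) {
  switch(region,
    above_inner_corner = c(paste0("eyebrow_", 1:5), paste0("eyelid_", 1:5)),
    under_eye = c(paste0("eyelid_", 1:5), paste0("underlid_", 1:5)),
    beside_eye = c("lateral_canthus", paste0("outline_", 1:3)),
    stop("unknown region: ", region)
  )
}

# Axis-aligned bbox c(x0, x1, y0, y1) of a region's defining landmarks.
#' @keywords internal
#' @noRd
region_bbox <- function(landmarks, region) {
  nms <- region_landmark_names(region)
  missing <- setdiff(nms, names(landmarks))
  if (length(missing)) {
    stop("missing landmark(s): ", paste(missing, collapse = ", "))
  }
  xy <- do.call(rbind, landmarks[nms])
  c(min(xy[, 1]), max(xy[, 1]), min(xy[, 2]), max(xy[, 2]))
}

# Sample one sinusoidal wrinkle polyline inside a bbox. Returns the analytic
# parameters plus dense sample points (m x 2, columns x/y, 0-based).
# Base heights use six fixed slots (recycled), so under one seed the first k
# curves are identical whatever the requested count: fixture families with
# increasing counts share geometry, which monotonicity oracles rely on.
#' @keywords internal
#' @noRd
sample_wrinkle_curve <- function(bbox, idx, width) {
  w <- bbox[2] - bbox[1]
  h <- bbox[4] - bbox[3]
  pad <- max(4, 2 * width)
  x0 <- bbox[1] + pad + stats::runif(1, 0, 0.1 * w)
  len <- (0.55 + stats::runif(1, 0, 0.2)) * (w - 2 * pad)
  slot <- ((idx - 1) %% 6 + 0.5) / 6
  y0 <- bbox[3] + pad + slot * (h - 2 * pad) +
    stats::runif(1, -0.03, 0.03) * h
  slope <- stats::runif(1, -0.15, 0.15)
  amp <- stats::runif(1, 1, 2.5)
  freq <- stats::runif(1, 1, 2)          # full sine periods along the curve
  phase <- stats::runif(1, 0, 2 * pi)
  params <- list(x0 = x0, y0 = y0, len = len, slope = slope,
                 amp = amp, freq = freq, phase = phase)
  list(params = params, points = wrinkle_curve_points(params))
}

# Dense analytic sampling of a wrinkle polyline from its parameters.
#' @keywords internal
#' @noRd
wrinkle_curve_points <- function(p, n = NULL) {
  if (is.null(n)) n <- max(50L, ceiling(4 * p$len))
  t <- seq(0, 1, length.out = n)
  cbind(x = p$x0 + t * p$len,
        y = p$y0 + t * p$len * p$slope + p$amp * sin(2 * pi * p$freq * t + p$phase))
}

# Stamp structure intensity and masks for a set of curve samples.
# Works on a local window around the curve for speed.
#' @keywords internal
#' @noRd
stamp_curve <- function(img, mask, pts, depth, width) {
  n <- nrow(img)
  sd <- width / 2
  reach <- ceiling(3 * sd)
  xr <- clamp(c(floor(min(pts[, 1])) - reach, ceiling(max(pts[, 1])) + reach), 0, n - 1)
  yr <- clamp(c(floor(min(pts[, 2])) - reach, ceiling(max(pts[, 2])) + reach), 0, n - 1)
  px <- xr[1]:xr[2]
  py <- yr[1]:yr[2]
  grid <- expand.grid(y = py, x = px)
  d2 <- rep(Inf, nrow(grid))
  # min squared distance to the dense samples, chunked to bound memory
  step <- 400L
  for (s in seq(1L, nrow(pts), by = step)) {
    e <- min(s + step - 1L, nrow(pts))
    dd <- outer(grid$x, pts[s:e, 1], "-")^2 + outer(grid$y, pts[s:e, 2], "-")^2
    d2 <- pmin(d2, do.call(pmin, as.data.frame(dd)))
  }
  ij <- cbind(grid$y + 1L, grid$x + 1L)
  img[ij] <- img[ij] - depth * exp(-d2 / (2 * sd^2))
  mask[ij[d2 <= (width / 2)^2, , drop = FALSE]] <- 1L
  list(img = img, mask = mask)
}

#' Generate a synthetic periorbital image with ground truth
#'
#' Renders the image described by a [face_image_spec()]: wrinkles are
#' sinusoidal polylines darkened with a Gaussian cross-section, pigmented
#' spots are soft-edged dark ellipses, both placed inside the configured
#' landmark-defined regions on a noisy background. The return value carries
#' the true structure masks and landmark coordinates, which downstream tests
#' use as detection oracles.
#'
#' @param spec a [face_image_spec()].
#' @return a list of class `periorbital_image` with elements
#'   \describe{
#'     \item{image}{numeric matrix in `[0, 255]`, indexed `[y + 1, x + 1]`.}
#'     \item{landmarks}{named list of `c(x, y)` pixel coordinates (0-based).}
#'     \item{truth}{list with `wrinkle_mask` and `spot_mask` (0/1 integer
#'       matrices the same shape as the image), `wrinkle_curves` (analytic
#'       curve parameters and sample points), `spots` (ellipse parameters),
#'       and the regions the structures were placed in.}
#'   }
#' @export
generate_periorbital_image <- function(spec) {
  stopifnot(inherits(spec, "face_image_spec"))
  n <- spec$canvas
  landmarks <- layout_landmarks(spec)

  wb <- region_bbox(landmarks, spec$wrinkle_region)
  sb <- region_bbox(landmarks, spec$spot_region)
  if (spec$n_wrinkles > 0) {
    pad <- max(4, 2 * spec$wrinkle_width)
    if (wb[2] - wb[1] < 4 * pad || wb[4] - wb[3] < 2 * pad + spec$n_wrinkles) {
      stop("canvas too small to place the requested wrinkles in region ",
           spec$wrinkle_region)
    }
  }
  if (spec$n_spots > 0 &&
      (sb[2] - sb[1] < 6 * spec$spot_radius[2] ||
       sb[4] - sb[3] < 4 * spec$spot_radius[2])) {
    stop("canvas too small to place the requested spots in region ",
         spec$spot_region)
  }

  set.seed(spec$seed)
  img <- matrix(spec$base_intensity, n, n) +
    matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n)
  wmask <- matrix(0L, n, n)
  smask <- matrix(0L, n, n)

  curves <- list()
  if (spec$n_wrinkles > 0) {
    for (i in seq_len(spec$n_wrinkles)) {
      cv <- sample_wrinkle_curve(wb, i, spec$wrinkle_width)
      st <- stamp_curve(img, wmask, cv$points, spec$wrinkle_depth, spec$wrinkle_width)
      img <- st$img
      wmask <- st$mask
      curves[[i]] <- cv
    }
  }

  spots <- list()
  if (spec$n_spots > 0) {
    rpad <- 2 * spec$spot_radius[2]
    for (i in seq_len(spec$n_spots)) {
      cx <- stats::runif(1, sb[1] + rpad, sb[2] - rpad)
      cy <- stats::runif(1, sb[3] + rpad, sb[4] - rpad)
      a <- stats::runif(1, spec$spot_radius[1], spec$spot_radius[2])
      b <- a * stats::runif(1, 0.7, 1)
      th <- stats::runif(1, 0, pi)
      reach <- ceiling(a) + 2L
      px <- clamp(floor(cx) - reach, 0, n - 1):clamp(ceiling(cx) + reach, 0, n - 1)
      py <- clamp(floor(cy) - reach, 0, n - 1):clamp(ceiling(cy) + reach, 0, n - 1)
      grid <- expand.grid(y = py, x = px)
      dx <- grid$x - cx
      dy <- grid$y - cy
      u <- (dx * cos(th) + dy * sin(th)) / a
      v <- (-dx * sin(th) + dy * cos(th)) / b
      rho2 <- u^2 + v^2
      ij <- cbind(grid$y + 1L, grid$x + 1L)
      img[ij] <- img[ij] - spec$spot_depth * exp(-rho2^2)
      smask[ij[rho2 <= 1, , drop = FALSE]] <- 1L
      spots[[i]] <- list(cx = cx, cy = cy, a = a, b = b, theta = th)
    }
  }

  structure(list(
    image = clamp(img, 0, 255),
    landmarks = landmarks,
    truth = list(
      wrinkle_mask = wmask, spot_mask = smask,
      wrinkle_curves = curves, spots = spots,
      wrinkle_region = spec$wrinkle_region, spot_region = spec$spot_region
    ),
    spec = spec
  ), class = "periorbital_image")
}

#' Write a synthetic image, its landmarks and ground-truth masks to disk
#'
#' The image and masks are written as PNG, the landmarks as a JSON object
#' mapping point names to `[x, y]` pixel coordinates.
#'
#' @param x a `periorbital_image` from [generate_periorbital_image()].
#' @param dir output directory (created if absent).
#' @param stem file-name stem.
#' @return invisibly, the paths written.
#' @export
save_periorbital_image <- function(x, dir, stem = "patch") {
  stopifnot(inherits(x, "periorbital_image"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(stem, c(".png", "_landmarks.json",
                                         "_wrinkle_mask.png", "_spot_mask.png")))
  png::writePNG(x$image / 255, paths[1])
  jsonlite::write_json(lapply(x$landmarks, unname), paths[2], digits = NA)
  png::writePNG(x$truth$wrinkle_mask + 0, paths[3])   # integer -> real for PNG
  png::writePNG(x$truth$spot_mask + 0, paths[4])
  invisible(paths)
}
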