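test_that("ROI crop is the landmark bounding box and records provenance", {
  img <- matrix(seq_len(120 * 120), 120, 120)
  lms <- c(
    lapply(setNames(seq(30, 90, length.out = 5), paste0("eyebrow_", 1:5)),
           function(x) c(x, 40 + (x - 30) / 6)),            # y in [40, 50]
    lapply(setNames(seq(30, 90, length.out = 5), paste0("eyelid_", 1:5)),
           function(x) c(x, 60 + (x - 30) / 12))            # y in [60, 65]
  )
  patch <- crop_periorbital_roi(img, lms, "above_inner_corner", margin = 0)
  expect_equal(unname(attr(patch, "bbox")), c(30, 90, 40, 65))
  expect_equal(dim(patch), c(26, 61))

  # translation equivariance: same content, shifted box
  lms2 <- lapply(lms, function(p) p + c(10, 10))
  patch2 <- crop_periorbital_roi(img, lms2, "above_inner_corner")
  expect_equal(unname(attr(patch2, "bbox")), c(40, 100, 50, 75))
  expect_equal(img[(50:75) + 1, (40:100) + 1], unclass(patch2),
               ignore_attr = TRUE)

  expect_error(crop_periorbital_roi(img, lms[-1], "above_inner_corner"),
               "eyebrow_1")
  degenerate <- lapply(lms, function(p) c(p[1], 50))
  degenerate <- lapply(degenerate, function(p) c(50, p[2]))
  expect_error(crop_periorbital_roi(img, degenerate, "above_inner_corner"),
               "degenerate")
})

test_that("cropped regions contain the ground-truth structure placed in them", {
  for (s in 1:5) {
    spec <- face_image_spec(n_wrinkles = 3, n_spots = 0, seed = s)
    out <- generate_periorbital_image(spec)
    patch <- crop_periorbital_roi(out$image, out$landmarks,
                                  spec$wrinkle_region, margin = 2)
    bb <- attr(patch, "bbox")
    idx <- which(out$truth$wrinkle_mask == 1, arr.ind = TRUE)
    xs <- idx[, 2] - 1
    ys <- idx[, 1] - 1
    contained <- mean(xs >= bb["x0"] & xs <= bb["x1"] &
                      ys >= bb["y0"] & ys <= bb["y1"])
    expect_gte(contained, 0.95)
  }
})

test_that("grayscale conversion follows the luminance standard", {
  g <- matrix(runif(100, 0, 255), 10, 10)
  rgb_gray <- array(rep(g, 3), dim = c(10, 10, 3))
  expect_equal(to_grayscale(rgb_gray), g)

  blackwhite <- array(0, dim = c(2, 2, 3))
  blackwhite[1, , ] <- 255
  conv <- to_grayscale(blackwhite)
  expect_equal(conv[1, ], c(255, 255))
  expect_equal(conv[2, ], c(0, 0))

  set.seed(1)
  rgb <- array(runif(3 * 64, 0, 255), dim = c(8, 8, 3))
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    oracle[i, j] <- 0.299 * rgb[i, j, 1] + 0.587 * rgb[i, j, 2] +
      0.114 * rgb[i, j, 3]
  }
  expect_equal(to_grayscale(rgb), oracle, tolerance = 1e-12)

  expect_error(to_grayscale(matrix(numeric(0), 0, 0)), "empty")
})

test_that("ridge response vanishes on constant images and is shift-invariant", {
  flat <- matrix(57.3, 48, 48)
  expect_equal(max(hessian_ridge_response(flat, ridge_params())), 0)

  img <- make_line_image(n = 48)
  r1 <- hessian_ridge_response(img, ridge_params(scales = 1.5))
  r2 <- hessian_ridge_response(img + 40, ridge_params(scales = 1.5))
  expect_equal(r1, r2, tolerance = 1e-10)

  expect_error(hessian_ridge_response(matrix(0, 4, 4),
                                      ridge_params(scales = c(3))),
               "kernel support")
  expect_error(ridge_params(scales = c(3, 1)), "ascending")
  expect_error(ridge_params(threshold = 1.2), "threshold")
})

test_that("ridge response localizes straight and oblique lines", {
  y0 <- 23.4
  img <- make_line_image(n = 64, y0 = y0, sd = 1.5)
  resp <- hessian_ridge_response(img, ridge_params(scales = 1.5))
  centers <- apply(resp[, 9:56], 2, which.max) - 1
  expect_gte(mean(abs(centers - y0) <= 1), 0.95)

  # 45-degree line; perpendicular error within 1 px
  img45 <- make_line_image(n = 80, y0 = 8.3, slope = 1, sd = 1.5)
  resp45 <- hessian_ridge_response(img45, ridge_params(scales = 1.5))
  errs <- vapply(8:60, function(x) {
    abs((which.max(resp45[, x + 1]) - 1) - (8.3 + x)) / sqrt(2)
  }, numeric(1))
  expect_gte(mean(errs <= 1), 0.95)
})

test_that("FFT enhancement preserves in-band structure and kills stop-band noise", {
  n <- 64
  phase <- outer(rep(1, n), 0:(n - 1))
  sine <- 0.5 + 0.4 * sin(2 * pi * 8 * phase / n)   # wavelength 8 px
  enh <- fft_enhance(sine, fft_band())
  expect_equal(enh, (sine - min(sine)) / diff(range(sine)), tolerance = 1e-6)

  checker <- outer(0:(n - 1), 0:(n - 1), function(i, j) (i + j) %% 2)
  out <- fft_enhance(checker, fft_band(c(3, 64)))   # wavelength-2 noise excluded
  expect_lt(max(out), 1e-8)

  expect_error(fft_band(c(16, 2)), "strictly below")
  expect_error(fft_band(c(-1, 4)), "positive")
})

test_that("FFT enhancement improves overlap with the true line mask", {
  set.seed(7)
  n <- 64
  img <- make_line_image(n = n, y0 = 31.5, sd = 1.5)
  truth <- abs(row(img) - 1 - 31.5) <= 1.5
  resp <- hessian_ridge_response(img, ridge_params(scales = 1.5))
  speckle <- matrix(rbinom(n * n, 1, 0.06) * runif(n * n, 0.4, 1), n, n)
  noisy <- pmin(resp + speckle, 1)
  enh <- fft_enhance(noisy, fft_band())
  expect_gt(iou_at(enh, truth), iou_at(noisy, truth))
})

test_that("scores map raw fractions onto 0-100 with hard floors and ceilings", {
  cal <- score_calibration(0.02, 0.3)
  expect_equal(wrinkle_score(matrix(0, 20, 20), cal), 0)

  # a map whose raw fraction equals the upper bound scores 100
  m <- matrix(0, 10, 10)
  m[1:30] <- 1
  expect_equal(wrinkle_raw_fraction(m), 0.3)
  expect_equal(wrinkle_score(m, cal), 100)

  expect_error(wrinkle_score(m, NULL), "calibrate_scores")
  expect_error(spot_score(matrix(100, 30, 30), "nope"), "calibrate_scores")
})

test_that("calibration fits percentile bounds, persists exactly, and rejects degenerate cohorts", {
  set.seed(3)
  raws <- runif(60, 0.05, 0.4)
  cal <- calibrate_scores(raws, provenance = "fixture cohort")
  expect_equal(cal$lower, unname(quantile(raws, 0.01)))
  expect_equal(cal$upper, unname(quantile(raws, 0.99)))

  # scoring the calibration cohort spans ~[0, 100]
  scores <- vapply(raws, function(r) {
    m <- matrix(0, 10, 10)
    m[seq_len(round(100 * r))] <- 1
    wrinkle_score(m, cal)
  }, numeric(1))
  expect_lt(min(scores), 5)
  expect_gt(max(scores), 95)

  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, path)
  cal2 <- read_calibration(path)
  expect_identical(cal2$lower, cal$lower)
  expect_identical(cal2$upper, cal$upper)

  expect_error(calibrate_scores(raws[1:10]), "at least 30")
  expect_error(calibrate_scores(rep(0.2, 50)), "degenerate")
})

test_that("spot detection recovers the true blobs and scores them monotonically", {
  spec <- face_image_spec(n_wrinkles = 0, n_spots = 6, seed = 5)
  out <- generate_periorbital_image(spec)
  det <- detect_spots(out$image)
  truth <- out$truth$spot_mask > 0
  expect_gte(sum(det & truth) / sum(det | truth), 0.5)

  cal <- score_calibration(0, 0.2, kind = "spot")
  blank <- generate_periorbital_image(
    face_image_spec(n_wrinkles = 0, n_spots = 0, seed = 6))
  expect_equal(spot_score(blank$image, cal), 0)

  scores <- vapply(c(2, 8), function(k) {
    im <- generate_periorbital_image(
      face_image_spec(n_wrinkles = 0, n_spots = k, seed = 42))
    p <- crop_periorbital_roi(im$image, im$landmarks, "under_eye", margin = 2)
    spot_score(p, cal)
  }, numeric(1))
  expect_gt(scores[2], scores[1])
})
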