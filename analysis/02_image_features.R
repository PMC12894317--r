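#!/usr/bin/env Rscript
# Stage 2: wrinkle and spot scoring on synthetic image patches.
#
# Runs the image pipeline - landmark-driven crop, grayscale, multi-scale
# Hessian dark-ridge response, FFT enhancement, area scoring - over a fixture
# family with known ground truth, calibrates the 0-100 score bounds on that
# cohort of patches, and reports how the scores track the true structure
# counts. This is the stage that stands in for a measurement device: its
# output feeds the same 0-100 interface the cohort tables use.

suppressMessages(library(periskin))

SEED <- 20260928L
dir.create("results", showWarnings = FALSE)

counts <- rep(c(1, 2, 3, 4, 5, 6), each = 6)
seeds <- SEED + seq_along(counts)

extract_one <- function(k, seed) {
  spec <- face_image_spec(n_wrinkles = k, n_spots = k, seed = seed)
  im <- generate_periorbital_image(spec)
  wp <- crop_periorbital_roi(im$image, im$landmarks, "beside_eye", margin = 2)
  enh <- fft_enhance(hessian_ridge_response(to_grayscale(wp), ridge_params()))
  sp <- crop_periorbital_roi(im$image, im$landmarks, "under_eye", margin = 2)
  c(wrinkle_raw = wrinkle_raw_fraction(enh),
    spot_raw = mean(detect_spots(sp)))
}

raw <- t(mapply(extract_one, counts, seeds))

wr_cal <- calibrate_scores(raw[, "wrinkle_raw"], kind = "wrinkle",
                           provenance = "synthetic fixture cohort")
sp_cal <- calibrate_scores(raw[, "spot_raw"], kind = "spot",
                           region = "under_eye",
                           provenance = "synthetic fixture cohort")
write_calibration(wr_cal, "results/wrinkle_calibration.json")
write_calibration(sp_cal, "results/spot_calibration.json")

rescale <- function(r, cal) {
  pmin(pmax((r - cal$lower) / (cal$upper - cal$lower) * 100, 0), 100)
}
tab <- data.frame(
  n_structures = counts,
  wrinkle_score = rescale(raw[, "wrinkle_raw"], wr_cal),
  spot_score = rescale(raw[, "spot_raw"], sp_cal)
)
write.csv(tab, "results/image_feature_scores.csv", row.names = FALSE)

by_count <- aggregate(cbind(wrinkle_score, spot_score) ~ n_structures,
                      tab, mean)
message("mean calibrated scores by true structure count:")
for (i in seq_len(nrow(by_count))) {
  message(sprintf("  %d structures: wrinkle %.1f, spot %.1f",
                  by_count$n_structures[i], by_count$wrinkle_score[i],
                  by_count$spot_score[i]))
}
message("wrinkle score / true count correlation: ",
        sprintf("%.3f", cor(tab$n_structures, tab$wrinkle_score)))
message("spot score / true count correlation: ",
        sprintf("%.3f", cor(tab$n_structures, tab$spot_score)))
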