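#!/usr/bin/env Rscript
# Stage 1: simulate the study material.
#
# Two cohorts mirror the study design: a build cohort of 2,000 women aged
# 20-69 (400 per 10-year decade) and an independent validation cohort of 515
# (103 per decade). The seven periorbital indices are generated from a single
# age factor with marginal age correlations 0.588/0.603/0.584 (wrinkles),
# 0.723/0.758 (pigmented spots) and 0.174/0.518 (morphology); disease flags
# D1-D7 follow per-disease logistic models in age. A small set of synthetic
# periorbital image patches with ground-truth wrinkles, spots and landmarks
# is written alongside for the image-feature stage.

suppressMessages(library(periskin))

SEED <- 20260928L
out_dir <- "results/simulation"

cfg <- run_config(stages = "simulate", seed = SEED, n_images = 8)
manifest <- run_pipeline(cfg, out_dir)

build <- read_cohort_csv(file.path(out_dir, "cohort_build.csv"))
val <- read_cohort_csv(file.path(out_dir, "cohort_validation.csv"))

message("build cohort: n = ", nrow(build), " (",
        paste(table(floor(build$age / 10)), collapse = "/"), " per decade)")
message("validation cohort: n = ", nrow(val))
message("achieved feature-age correlations (targets in parentheses):")
targets <- default_feature_correlations()
for (f in names(targets)) {
  message(sprintf("  %s: %.3f (%.3f)", f, cor(build[[f]], build$age),
                  targets[[f]]))
}
message("disease prevalence (build): ",
        paste(sprintf("%s %.1f%%", paste0("D", 1:7),
                      100 * colMeans(build[paste0("D", 1:7)])),
              collapse = ", "))
message("wrote ", length(manifest$artifacts), " artifacts to ", out_dir)
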