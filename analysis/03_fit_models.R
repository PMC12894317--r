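#!/usr/bin/env Rscript
# Stage 3: the nine age-prediction models.
#
# Fits each model's feature subset by ordinary least squares on the build
# cohort, evaluates it by 10-fold cross-validation (mean Pearson r between
# predicted and actual age over held-out folds), refits the final equation
# on the full build set, refines away negative coefficients where
# collinearity produced them (double-prime variants), and validates the
# final models on the independent cohort. The conditional-independence
# closed form sqrt(S/(1+S)), S = sum r_i^2/(1-r_i^2), gives the population
# benchmark each model's CV performance should approach.

suppressMessages(library(periskin))

SEED <- 20260928L
sim_dir <- "results/simulation"
if (!file.exists(file.path(sim_dir, "cohort_build.csv"))) {
  stop("run analysis/01_simulate.R first")
}
build <- read_cohort_csv(file.path(sim_dir, "cohort_build.csv"))
val <- read_cohort_csv(file.path(sim_dir, "cohort_validation.csv"))
targets <- default_feature_correlations()

catalog <- model_catalog()
rows <- lapply(1:9, function(m) {
  subset <- catalog[[m]]
  cv <- cross_validate(build, subset, k = 10, seed = SEED + m)
  final <- fit_age_model(build, subset, training_id = "build cohort")
  refined <- refine_model(final, build)
  data.frame(
    model = m,
    features = paste(subset, collapse = "+"),
    cv_r = cv$mean_r,
    expected_r = expected_multiple_correlation(targets, subset),
    validation_r = validate_model(refined, val),
    removed = paste(refined$removed, collapse = "+")
  )
})
perf <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(perf, "results/model_performance.csv", row.names = FALSE)

message("model performance (10-fold CV / closed-form benchmark / validation):")
for (i in 1:9) {
  message(sprintf("  model %d [%-20s] r = %.3f / %.3f / %.3f %s",
                  perf$model[i], perf$features[i], perf$cv_r[i],
                  perf$expected_r[i], perf$validation_r[i],
                  if (nzchar(perf$removed[i]))
                    paste0("(refined: -", perf$removed[i], ")") else ""))
}
pig <- c(3, 5, 6, 7, 9)
message(sprintf(
  "pigmentation-bearing models (3,5,6,7,9) span r = %.3f-%.3f; models 2 and 8 reach %.3f and %.3f",
  min(perf$cv_r[pig]), max(perf$cv_r[pig]), perf$cv_r[2], perf$cv_r[8]))
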