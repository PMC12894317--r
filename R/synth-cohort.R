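#' Default feature-age correlation targets
#'
#' Target Pearson correlations between chronological age and the seven
#' periorbital aging indices used throughout the package: wrinkles beside,
#' under and above the inner corner of the eyes (Wb, Wu, Wa), pigmented spots
#' beside and under the eyes (Pb, Pu), and the two morphology indices eye
#' droopiness (Md) and temporal width (Mw). The defaults reproduce the
#' correlation structure the analysis is calibrated to: moderate for
#' wrinkles, strongest for pigmentation, weakest for droopiness.
#'
#' @return named numeric vector of length 7.
#' @export
default_feature_correlations <- function() {
  c(Wb = 0.588, Wu = 0.603, Wa = 0.584,
    Pb = 0.723, Pu = 0.758,
    Md = 0.174, Mw = 0.518)
}

#' Default disease-history model
#'
#' Per-disease logistic intercepts and slopes in age, on the scale
#' `logit P(D) = intercept + slope * (age - 45)`. Intercepts put prevalence in
#' the 2-20% range at the cohort mean age; slopes are positive for the five
#' conditions modeled as age-linked (hypertension, hyperlipidemia, fatty
#' liver, kidney disease, diabetes) and zero for heart disease and cancer,
#' which are modeled as age-independent.
#'
#' @return data.frame with columns `code`, `disease`, `intercept`, `slope`.
#' @export
default_disease_model <- function() {
  data.frame(
    code = paste0("D", 1:7),
    disease = c("heart disease", "high blood pressure", "hyperlipidemia",
                "fatty liver", "kidney disease", "diabetes", "cancer"),
    intercept = stats::qlogis(c(0.03, 0.12, 0.10, 0.10, 0.05, 0.06, 0.04)),
    slope = c(0, 0.09, 0.08, 0.06, 0.07, 0.08, 0),
    stringsAsFactors = FALSE
  )
}

#' Configuration of a synthetic study cohort
#'
#' Describes the sampling design of a cohort table: five 10-year age decades
#' spanning 20-69 years with an exact number of subjects per decade (400 for
#' the model-building design, 103 for the validation design), seven aging
#' indices generated from a single age factor with configurable marginal
#' age correlations, binary disease-history flags drawn from per-disease
#' logistic models in age, and lifestyle covariates.
#'
#' Each index is generated as `x_i = r_i * z + sqrt(1 - r_i^2) * e_i` with
#' `z` the within-cohort age z-score and `e_i` independent standard Gaussian
#' noise, then mapped affinely from +/- 4 SD of the latent scale onto
#' `[0, 100]` and clipped. Features are therefore conditionally independent
#' given age, which gives the age-model stage a closed-form multiple
#' correlation to be checked against.
#'
#' @param n_per_decade subjects per 10-year decade (build design: 400;
#'   validation design: 103).
#' @param age_range inclusive-exclusive age span covered by the decades.
#' @param correlations named feature-age correlation targets, `|r| < 1`;
#'   defaults to [default_feature_correlations()].
#' @param disease_model data.frame as [default_disease_model()].
#' @param seed integer seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_decade = 400L,
                          age_range = c(20, 70),
                          correlations = default_feature_correlations(),
                          disease_model = default_disease_model(),
                          seed = 1L) {
  if (any(abs(correlations) >= 1)) {
    stop("feature-age correlations must lie strictly inside (-1, 1)")
  }
  if (n_per_decade < 1) stop("n_per_decade must be positive")
  if (diff(age_range) <= 0 || diff(age_range) %% 10 != 0) {
    stop("age_range must span a positive whole number of decades")
  }
  feats <- c("Wb", "Wu", "Wa", "Pb", "Pu", "Md", "Mw")
  if (!all(feats %in% names(correlations))) {
    stop("correlations must be named with all of: ", paste(feats, collapse = ", "))
  }
  structure(list(
    n_per_decade = as.integer(n_per_decade),
    age_range = age_range,
    correlations = correlations[feats],
    disease_model = disease_model,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Generate a synthetic cohort table
#'
#' Draws ages uniformly within each decade (exact per-decade counts), the
#' seven aging indices from the single-age-factor model described in
#' [cohort_config()], disease-history flags D1-D7 from the configured
#' logistic models, the derived any-disease flag D0, and lifestyle covariates
#' (sun-exposure hours, sunscreen-use frequency, smoking).
#'
#' @param config a [cohort_config()].
#' @param id_prefix prefix for subject identifiers.
#' @return data.frame with one row per subject and columns `id`, `age`,
#'   `Wb`, `Wu`, `Wa`, `Pb`, `Pu`, `Md`, `Mw`, `D1`..`D7`, `D0`,
#'   `sun_hours`, `sunscreen_freq`, `smoker`.
#' @export
generate_cohort <- function(config, id_prefix = "S") {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  decades <- seq(config$age_range[1], config$age_range[2] - 10, by = 10)
  n <- config$n_per_decade * length(decades)
  age <- unlist(lapply(decades, function(d) {
    stats::runif(config$n_per_decade, d, d + 10)
  }))
  z <- as.vector(scale(age))

  feats <- names(config$correlations)
  x <- sapply(feats, function(f) {
    r <- config$correlations[[f]]
    lat <- r * z + sqrt(1 - r^2) * stats::rnorm(n)
    clamp((lat + 4) / 8 * 100, 0, 100)
  })

  dm <- config$disease_model
  d <- sapply(seq_len(nrow(dm)), function(j) {
    p <- stats::plogis(dm$intercept[j] + dm$slope[j] * (age - 45))
    stats::rbinom(n, 1L, p)
  })
  colnames(d) <- dm$code

  tab <- data.frame(
    id = sprintf("%s%04d", id_prefix, seq_len(n)),
    age = age,
    x,
    d,
    D0 = as.integer(rowSums(d) > 0),
    sun_hours = stats::rlnorm(n, log(1.5), 0.5),
    sunscreen_freq = sample(0:4, n, replace = TRUE,
                            prob = c(0.1, 0.15, 0.25, 0.3, 0.2)),
    smoker = stats::rbinom(n, 1L, 0.06),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  tab
}

#' @keywords internal
#' @noRd
feature_names <- function() c("Wb", "Wu", "Wa", "Pb", "Pu", "Md", "Mw")

#' Closed-form multiple correlation of age on a feature subset
#'
#' Under the single-age-factor generative model of [cohort_config()]
#' (features conditionally independent given age, marginal age correlations
#' `r_i`), the population multiple correlation between age and the best
#' linear combination of a feature subset is `sqrt(S / (1 + S))` with
#' `S = sum r_i^2 / (1 - r_i^2)` over the subset, by Sherman-Morrison
#' inversion of the implied equicorrelation-structure covariance. This is the
#' analytic oracle the cross-validated model performance is compared to.
#'
#' @param correlations named feature-age correlations.
#' @param subset feature names to include (default: all).
#' @return the population multiple correlation (scalar in `[0, 1)`).
#' @export
expected_multiple_correlation <- function(correlations, subset = names(correlations)) {
  r <- correlations[subset]
  if (anyNA(r)) stop("unknown feature in subset")
  S <- sum(r^2 / (1 - r^2))
  sqrt(S / (1 + S))
}
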