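# The nine linear age-prediction models over the seven periorbital indices,
# 10-fold cross-validation, negative-coefficient refinement, and validation.

#' Catalog of the nine age-prediction models
#'
#' Feature subsets of the nine linear models: models 1-3 use one index
#' category each (wrinkles, morphology, pigmented spots), models 4-6 pair
#' two categories, model 7 uses all seven indices, and models 8 and 9 drop
#' the image-pipeline wrinkle index Wa from models 1 and 5 so that they rely
#' on device-style indices only.
#'
#' @return named list `m1`..`m9` of character vectors of feature names.
#' @export
model_catalog <- function() {
  list(
    m1 = c("Wb", "Wu", "Wa"),
    m2 = c("Md", "Mw"),
    m3 = c("Pb", "Pu"),
    m4 = c("Wb", "Wu", "Wa", "Md", "Mw"),
    m5 = c("Wb", "Wu", "Wa", "Pb", "Pu"),
    m6 = c("Md", "Mw", "Pb", "Pu"),
    m7 = c("Wb", "Wu", "Wa", "Md", "Mw", "Pb", "Pu"),
    m8 = c("Wb", "Wu"),
    m9 = c("Wb", "Wu", "Pb", "Pu")
  )
}

#' @keywords internal
#' @noRd
check_cohort_features <- function(cohort, subset) {
  missing <- setdiff(c("age", subset), names(cohort))
  if (length(missing)) {
    stop("cohort lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyNA(cohort[c("age", subset)])) stop("missing values in model columns")
}

#' Fit a linear age-prediction model
#'
#' Ordinary least squares of chronological age on a subset of the seven
#' periorbital indices: `y = b0 + sum(bi * xi) + e`.
#'
#' @param cohort cohort data.frame with `age` and the feature columns.
#' @param subset character vector of feature names.
#' @param training_id identifier of the training set, kept for provenance.
#' @return object of class `age_model`: fields `subset`, `coefficients`
#'   (named, first element `(Intercept)`), `sigma` (residual SD), `refined`,
#'   `removed`, `training_id`, `n`.
#' @export
fit_age_model <- function(cohort, subset, training_id = "unspecified") {
  check_cohort_features(cohort, subset)
  if (nrow(cohort) <= length(subset) + 1) {
    stop("need more subjects than coefficients to fit")
  }
  fm <- stats::as.formula(paste("age ~", paste(subset, collapse = " + ")))
  fit <- stats::lm(fm, data = cohort)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear feature(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(
    subset = subset,
    coefficients = stats::coef(fit),
    sigma = sqrt(sum(stats::resid(fit)^2) / fit$df.residual),
    refined = FALSE,
    removed = character(0),
    training_id = training_id,
    n = nrow(cohort)
  ), class = "age_model")
}

#' Predict periorbital skin age
#'
#' Applies `y_hat = b0 + sum(bi * xi)` to new feature data. Predictions are
#' not clipped; values outside a plausible human age span trigger a warning
#' but are reported as-is.
#'
#' @param object an `age_model`.
#' @param newdata data.frame (or single named vector) containing the model's
#'   features.
#' @param ... unused.
#' @return numeric vector of predicted ages ("periorbital skin age"), years.
#' @export
predict.age_model <- function(object, newdata, ...) {
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  missing <- setdiff(object$subset, names(newdata))
  if (length(missing)) {
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  }
  X <- as.matrix(newdata[object$subset])
  yhat <- drop(object$coefficients[1] + X %*% object$coefficients[object$subset])
  if (any(yhat < 0 | yhat > 120)) {
    warning("predicted age outside [0, 120] for ",
            sum(yhat < 0 | yhat > 120), " subject(s); reported unclipped")
  }
  yhat
}

#' @export
print.age_model <- function(x, ...) {
  cat("Periorbital age model", if (x$refined) "(refined)" else "",
      "\n  features:", paste(x$subset, collapse = ", "),
      "\n  trained on:", x$training_id, sprintf("(n = %d)", x$n), "\n")
  print(round(x$coefficients, 4))
  if (length(x$removed)) cat("  removed during refinement:",
                             paste(x$removed, collapse = ", "), "\n")
  invisible(x)
}

#' K-fold cross-validated performance of a feature subset
#'
#' Randomly partitions subjects into `k` folds (seeded; optionally
#' age-decade-stratified), fits the model on `k - 1` folds and computes the
#' Pearson correlation between predicted and actual age on the held-out
#' fold, cycling through all folds. Performance is the mean per-fold
#' correlation.
#'
#' @param cohort cohort data.frame.
#' @param subset feature names.
#' @param k number of folds.
#' @param seed integer seed for the fold assignment.
#' @param stratify stratify fold assignment by 10-year age decade.
#' @details When the cohort has an `id` column, folds are assigned in id
#'   order, so the partition (and hence the result) does not depend on the
#'   row order of the table.
#' @return list of class `cv_result`: `fold_r` (length `k`), `mean_r`, `k`,
#'   `seed`, `subset`.
#' @export
cross_validate <- function(cohort, subset, k = 10, seed = 1L, stratify = FALSE) {
  check_cohort_features(cohort, subset)
  n <- nrow(cohort)
  ord <- if ("id" %in% names(cohort)) order(cohort$id) else seq_len(n)
  set.seed(seed)
  fold <- integer(n)
  if (stratify) {
    dec <- floor(cohort$age[ord] / 10)
    fs <- integer(n)
    for (d in unique(dec)) {
      idx <- which(dec == d)
      fs[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold[ord] <- fs
  } else {
    fold[ord] <- sample(rep_len(seq_len(k), n))
  }
  if (min(table(fold)) < 3) stop("a fold has fewer than 3 subjects")
  fold_r <- vapply(seq_len(k), function(f) {
    train <- cohort[fold != f, , drop = FALSE]
    test <- cohort[fold == f, , drop = FALSE]
    m <- fit_age_model(train, subset, training_id = sprintf("cv fold %d", f))
    stats::cor(suppressWarnings(predict(m, test)), test$age)
  }, numeric(1))
  structure(list(fold_r = fold_r, mean_r = mean(fold_r), k = k,
                 seed = seed, subset = subset),
            class = "cv_result")
}

#' Refine a model by removing negative-coefficient features
#'
#' Collinearity among indices that all increase with age can flip individual
#' coefficient signs. Refinement iteratively removes the feature with the
#' most negative coefficient and refits, until all coefficients are
#' non-negative, yielding the concise "double-prime" model variant. The
#' removal sequence is recorded on the returned model.
#'
#' @param model an `age_model`.
#' @param cohort the cohort to refit on.
#' @return an `age_model` with `refined = TRUE` and all slope coefficients
#'   `>= 0`; returned unchanged (except the flag) if none were negative.
#' @export
refine_model <- function(model, cohort) {
  stopifnot(inherits(model, "age_model"))
  subset <- model$subset
  removed <- character(0)
  current <- model
  repeat {
    betas <- current$coefficients[subset]
    if (all(betas >= 0)) break
    drop_feat <- names(which.min(betas))
    removed <- c(removed, drop_feat)
    subset <- setdiff(subset, drop_feat)
    if (!length(subset)) {
      stop("refinement removed every feature; model is degenerate")
    }
    current <- fit_age_model(cohort, subset, training_id = model$training_id)
  }
  current$refined <- TRUE
  current$removed <- removed
  current
}

#' Validate a fitted model on an independent cohort
#'
#' @param model an `age_model`.
#' @param validation independent cohort data.frame (n >= 10).
#' @return Pearson correlation between predicted and actual age.
#' @export
validate_model <- function(model, validation) {
  check_cohort_features(validation, model$subset)
  if (nrow(validation) < 10) stop("validation cohort too small (n < 10)")
  stats::cor(suppressWarnings(predict(model, validation)), validation$age)
}
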