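# Disease-history association analyses: logistic regression of disease flags
# on periorbital skin age (crude and covariate-adjusted), Benjamini-Hochberg
# FDR control, and PCA of the binary disease indicators.

#' Logistic association between a disease flag and a predictor
#'
#' Maximum-likelihood logistic regression of a binary disease-history flag on
#' a predictor (typically periorbital skin age or chronological age), with
#' optional adjustment covariates such as chronological age and sun-exposure
#' hours. Reports the predictor's log-odds coefficient and, by default, its
#' Wald p-value; a likelihood-ratio p-value is also available.
#'
#' @param cohort data.frame containing the disease flag, predictor and
#'   covariates.
#' @param disease name of the binary outcome column.
#' @param predictor name of the predictor column.
#' @param covariates character vector of adjustment covariate columns.
#' @param p_type `"wald"` (default) or `"lrt"`.
#' @return data.frame of class `association_result` with one row: `disease`,
#'   `predictor`, `covariates`, `beta`, `se`, `p`, `n`, `n_cases`.
#' @export
logistic_association <- function(cohort, disease, predictor,
                                 covariates = character(0),
                                 p_type = c("wald", "lrt")) {
  p_type <- match.arg(p_type)
  missing <- setdiff(c(disease, predictor, covariates), names(cohort))
  if (length(missing)) {
    stop("cohort lacks column(s): ", paste(missing, collapse = ", "))
  }
  y <- cohort[[disease]]
  if (!all(y %in% c(0, 1))) stop(disease, " is not a 0/1 flag")
  if (length(unique(y)) < 2) {
    stop("outcome ", disease, " has a single observed class; ",
         "association is not estimable")
  }
  fm <- stats::as.formula(paste(disease, "~",
                                paste(c(predictor, covariates), collapse = " + ")))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fm, data = cohort, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (sep_warn || !fit$converged || abs(stats::coef(fit)[predictor]) > 50) {
    stop("(quasi-)complete separation fitting ", disease, " ~ ", predictor,
         "; collapse sparse categories or use a penalized fit")
  }
  sm <- summary(fit)$coefficients
  beta <- sm[predictor, "Estimate"]
  se <- sm[predictor, "Std. Error"]
  p <- if (p_type == "wald") {
    sm[predictor, "Pr(>|z|)"]
  } else {
    fm0 <- stats::as.formula(paste(
      disease, "~", if (length(covariates)) paste(covariates, collapse = " + ") else "1"))
    fit0 <- stats::glm(fm0, data = cohort, family = stats::binomial())
    stats::pchisq(fit0$deviance - fit$deviance, df = 1, lower.tail = FALSE)
  }
  structure(data.frame(
    disease = disease, predictor = predictor,
    covariates = paste(covariates, collapse = "+"),
    beta = beta, se = se, p = p,
    n = nrow(cohort), n_cases = sum(y),
    stringsAsFactors = FALSE, row.names = NULL
  ), class = c("association_result", "data.frame"))
}

#' Benjamini-Hochberg FDR q-values
#'
#' Step-up false-discovery-rate adjustment over a family of p-values
#' (delegating to [stats::p.adjust()] with `method = "BH"`). Adjusted values
#' are order-preserving and equal p-values receive equal q-values.
#'
#' @param p numeric vector of p-values in `[0, 1]` (non-empty).
#' @return numeric vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) stop("empty p-value family")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' PCA of the binary disease-history indicators
#'
#' Principal component analysis of the column-standardized disease matrix
#' (correlation-matrix convention). Zero-variance columns are dropped with a
#' warning. The sign of PC1 is fixed so that its loadings sum positive,
#' making downstream correlations reproducible across platforms.
#'
#' @param diseases data.frame or matrix of 0/1 columns (the seven
#'   disease-history flags), n >= 30 rows.
#' @return list of class `disease_pca`: `loadings` (columns = components),
#'   `scores` (PC scores per subject), `explained` (variance fractions),
#'   `dropped` (names of zero-variance columns removed).
#' @export
disease_pca <- function(diseases) {
  d <- as.matrix(diseases)
  if (nrow(d) < 30) stop("PCA needs at least 30 subjects")
  if (!all(d %in% c(0, 1))) stop("disease matrix must be 0/1")
  v <- apply(d, 2, stats::var)
  dropped <- colnames(d)[v == 0]
  if (length(dropped)) {
    warning("dropping zero-variance disease column(s): ",
            paste(dropped, collapse = ", "))
    d <- d[, v > 0, drop = FALSE]
  }
  if (ncol(d) < 2) stop("need at least 2 diseases with nonzero variance")
  pc <- stats::prcomp(d, center = TRUE, scale. = TRUE)
  if (sum(pc$rotation[, 1]) < 0) {
    pc$rotation[, 1] <- -pc$rotation[, 1]
    pc$x[, 1] <- -pc$x[, 1]
  }
  structure(list(
    loadings = pc$rotation,
    scores = pc$x,
    explained = pc$sdev^2 / sum(pc$sdev^2),
    dropped = dropped
  ), class = "disease_pca")
}

#' Correlation between the first disease principal component and skin age
#'
#' @param pca a [disease_pca()].
#' @param skin_age numeric vector of periorbital skin ages, in the same
#'   subject order as the PCA input.
#' @return list: `r` (Pearson correlation), `p` (two-sided p-value).
#' @export
pc1_correlation <- function(pca, skin_age) {
  stopifnot(inherits(pca, "disease_pca"))
  if (length(skin_age) != nrow(pca$scores)) {
    stop("skin_age length (", length(skin_age),
         ") does not match the PCA subject count (", nrow(pca$scores), ")")
  }
  ct <- stats::cor.test(pca$scores[, 1], skin_age)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Full disease-association report
#'
#' For the any-disease flag D0 and each disease D1-D7, fits logistic
#' regressions of the flag on chronological age and on periorbital skin age,
#' and applies Benjamini-Hochberg FDR adjustment across the skin-age family.
#' By default the family comprises all eight rows including D0; set
#' `fdr_family = "diseases_only"` to adjust over D1-D7 only.
#'
#' @param cohort cohort data.frame with `age` and `D0`..`D7`.
#' @param skin_age periorbital skin age per subject, matching `cohort` rows.
#' @param fdr_family `"with_d0"` (default) or `"diseases_only"`.
#' @return data.frame with one row per code D0-D7: `code`, `beta_age`,
#'   `p_age`, `beta_skin`, `p_skin`, `q_skin`.
#' @export
association_table <- function(cohort, skin_age,
                              fdr_family = c("with_d0", "diseases_only")) {
  fdr_family <- match.arg(fdr_family)
  if (length(skin_age) != nrow(cohort)) {
    stop("skin_age length does not match the cohort")
  }
  codes <- paste0("D", 0:7)
  missing <- setdiff(codes, names(cohort))
  if (length(missing)) {
    stop("cohort lacks disease column(s): ", paste(missing, collapse = ", "))
  }
  dat <- cohort
  dat$.skin_age <- skin_age
  rows <- lapply(codes, function(code) {
    a <- logistic_association(dat, code, "age")
    s <- logistic_association(dat, code, ".skin_age")
    data.frame(code = code,
               beta_age = a$beta, p_age = a$p,
               beta_skin = s$beta, p_skin = s$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_skin <- NA_real_
  idx <- if (fdr_family == "with_d0") seq_len(8) else 2:8
  out$q_skin[idx] <- bh_fdr(out$p_skin[idx])
  out
}
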