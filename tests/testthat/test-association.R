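test_that("logistic association on a 2x2 table equals the hand-computed log odds ratio", {
  # predictor is binary: the fitted slope is exactly the log OR of the table
  d <- data.frame(
    x = rep(c(0, 1), times = c(120, 80)),
    D = c(rep(c(0, 1), times = c(100, 20)), rep(c(0, 1), times = c(50, 30)))
  )
  res <- logistic_association(d, "D", "x")
  lor <- log((30 * 100) / (50 * 20))
  expect_equal(res$beta, lor, tolerance = 1e-6)
  expect_equal(res$n_cases, 50)

  # Wald and LRT agree in order of magnitude here
  res_lrt <- logistic_association(d, "D", "x", p_type = "lrt")
  expect_lt(abs(log10(res$p) - log10(res_lrt$p)), 0.5)
})

test_that("logistic association rejects unusable outcomes", {
  d <- data.frame(x = rnorm(50), D = 0)
  expect_error(logistic_association(d, "D", "x"), "single observed class")
  d2 <- data.frame(x = c(rep(0, 25), rep(1, 25)), D = c(rep(0, 25), rep(1, 25)))
  expect_error(logistic_association(d2, "D", "x"), "separation")
  d3 <- data.frame(x = rnorm(20), D = sample(c(0.5, 1), 20, TRUE))
  expect_error(logistic_association(d3, "D", "x"), "0/1")
  expect_error(logistic_association(d2, "D", "missing_col"), "missing_col")
})

test_that("known logistic slopes are recovered within their confidence intervals", {
  hits <- vapply(1:100, function(s) {
    set.seed(900 + s)
    n <- 515
    skin <- runif(n, 20, 70)
    d <- data.frame(skin = skin,
                    D = rbinom(n, 1, plogis(-3.5 + 0.05 * (skin - 45))))
    if (length(unique(d$D)) < 2) return(NA)
    res <- logistic_association(d, "D", "skin")
    res$beta - 1.96 * res$se <= 0.05 && 0.05 <= res$beta + 1.96 * res$se
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.90)
})

test_that("age adjustment attenuates an association mediated by age alone", {
  set.seed(77)
  n <- 2000
  age <- runif(n, 20, 70)
  skin <- age + rnorm(n, 0, 5)          # skin age tracks age
  d <- data.frame(age = age, skin = skin,
                  D = rbinom(n, 1, plogis(-4 + 0.08 * (age - 45))))
  crude <- logistic_association(d, "D", "skin")
  adjusted <- logistic_association(d, "D", "skin", covariates = "age")
  expect_gt(crude$beta, 0)
  expect_lt(abs(adjusted$beta), abs(crude$beta) / 2)
})

test_that("BH q-values match the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)                # single test
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))  # ties share a q

  set.seed(11)
  for (m in c(2, 5, 8, 13, 20)) {
    p <- runif(m)^2
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("disease PCA follows the correlation-matrix eigenstructure", {
  set.seed(21)
  n <- 400
  latent <- rnorm(n)
  D <- sapply(1:7, function(j) rbinom(n, 1, plogis(-1.5 + 1.2 * latent)))
  colnames(D) <- paste0("D", 1:7)
  pca <- disease_pca(D)

  # one shared factor: all PC1 loadings same sign (positive by convention)
  expect_true(all(pca$loadings[, 1] > 0))

  # oracle: eigendecomposition of the correlation matrix
  ev <- eigen(cor(D), symmetric = TRUE)
  v1 <- ev$vectors[, 1] * sign(sum(ev$vectors[, 1]))
  expect_equal(abs(pca$loadings[, 1]), abs(v1), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(pca$explained, ev$values / sum(ev$values), tolerance = 1e-8)

  # rank-1 case: two identical diseases, the rest constant
  D2 <- cbind(a = rep(c(0, 1), 20), b = rep(c(0, 1), 20),
              c = 0, d = 0, e = 0, f = 0, g = 0)
  expect_warning(p2 <- disease_pca(D2), "zero-variance")
  expect_equal(p2$explained[1], 1, tolerance = 1e-12)
  expect_setequal(p2$dropped, c("c", "d", "e", "f", "g"))

  expect_error(disease_pca(matrix(0, 40, 7)), "zero")
  expect_error(disease_pca(D[1:10, ]), "30")
})

test_that("PC1 correlation matches a direct computation and handles the null", {
  set.seed(9)
  n <- 515
  D <- sapply(1:7, function(j) rbinom(n, 1, 0.15))
  colnames(D) <- paste0("D", 1:7)
  pca <- disease_pca(D)

  res <- pc1_correlation(pca, pca$scores[, 1])
  expect_equal(res$r, 1, tolerance = 1e-12)

  skin <- rnorm(n)   # independent of the diseases
  res0 <- pc1_correlation(pca, skin)
  expect_lt(abs(res0$r), 0.1)
  # brute-force covariance / sd formula
  s1 <- pca$scores[, 1]
  r_manual <- mean((s1 - mean(s1)) * (skin - mean(skin))) /
    (sqrt(mean((s1 - mean(s1))^2)) * sqrt(mean((skin - mean(skin))^2)))
  expect_equal(res0$r, r_manual, tolerance = 1e-12)

  expect_error(pc1_correlation(pca, skin[-1]), "does not match")
})

test_that("the association table has the eight published rows and a coherent FDR family", {
  build <- generate_cohort(cohort_config(seed = 61))
  val <- generate_cohort(cohort_config(n_per_decade = 103, seed = 62))
  m7 <- refine_model(fit_age_model(build, model_catalog()$m7), build)
  skin <- suppressWarnings(predict(m7, val))

  tab <- association_table(val, skin)
  expect_equal(nrow(tab), 8)
  expect_equal(tab$code, paste0("D", 0:7))
  expect_true(all(tab$q_skin >= tab$p_skin - 1e-12))
  expect_equal(bh_oracle(tab$p_skin), tab$q_skin, tolerance = 1e-12)

  tab2 <- association_table(val, skin, fdr_family = "diseases_only")
  expect_true(is.na(tab2$q_skin[1]))
  expect_equal(bh_oracle(tab2$p_skin[2:8]), tab2$q_skin[2:8], tolerance = 1e-12)

  expect_error(association_table(val, skin[-1]), "does not match")
})
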