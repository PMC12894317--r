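test_that("the model catalog matches the nine published feature subsets", {
  cat9 <- model_catalog()
  expect_length(cat9, 9)
  expect_equal(cat9$m3, c("Pb", "Pu"))
  expect_length(cat9$m7, 7)
  expect_equal(cat9$m8, setdiff(cat9$m1, "Wa"))
  expect_equal(cat9$m9, setdiff(cat9$m5, "Wa"))
  expect_equal(cat9$m2, c("Md", "Mw"))
})

test_that("OLS fit recovers exact linear structure and matches the normal equations", {
  co <- noiseless_cohort()
  co$age <- 30 + 0.2 * co$Pu
  m <- fit_age_model(co, "Pu")
  expect_equal(unname(m$coefficients), c(30, 0.2), tolerance = 1e-8)

  build <- generate_cohort(cohort_config(n_per_decade = 60, seed = 14))
  for (subset in model_catalog()) {
    m <- fit_age_model(build, subset)
    oracle <- ols_oracle(build[subset], build$age)
    expect_equal(unname(m$coefficients), unname(oracle), tolerance = 1e-8)
  }

  co$Pu2 <- co$Pu
  expect_error(fit_age_model(co, c("Pu", "Pu2")), "collinear.*Pu2")
  expect_error(fit_age_model(co[1:2, ], "Pu"), "more subjects")
  expect_error(fit_age_model(co, c("Pu", "nope")), "nope")
})

test_that("fitted betas fall inside their own confidence intervals at the nominal rate", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 150
    d <- data.frame(Pb = runif(n, 0, 100), Mw = runif(n, 0, 100))
    d$age <- 25 + 0.15 * d$Pb + 0.08 * d$Mw + rnorm(n, 0, 4)
    fit <- lm(age ~ Pb + Mw, d)
    ci <- confint(fit)
    ci["Pb", 1] <= 0.15 && 0.15 <= ci["Pb", 2]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("cross-validation is exact on noiseless cohorts and null on permuted ages", {
  co <- noiseless_cohort()
  cv <- cross_validate(co, c("Wb", "Wu", "Pu"), k = 10, seed = 7)
  expect_equal(cv$mean_r, 1, tolerance = 1e-9)
  expect_length(cv$fold_r, 10)

  build <- generate_cohort(cohort_config(seed = 23))
  perm <- build
  set.seed(5)
  perm$age <- sample(perm$age)
  cvp <- cross_validate(perm, model_catalog()$m7, seed = 7)
  expect_lt(abs(cvp$mean_r), 0.1)

  expect_error(cross_validate(co[1:20, ], "Pu", k = 10), "fewer than 3")
})

test_that("cross-validation does not depend on subject ordering", {
  build <- generate_cohort(cohort_config(n_per_decade = 60, seed = 3))
  shuffled <- build[sample(nrow(build)), ]
  a <- cross_validate(build, model_catalog()$m6, seed = 11)
  b <- cross_validate(shuffled, model_catalog()$m6, seed = 11)
  expect_equal(a$mean_r, b$mean_r, tolerance = 1e-12)
})

test_that("refinement removes negative coefficients and is a fixed point otherwise", {
  build <- generate_cohort(cohort_config(n_per_decade = 60, seed = 8))
  m3 <- fit_age_model(build, model_catalog()$m3)
  expect_true(all(m3$coefficients[m3$subset] >= 0))
  r3 <- refine_model(m3, build)
  expect_identical(r3$coefficients, m3$coefficients)
  expect_true(r3$refined)

  # constructed collinearity: x2 duplicates x1 up to noise; only x1 drives age
  set.seed(106)  # a draw in which the redundant copy takes the negative sign
  n <- 200
  x1 <- runif(n, 0, 100)
  d <- data.frame(x1 = x1, x2 = x1 + rnorm(n, 0, 0.5))
  d$age <- 20 + 0.3 * d$x1 + rnorm(n, 0, 3)
  m <- fit_age_model(d, c("x1", "x2"))
  expect_lt(m$coefficients["x2"], 0)
  r <- refine_model(m, d)
  expect_identical(r$removed, "x2")
  expect_identical(r$subset, "x1")
  expect_true(all(r$coefficients[r$subset] >= 0))

  # postcondition across a battery of cohorts
  for (s in 1:6) {
    co <- generate_cohort(cohort_config(n_per_decade = 50, seed = 300 + s))
    for (subset in model_catalog()[c("m5", "m7", "m9")]) {
      ref <- refine_model(fit_age_model(co, subset), co)
      expect_true(all(ref$coefficients[ref$subset] >= 0))
    }
  }
})

test_that("prediction is the stored linear combination", {
  m <- structure(list(subset = "Pu",
                      coefficients = c(`(Intercept)` = 20, Pu = 0.5),
                      sigma = 0, refined = FALSE, removed = character(0),
                      training_id = "toy", n = 0), class = "age_model")
  expect_equal(predict(m, c(Pu = 40)), 40)
  expect_equal(predict(m, c(Pu = 0)), 20)
  expect_error(predict(m, c(Pb = 10)), "Pu")

  build <- generate_cohort(cohort_config(n_per_decade = 60, seed = 19))
  fit <- fit_age_model(build, model_catalog()$m7)
  r_insample <- cor(predict(fit, build), build$age)
  # oracle: multiple correlation from the closed-form OLS solution
  beta <- ols_oracle(build[fit$subset], build$age)
  yhat <- beta[1] + as.matrix(build[fit$subset]) %*% beta[-1]
  expect_equal(r_insample, cor(drop(yhat), build$age), tolerance = 1e-10)

  tiny <- structure(list(subset = "Pu",
                         coefficients = c(`(Intercept)` = 500, Pu = 1),
                         sigma = 0, refined = FALSE, removed = character(0),
                         training_id = "toy", n = 0), class = "age_model")
  expect_warning(predict(tiny, c(Pu = 50)), "outside")
})

test_that("independent validation tracks the cross-validated performance", {
  build <- generate_cohort(cohort_config(seed = 41))
  val <- generate_cohort(cohort_config(n_per_decade = 103, seed = 42))
  expect_equal(nrow(val), 515)
  m <- fit_age_model(build, model_catalog()$m7)
  r_val <- validate_model(m, val)
  r_cv <- cross_validate(build, model_catalog()$m7, seed = 2)$mean_r
  expect_lt(abs(r_val - r_cv), 0.05)

  co <- noiseless_cohort()
  m0 <- fit_age_model(co, c("Wb", "Wu", "Pu"))
  expect_equal(validate_model(m0, noiseless_cohort(seed = 9)), 1,
               tolerance = 1e-9)
  expect_error(validate_model(m, val[1:5, ]), "too small")
})

test_that("in-sample fit quality is monotone in feature-set nesting", {
  build <- generate_cohort(cohort_config(seed = 51))
  r2 <- vapply(model_catalog(), function(subset) {
    summary(lm(reformulate(subset, "age"), build))$r.squared
  }, numeric(1))
  expect_gte(r2["m7"], r2["m5"])
  expect_gte(r2["m6"], r2["m3"])
  expect_gte(r2["m1"], r2["m8"])
})
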