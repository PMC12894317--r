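# Shared fixtures and independent oracles for the test suite.

# Straight dark-line image: Gaussian-profile valley of standard deviation
# `sd` along y = y0 + slope * x, on a constant background.
make_line_image <- function(n = 64, y0 = n / 2, slope = 0, sd = 1.5,
                            depth = 60, base = 200) {
  img <- matrix(base, n, n)
  for (x in 0:(n - 1)) {
    yc <- y0 + slope * x
    d <- (0:(n - 1) - yc) / sqrt(1 + slope^2)   # perpendicular distance
    img[, x + 1] <- img[, x + 1] - depth * exp(-d^2 / (2 * sd^2))
  }
  img
}

# Intersection-over-union of a thresholded map with a truth mask.
iou_at <- function(map, truth, frac = 0.3) {
  b <- map > frac * max(map)
  sum(b & truth) / sum(b | truth)
}

# Independent OLS oracle: closed-form normal equations.
ols_oracle <- function(X, y) {
  A <- cbind(1, as.matrix(X))
  drop(solve(crossprod(A), crossprod(A, y)))
}

# Independent Benjamini-Hochberg oracle: literal step-up definition,
# q_i = min over j with p_(j) >= p_(i) of p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- which(ps >= ps[i])
    q[o[i]] <- min(1, min(ps[js] * m / js))
  }
  q
}

# Toy full-face landmark set used by the morphology tests: H1 = 120,
# H2 = 115 at image height 200; L1 = 100, L2 = 10, L3 = 12.
toy_landmarks <- function() {
  landmark_set(list(
    medial_canthus_left = c(30, 80),      # height 200 - 80 = 120
    lateral_canthus_left = c(20, 85),     # height 115
    medial_canthus_right = c(88, 80),
    lateral_canthus_right = c(98, 85),
    outline_left_1 = c(10, 40), outline_left_2 = c(10, 130),
    outline_right_1 = c(110, 40), outline_right_2 = c(110, 130)
  ), image_height = 200)
}

# Small cohort with an exactly linear age-feature relationship (no noise).
noiseless_cohort <- function(n = 300, seed = 4) {
  set.seed(seed)
  d <- data.frame(id = sprintf("N%03d", 1:n),
                  Wb = runif(n, 0, 100), Wu = runif(n, 0, 100),
                  Pu = runif(n, 0, 100))
  d$age <- 20 + 0.1 * d$Wb + 0.05 * d$Wu + 0.2 * d$Pu
  d
}
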