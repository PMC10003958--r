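test_that("exact affine data recover the line exactly", {
  f <- pb_fit(c(1, 2, 3), c(1, 2, 3))
  expect_identical(c(f$slope, f$intercept), c(1, 0))
  f <- pb_fit(c(1, 2, 3), c(3, 5, 7))
  expect_identical(c(f$slope, f$intercept), c(2, 1))
})

test_that("scattered five-point fit equals the exhaustive pairwise-slope oracle", {
  x <- c(1.0, 2.0, 3.0, 4.0, 5.0)
  y <- c(1.1, 1.9, 3.3, 3.8, 5.4)
  f <- pb_fit(x, y)
  # frozen from the enumeration oracle: sorted slopes (0.5, 0.8, 0.9, 0.95,
  # 1.05, 1.075, 1.1, 1.1667, 1.4, 1.6), K = 0, median = (1.05 + 1.075)/2
  expect_equal(f$slope, 1.0625, tolerance = 1e-12)
  expect_equal(f$intercept, 0.0375, tolerance = 1e-12)
  o <- pb_oracle(x, y)
  expect_identical(f$slope, o$slope)
  expect_identical(f$intercept, o$intercept)
})

test_that("fit matches the exhaustive oracle exactly on random small instances", {
  set.seed(401)
  for (rep in 1:100) {
    n <- sample(3:12, 1)
    p <- make_pairs(n, slope = runif(1, 0.3, 3), intercept = runif(1, -0.5, 0.5),
                    cv = runif(1, 0.01, 0.3))
    f <- pb_fit(p$x, p$y)
    o <- pb_oracle(p$x, p$y)
    expect_identical(f$slope, o$slope)
    expect_identical(f$intercept, o$intercept)
  }
})

test_that("degenerate and undersized inputs are rejected", {
  expect_error(pb_fit(c(1, 2), c(1, 2)), "insufficient")
  expect_error(pb_fit(c(2, 2, 2), c(1, 2, 3)), "degenerate")
  expect_error(pearson_r(c(1, 2, 3), c(2, 2, 2)), "zero variance")
})

test_that("scale equivariance: (kx, ky) keeps the slope, scales the intercept", {
  set.seed(402)
  p <- make_pairs(25, slope = 0.9, intercept = 0.1)
  f <- pb_fit(p$x, p$y)
  for (k in c(0.25, 3, 117)) {
    fk <- pb_fit(k * p$x, k * p$y)
    expect_equal(fk$slope, f$slope, tolerance = 1e-9)
    expect_equal(fk$intercept, k * f$intercept, tolerance = 1e-9)
  }
})

test_that("exchange symmetry: swapping axes maps (b, a) to (1/b, -a/b)", {
  set.seed(403)
  for (rep in 1:20) {
    p <- make_pairs(sample(5:30, 1), slope = runif(1, 0.5, 2),
                    intercept = runif(1, -0.2, 0.2))
    f <- pb_fit(p$x, p$y)
    g <- pb_fit(p$y, p$x)
    # exact for an odd slope count; for an even count the arithmetic mean of
    # the two central slopes inverts only to O(spacing^2)
    expect_equal(g$slope, 1 / f$slope, tolerance = 1e-5)
    expect_lt(abs(g$intercept - (-f$intercept / f$slope)), 5e-4)
  }
})

test_that("the estimator resists a gross outlier better than least squares", {
  set.seed(404)
  x <- seq(0.5, 5, length.out = 21)
  y <- 1.2 * x + 0.1
  y[21] <- y[21] + 20
  pb <- pb_fit(x, y)$slope
  ols <- unname(coef(lm(y ~ x))[2])
  expect_lt(abs(pb - 1.2), abs(ols - 1.2))
})

test_that("rank CI matches the sort-and-index oracle and degenerates when collinear", {
  set.seed(405)
  p <- make_pairs(20, slope = 1.1, intercept = 0.05)
  ci <- pb_ci_rank(p$x, p$y)
  expect_equal(ci$slope_ci, pb_rank_ci_oracle(p$x, p$y), tolerance = 1e-15)
  b <- pb_fit(p$x, p$y)$slope
  expect_lte(ci$slope_ci[1], b)
  expect_gte(ci$slope_ci[2], b)

  x <- seq(1, 10)
  ci0 <- pb_ci_rank(x, 2 * x + 1)
  expect_equal(ci0$slope_ci, c(2, 2))
  expect_equal(ci0$intercept_ci, c(1, 1))
})

test_that("widening the confidence level never narrows the rank interval", {
  set.seed(406)
  p <- make_pairs(30, slope = 0.9)
  ci90 <- pb_ci_rank(p$x, p$y, 0.90)$slope_ci
  ci95 <- pb_ci_rank(p$x, p$y, 0.95)$slope_ci
  ci99 <- pb_ci_rank(p$x, p$y, 0.99)$slope_ci
  expect_lte(ci95[1], ci90[1])
  expect_gte(ci95[2], ci90[2])
  expect_lte(ci99[1], ci95[1])
  expect_gte(ci99[2], ci95[2])
})

test_that("bootstrap percentile CI honours its degenerate and determinism contracts", {
  set.seed(407)
  p <- make_pairs(30)
  const <- bootstrap_ci(p$x, p$y, function(x, y) 1.0, iterations = 50, seed = 1)
  expect_equal(as.numeric(const), c(1, 1))

  s <- function(x, y) pb_fit(x, y)$slope
  a <- bootstrap_ci(p$x, p$y, s, iterations = 200, seed = 99)
  b <- bootstrap_ci(p$x, p$y, s, iterations = 200, seed = 99)
  expect_identical(a, b)
  c_ <- bootstrap_ci(p$x, p$y, s, iterations = 200, seed = 100)
  expect_false(identical(a, c_))
})

test_that("bootstrap errors out when the statistic is undefined on every resample", {
  p <- make_pairs(10)
  expect_error(
    bootstrap_ci(p$x, p$y, function(x, y) stop("nope"), iterations = 5, seed = 1),
    "resamples")
})

test_that("percentile CI for a normal mean attains nominal coverage", {
  # mean of n = 50 draws from N(10, 4): 95% percentile interval should cover
  # the true mean in about 95% of repetitions
  set.seed(408)
  reps <- 1000
  covered <- 0L
  for (i in 1:reps) {
    z <- rnorm(50, 10, 2)
    ci <- bootstrap_ci(z, z, function(x, y) mean(x), iterations = 500)
    covered <- covered + (ci[1] <= 10 && 10 <= ci[2])
  }
  expect_gte(covered / reps, 0.93)
  expect_lte(covered / reps, 0.97)
})

test_that("pearson_r matches the textbook product-moment formula", {
  expect_identical(pearson_r(c(1, 2, 3), c(3, 5, 7)), 1)
  expect_identical(pearson_r(c(1, 2, 3), c(7, 5, 3)), -1)
  x <- c(1, 2, 4, 5)
  y <- c(1.1, 1.9, 4.4, 4.6)
  n <- 4
  hand <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(pearson_r(x, y), hand, tolerance = 1e-12)
})

test_that("pb_predict evaluates the fitted equation at a decision level", {
  fit <- structure(list(slope = 1, intercept = 0), class = "pb_fit")
  expect_identical(pb_predict(fit, 1.6), 1.6)
  fit <- structure(list(slope = 0.89, intercept = -0.01), class = "pb_fit")
  expect_equal(pb_predict(fit, 0.6), 0.524, tolerance = 1e-12)
  fit <- structure(list(slope = 2, intercept = 1), class = "pb_fit")
  expect_identical(pb_predict(fit, 3), 7)
})

test_that("bootstrap regression CIs agree with rank CIs on well-behaved data", {
  set.seed(409)
  p <- make_pairs(100, slope = 1, intercept = 0, cv = 0.03)
  boot <- pb_regression(p$x, p$y, ci_method = "bootstrap", iterations = 5000,
                        seed = 5)
  rank <- pb_regression(p$x, p$y, ci_method = "rank")
  expect_lt(max(abs(boot$slope_ci - rank$slope_ci)), 0.05)
})
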