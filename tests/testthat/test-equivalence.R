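pb <- function(slope, intercept, boot = NULL) {
  structure(list(slope = slope, intercept = intercept, ci_level = 0.95,
                 boot = boot), class = "pb_fit")
}

test_that("an identity fit has zero systematic difference at every level", {
  fit <- pb(1, 0)
  for (lev in c(0.6, 1.6, 6.0)) {
    row <- systematic_difference(fit, lev, tea_percent = 7.4)
    expect_identical(row$systematic_difference, 0)
    expect_identical(row$systematic_difference_pct, 0)
    expect_identical(row$verdict, "acceptable")
  }
})

test_that("systematic difference is affine in the level with the expected worked values", {
  fit <- pb(0.89, -0.01)
  low <- systematic_difference(fit, 0.6, 7.4)
  expect_equal(low$systematic_difference, -0.076, tolerance = 1e-9)
  expect_equal(round(low$systematic_difference, 2), -0.08)
  mid <- systematic_difference(fit, 1.6, 7.4)
  expect_equal(mid$systematic_difference, -0.186, tolerance = 1e-9)
  expect_equal(round(mid$systematic_difference, 2), -0.19)
  expect_identical(c(low$verdict, mid$verdict),
                   c("inequivalent", "inequivalent"))
  # affine: difference(level) = intercept + (slope - 1) * level
  levs <- c(0.5, 1, 2, 4)
  d <- vapply(levs, function(l) systematic_difference(fit, l, 7.4)$systematic_difference,
              numeric(1))
  expect_equal(d, -0.01 + (0.89 - 1) * levs, tolerance = 1e-12)
})

test_that("a constant offset is judged against TEa on the percent scale", {
  row <- systematic_difference(pb(1, 0.5), 1.0, 7.4)
  expect_identical(row$systematic_difference, 0.5)
  expect_identical(row$systematic_difference_pct, 50)
  expect_identical(row$verdict, "inequivalent")
  # the boundary passes (values chosen to be exact in binary)
  at_limit <- systematic_difference(pb(1.25, 0), 1.0, 25)
  expect_identical(at_limit$verdict, "acceptable")
  expect_error(systematic_difference(pb(1, 0), -1, 7.4), "> 0")
})

test_that("bootstrap coefficient draws propagate into the difference CI", {
  boot <- data.frame(slope = c(0.88, 0.89, 0.90), intercept = c(-0.02, -0.01, 0))
  row <- systematic_difference(pb(0.89, -0.01, boot = boot), 1.6, 7.4)
  d <- boot$intercept + boot$slope * 1.6 - 1.6
  expect_equal(c(row$ci_low, row$ci_high),
               unname(quantile(d, c(0.025, 0.975))), tolerance = 1e-12)
  expect_equal(row$ci_low_pct, 100 * row$ci_low / 1.6, tolerance = 1e-12)
})

test_that("duplicate SD follows its closed forms", {
  expect_identical(duplicate_sd(c(1, 2, 3), c(1, 2, 3))$sd, 0)
  d <- 0.3
  expect_equal(duplicate_sd(2.0, 2.0 + d)$sd, d / sqrt(2), tolerance = 1e-15)
  got <- duplicate_sd(c(1.0, 2.0, 3.0), c(1.2, 2.0, 2.6))
  expect_equal(got$sd, sqrt((0.04 / 2 + 0 + 0.16 / 2) / 3), tolerance = 1e-15)
  expect_equal(got$sd, 0.1825741858, tolerance = 1e-9)
  expect_identical(got$k, 3L)
  # replicate order within a pair is irrelevant
  expect_identical(duplicate_sd(c(1.2, 2.0, 2.6), c(1.0, 2.0, 3.0))$sd, got$sd)
  expect_error(duplicate_sd(c(NA, NA), c(1, 2)), "empty group")
})

test_that("duplicate SD and %CV are scale-equivariant under k * X", {
  set.seed(201)
  v1 <- runif(20, 0.5, 3)
  v2 <- v1 * (1 + rnorm(20, 0, 0.03))
  base <- duplicate_sd(v1, v2)
  cv <- percent_cv(base$sd, mean(c(v1, v2)))
  for (k in c(0.1, 7)) {
    sk <- duplicate_sd(k * v1, k * v2)
    expect_equal(sk$sd, k * base$sd, tolerance = 1e-12)
    expect_equal(percent_cv(sk$sd, mean(c(k * v1, k * v2))), cv,
                 tolerance = 1e-12)
  }
})

test_that("percent CV is the direct ratio with guarded inputs", {
  expect_identical(percent_cv(0, 1.3), 0)
  expect_identical(percent_cv(0.02, 1.00), 2)
  expect_equal(percent_cv(0.123, 4.56), 100 * 0.123 / 4.56, tolerance = 1e-12)
  expect_error(percent_cv(0.1, 0), "mean")
  expect_error(percent_cv(-0.1, 1), "sd")
})

test_that("SD ratio composes the two duplicate SDs and bootstraps by subject", {
  set.seed(202)
  n <- 30
  subj <- sprintf("S%02d", 1:n)
  prim <- data.frame(subject_id = subj, value_1 = runif(n, 1, 3))
  prim$value_2 <- prim$value_1 + rnorm(n, 0, 0.05)
  cand <- data.frame(subject_id = subj, value_1 = prim$value_1,
                     value_2 = prim$value_1 + 2 * (prim$value_2 - prim$value_1))

  ident <- sd_ratio_with_ci(prim, prim, iterations = 100, seed = 3)
  expect_identical(ident$ratio, 1)
  expect_true(ident$ratio_ci[1] <= 1 && 1 <= ident$ratio_ci[2])

  doubled <- sd_ratio_with_ci(cand, prim, iterations = 100, seed = 3)
  expect_equal(doubled$ratio, 2, tolerance = 1e-12)

  # two-pass oracle: each SD computed separately, then divided
  oracle <- duplicate_sd(cand$value_1, cand$value_2)$sd /
    duplicate_sd(prim$value_1, prim$value_2)$sd
  expect_equal(doubled$ratio, oracle, tolerance = 1e-12)

  a <- sd_ratio_with_ci(cand, prim, iterations = 150, seed = 11)
  b <- sd_ratio_with_ci(cand, prim, iterations = 150, seed = 11)
  expect_identical(a$ratio_ci, b$ratio_ci)

  expect_error(sd_ratio_with_ci(cand[-1, ], prim, iterations = 10, seed = 1),
               "alignment")
  zero <- prim
  zero$value_2 <- zero$value_1
  expect_error(sd_ratio_with_ci(cand, zero, iterations = 10, seed = 1),
               "infinite ratio")
})

test_that("the three-tier rule reproduces all verdict/criterion combinations", {
  dec <- function(...) acceptance_decision(...)
  # (i): ratio at or below one
  expect_identical(dec(0.68, c(0.40, 1.15), 5, 2.3),
                   list(verdict = "acceptable", criterion = "i"))
  expect_identical(dec(1.00, c(0.9, 1.1), 5, 2.3)$criterion, "i")
  # (ii): ratio above one, CI straddles one
  expect_identical(dec(1.20, c(0.90, 1.60), 99, 2.3),
                   list(verdict = "acceptable", criterion = "ii"))
  # (iii): CI clear of one but imprecision within the allowable CV
  expect_identical(dec(1.41, c(1.09, 1.84), 1.89, 2.3),
                   list(verdict = "acceptable", criterion = "iii"))
  # none: CI clear of one and CV too large
  expect_identical(dec(2.00, c(1.54, 2.61), 3.17, 2.3),
                   list(verdict = "unacceptable", criterion = "none"))
  # boundary of (iii) passes
  expect_identical(dec(1.5, c(1.1, 2.0), 2.3, 2.3)$criterion, "iii")
})

test_that("decreasing the ratio never flips an acceptable verdict", {
  set.seed(203)
  for (rep in 1:50) {
    cv <- runif(1, 0, 5)
    allow <- 2.3
    lo <- runif(1, 0.5, 1.5)
    hi <- lo + runif(1, 0, 1)
    r_hi <- runif(1, 1, 2.5)
    r_lo <- runif(1, 0, r_hi)
    v_hi <- acceptance_decision(r_hi, c(lo, hi), cv, allow)$verdict
    v_lo <- acceptance_decision(r_lo, c(lo, hi), cv, allow)$verdict
    if (v_hi == "acceptable") expect_identical(v_lo, "acceptable")
    if (r_lo <= 1) expect_identical(acceptance_decision(r_lo, c(lo, hi), cv, allow)$criterion, "i")
  }
})

test_that("subinterval assignment uses a closed middle interval", {
  got <- assign_subintervals(c(0.5, 0.7, 1.7, 1.8), c(0.7, 1.7))
  expect_identical(as.character(got), c("low", "mid", "mid", "high"))
  all_low <- assign_subintervals(c(0.1, 0.2), c(0.7, 1.7))
  expect_identical(as.character(all_low), c("low", "low"))
  expect_identical(levels(all_low), c("low", "mid", "high"))
  expect_error(assign_subintervals(1, c(2, 1)), "increasing")
})
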