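# Passing-Bablok nonparametric regression.
#
# The slope is the shifted median of all pairwise slopes
# S_ij = (y_j - y_i) / (x_j - x_i), i < j, after discarding pairs with
# x_i = x_j (including identical points) and slopes exactly equal to -1;
# the median index is offset by K = #(slopes < -1), which makes the
# estimator invariant to exchanging the axes. The intercept is
# median(y - b x).

# All valid pairwise slopes (unsorted). Exclusions: dx == 0, slope == -1.
pb_pairwise_slopes <- function(x, y) {
  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  ut <- upper.tri(dx)
  dxv <- dx[ut]
  dyv <- dy[ut]
  keep <- dxv != 0
  s <- dyv[keep] / dxv[keep]
  s[s != -1]
}

check_pairs <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (anyNA(x) || anyNA(y) || !all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite and non-missing", call. = FALSE)
  if (length(x) < 3)
    stop("insufficient data: Passing-Bablok regression needs n >= 3", call. = FALSE)
  if (length(unique(x)) == 1)
    stop("degenerate input: all comparator values identical", call. = FALSE)
  invisible(TRUE)
}

# Shifted median of sorted slopes with offset K; indices clamped to [1, N].
pb_shifted_median <- function(s_sorted) {
  N <- length(s_sorted)
  K <- sum(s_sorted < -1)
  clamp <- function(i) min(max(i, 1L), N)
  if (N %% 2L == 1L) {
    s_sorted[clamp((N + 1L) %/% 2L + K)]
  } else {
    mean(s_sorted[c(clamp(N %/% 2L + K), clamp(N %/% 2L + 1L + K))])
  }
}

#' Passing-Bablok point estimates
#'
#' Classical Passing-Bablok regression of candidate (`y`) on comparator
#' (`x`): slope = shifted median of pairwise slopes, intercept =
#' median(y - slope * x). Use [pb_regression()] for a fit with confidence
#' intervals and correlation.
#'
#' @param x Comparator values (mg/dL).
#' @param y Candidate values (mg/dL), same subjects in the same order.
#' @return An object of class `"pb_fit"`: list with `slope`, `intercept`,
#'   `n`.
#' @export
#' @examples
#' pb_fit(c(1, 2, 3), c(3, 5, 7)) # slope 2, intercept 1
pb_fit <- function(x, y) {
  check_pairs(x, y)
  s <- sort(pb_pairwise_slopes(x, y))
  if (length(s) == 0)
    stop("degenerate input: no valid pairwise slopes", call. = FALSE)
  b <- pb_shifted_median(s)
  a <- stats::median(y - b * x)
  structure(list(slope = b, intercept = a, n = length(x)), class = "pb_fit")
}

#' Rank-based confidence interval for a Passing-Bablok fit
#'
#' Analytic interval from the order statistics of the valid pairwise slopes,
#' at ranks given by the normal approximation of Kendall's statistic:
#' with N valid slopes and n points, C = z * sqrt(n(n-1)(2n+5)/18),
#' M1 = round((N - C)/2), M2 = N - M1 + 1, and the bounds are the (M1+K)-th
#' and (M2+K)-th sorted slopes. Intercept bounds are medians of
#' y - b_bound * x at the slope bounds.
#'
#' @inheritParams pb_fit
#' @param ci_level Two-sided confidence level in (0, 1).
#' @return List with `slope_ci` and `intercept_ci` (length-2 numeric) and
#'   `ci_level`.
#' @export
pb_ci_rank <- function(x, y, ci_level = 0.95) {
  check_pairs(x, y)
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must be in (0, 1)", call. = FALSE)
  n <- length(x)
  s <- sort(pb_pairwise_slopes(x, y))
  N <- length(s)
  K <- sum(s < -1)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  C <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - C) / 2)
  M2 <- N - M1 + 1
  if (M1 + K < 1 || M2 + K > N)
    stop("coverage error: too few pairwise slopes for ci_level = ", ci_level,
         call. = FALSE)
  b_lo <- s[M1 + K]
  b_hi <- s[M2 + K]
  a_bounds <- c(stats::median(y - b_hi * x), stats::median(y - b_lo * x))
  list(slope_ci = c(b_lo, b_hi),
       intercept_ci = c(min(a_bounds), max(a_bounds)),
       ci_level = ci_level)
}

#' Bootstrap percentile confidence interval for a paired-data statistic
#'
#' Resamples subjects (their (x, y) pairs) with replacement and returns the
#' percentile interval of the statistic. Resamples on which the statistic is
#' undefined (error or non-finite result) are redrawn, with a cap of
#' `10 * iterations` total draws. Fully reproducible given `seed`.
#'
#' @inheritParams pb_fit
#' @param statistic Function of `(x, y)` returning a single number.
#' @param iterations Number of bootstrap resamples (default 1000).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param ci_level Two-sided confidence level.
#' @return Length-2 numeric interval, with attribute `"draws"` holding the
#'   bootstrap replicates.
#' @export
bootstrap_ci <- function(x, y, statistic, iterations = 1000, seed = NULL,
                         ci_level = 0.95) {
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  n <- length(x)
  draws <- boot_draws(n, iterations, seed,
                      function(idx) statistic(x[idx], y[idx]))
  alpha <- (1 - ci_level) / 2
  out <- unname(stats::quantile(draws, c(alpha, 1 - alpha)))
  attr(out, "draws") <- draws
  out
}

# Shared resample-with-redraw loop. fn(idx) must return a numeric scalar or
# vector of fixed length; non-finite results / errors trigger a redraw.
boot_draws <- function(n, iterations, seed, fn) {
  run <- function() {
    out <- NULL
    i <- 1L
    attempts <- 0L
    while (i <= iterations) {
      attempts <- attempts + 1L
      if (attempts > 10L * iterations)
        stop("bootstrap failed: statistic undefined on too many resamples",
             call. = FALSE)
      idx <- sample.int(n, n, replace = TRUE)
      val <- tryCatch(fn(idx), error = function(e) NA_real_)
      if (!is.numeric(val) || !all(is.finite(val))) next
      if (is.null(out)) out <- matrix(NA_real_, nrow = iterations, ncol = length(val))
      out[i, ] <- val
      i <- i + 1L
    }
    out
  }
  res <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  if (ncol(res) == 1L) drop(res) else res
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()] for method-comparison pairs.
#'
#' @inheritParams pb_fit
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  check_pairs(x, y)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  stats::cor(x, y)
}

#' Passing-Bablok regression with confidence intervals
#'
#' Full method-comparison fit: classical point estimates ([pb_fit()]),
#' Pearson correlation, and confidence intervals for slope and intercept by
#' either subject-level bootstrap percentiles (the default) or the analytic
#' rank method ([pb_ci_rank()]). Bootstrap fits store the resampled
#' (slope, intercept) draws so downstream quantities (e.g. systematic
#' differences at decision levels, [systematic_difference()]) can propagate
#' them jointly.
#'
#' @inheritParams pb_ci_rank
#' @param ci_method `"bootstrap"` (percentile, default) or `"rank"`.
#' @param iterations Bootstrap resamples (ignored for `"rank"`).
#' @param seed Integer seed for the bootstrap.
#' @param comparator_label,candidate_label Labels carried into reports.
#' @return Object of class `"pb_fit"` with `slope`, `intercept`, `slope_ci`,
#'   `intercept_ci`, `pearson_r`, `n`, `ci_method`, `ci_level`, labels, and
#'   (bootstrap only) a data frame `boot` of coefficient draws plus `seed`
#'   and `iterations`.
#' @export
pb_regression <- function(x, y, ci_method = c("bootstrap", "rank"),
                          iterations = 1000, seed = 20230301,
                          ci_level = 0.95,
                          comparator_label = "comparator",
                          candidate_label = "candidate") {
  ci_method <- match.arg(ci_method)
  fit <- pb_fit(x, y)
  fit$pearson_r <- pearson_r(x, y)
  fit$ci_level <- ci_level
  fit$ci_method <- ci_method
  fit$comparator_label <- comparator_label
  fit$candidate_label <- candidate_label
  if (ci_method == "rank") {
    ci <- pb_ci_rank(x, y, ci_level)
    fit$slope_ci <- ci$slope_ci
    fit$intercept_ci <- ci$intercept_ci
  } else {
    coefs <- boot_draws(length(x), iterations, seed, function(idx) {
      f <- pb_fit(x[idx], y[idx])
      c(f$slope, f$intercept)
    })
    alpha <- (1 - ci_level) / 2
    probs <- c(alpha, 1 - alpha)
    fit$slope_ci <- unname(stats::quantile(coefs[, 1], probs))
    fit$intercept_ci <- unname(stats::quantile(coefs[, 2], probs))
    fit$boot <- data.frame(slope = coefs[, 1], intercept = coefs[, 2])
    fit$seed <- seed
    fit$iterations <- iterations
  }
  fit
}

#' Predict a candidate value from a Passing-Bablok fit
#'
#' @param fit A `"pb_fit"`.
#' @param level Comparator concentration(s), mg/dL.
#' @return `intercept + slope * level`.
#' @export
pb_predict <- function(fit, level) {
  stopifnot(inherits(fit, "pb_fit"))
  fit$intercept + fit$slope * level
}

#' @export
print.pb_fit <- function(x, ...) {
  cat("Passing-Bablok regression (n = ", x$n, ")\n", sep = "")
  if (!is.null(x$candidate_label))
    cat(" ", x$candidate_label, "~", x$comparator_label, "\n")
  fmt_ci <- function(ci) {
    if (is.null(ci)) "" else sprintf(" (%.4g, %.4g)", ci[1], ci[2])
  }
  cat(sprintf("  slope:     %.4g%s\n", x$slope, fmt_ci(x$slope_ci)))
  cat(sprintf("  intercept: %.4g%s mg/dL\n", x$intercept, fmt_ci(x$intercept_ci)))
  if (!is.null(x$pearson_r)) cat(sprintf("  Pearson r: %.4f\n", x$pearson_r))
  if (!is.null(x$ci_method))
    cat("  CI method:", x$ci_method,
        if (x$ci_method == "bootstrap")
          sprintf("(%d iterations, seed %d)", x$iterations, x$seed) else "",
        "\n")
  invisible(x)
}
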