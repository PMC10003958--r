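# Bland-Altman agreement and the omnibus one-way ANOVA mean comparison.

#' Bland-Altman agreement summary
#'
#' Differences are `candidate - comparator` (device under test minus
#' reference). Limits of agreement are `mean +/- loa_multiplier * SD` of the
#' differences (multiplier 2 by default); the CI of the mean difference is
#' the t-based interval. Per-point plot coordinates (mean of the two methods
#' vs difference) are returned for figure generation.
#'
#' @param x Comparator values (mg/dL).
#' @param y Candidate values (mg/dL), same subjects in the same order.
#' @param ci_level Confidence level for the mean difference.
#' @param loa_multiplier SD multiple for the limits of agreement.
#' @return Object of class `"bland_altman"`: `mean_difference`,
#'   `mean_difference_ci`, `sd_of_differences`, `loa_low`, `loa_high`,
#'   `mean_percent_difference`, `n`, and a tibble `points` with columns
#'   `mean` and `difference`.
#' @export
bland_altman <- function(x, y, ci_level = 0.95, loa_multiplier = 2) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("insufficient data: Bland-Altman needs n >= 2", call. = FALSE)
  d <- y - x
  md <- mean(d)
  sd_d <- stats::sd(d)
  se <- sd_d / sqrt(n)
  tq <- stats::qt(1 - (1 - ci_level) / 2, df = n - 1)
  structure(list(
    mean_difference = md,
    mean_difference_ci = c(md - tq * se, md + tq * se),
    sd_of_differences = sd_d,
    loa_low = md - loa_multiplier * sd_d,
    loa_high = md + loa_multiplier * sd_d,
    mean_percent_difference = if (all(x > 0)) mean_percent_difference(x, y) else NA_real_,
    n = n,
    ci_level = ci_level,
    loa_multiplier = loa_multiplier,
    points = tibble::tibble(mean = (x + y) / 2, difference = d)
  ), class = "bland_altman")
}

#' Mean percent difference between two methods
#'
#' Mean over subjects of `100 * (candidate - comparator) / comparator`
#' (per-subject percent differences, not the ratio of the mean difference to
#' the comparator mean).
#'
#' @inheritParams bland_altman
#' @return Percent.
#' @export
mean_percent_difference <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (any(x == 0)) stop("comparator values must be nonzero", call. = FALSE)
  mean(100 * (y - x) / x)
}

#' One-way fixed-effects analysis of variance
#'
#' Omnibus comparison of group means across analyzers or specimen types,
#' via [stats::aov()]. The fully degenerate case (zero within-group variance
#' everywhere with equal means) is defined as F = 0, p = 1.
#'
#' @param groups Named list of two or more numeric vectors (each length
#'   >= 2).
#' @return List with `f_statistic`, `p_value`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least two values", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)))
  )
  k <- length(groups)
  df_b <- k - 1L
  df_w <- nrow(df) - k
  # degenerate inputs make aov's 0/0 numerically unstable; settle them first
  if (all(vapply(groups, function(g) stats::var(g) == 0, logical(1)))) {
    means <- vapply(groups, mean, numeric(1))
    if (max(means) == min(means))
      return(list(f_statistic = 0, p_value = 1, df_between = df_b, df_within = df_w))
    return(list(f_statistic = Inf, p_value = 0, df_between = df_b, df_within = df_w))
  }
  tab <- summary(stats::aov(value ~ group, data = df))[[1]]
  list(f_statistic = tab[["F value"]][1], p_value = tab[["Pr(>F)"]][1],
       df_between = tab[["Df"]][1], df_within = tab[["Df"]][2])
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("Bland-Altman agreement (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  mean difference: %.4g mg/dL (%g%% CI %.4g, %.4g)\n",
              x$mean_difference, 100 * x$ci_level,
              x$mean_difference_ci[1], x$mean_difference_ci[2]))
  cat(sprintf("  limits of agreement (+/- %g SD): %.4g to %.4g mg/dL\n",
              x$loa_multiplier, x$loa_low, x$loa_high))
  if (is.finite(x$mean_percent_difference))
    cat(sprintf("  mean %% difference: %.4g%%\n", x$mean_percent_difference))
  invisible(x)
}
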