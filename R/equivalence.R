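# Specimen-equivalence assessment in the CLSI EP35 style: systematic
# differences at medical decision levels judged against total allowable
# error, duplicate-replicate imprecision, SD ratios with paired-bootstrap
# CIs, and the three-tier acceptance decision.

#' Systematic difference at a medical decision level
#'
#' Evaluates the fitted Passing-Bablok equation at a decision level and
#' compares the deviation from identity with the total-allowable-error
#' limit: difference = (intercept + slope * level) - level, percent
#' difference = 100 * difference / level, verdict `"acceptable"` iff
#' |percent difference| <= TEa (the boundary passes). When the fit carries
#' bootstrap coefficient draws (see [pb_regression()]), each (slope,
#' intercept) draw is propagated through the same formula and the percentile
#' interval is reported, preserving the slope-intercept dependence.
#'
#' @param fit A `"pb_fit"`, typically from [pb_regression()].
#' @param level Medical decision level, mg/dL (> 0).
#' @param tea_percent Total allowable error at that level, percent.
#' @param ci_level Confidence level for the propagated interval.
#' @return One-row tibble: `decision_level`, `systematic_difference` (mg/dL),
#'   `systematic_difference_pct`, `ci_low`/`ci_high` (mg/dL),
#'   `ci_low_pct`/`ci_high_pct`, `tea_percent`, `verdict`.
#' @export
systematic_difference <- function(fit, level, tea_percent, ci_level = NULL) {
  stopifnot(inherits(fit, "pb_fit"))
  if (!is.numeric(level) || level <= 0)
    stop("decision level must be > 0 mg/dL", call. = FALSE)
  ci_level <- ci_level %||% fit$ci_level %||% 0.95
  diff <- pb_predict(fit, level) - level
  pct <- 100 * diff / level
  ci <- c(NA_real_, NA_real_)
  if (!is.null(fit$boot)) {
    d <- fit$boot$intercept + fit$boot$slope * level - level
    alpha <- (1 - ci_level) / 2
    ci <- unname(stats::quantile(d, c(alpha, 1 - alpha)))
  }
  tibble::tibble(
    decision_level = level,
    systematic_difference = diff,
    systematic_difference_pct = pct,
    ci_low = ci[1], ci_high = ci[2],
    ci_low_pct = 100 * ci[1] / level, ci_high_pct = 100 * ci[2] / level,
    tea_percent = tea_percent,
    verdict = if (abs(pct) <= tea_percent) "acceptable" else "inequivalent"
  )
}

#' Duplicate-based standard deviation
#'
#' Imprecision estimated from paired replicates:
#' `SD^2 = (1/K) * sum_i (X_i2 - X_i1)^2 / 2` over the K complete pairs.
#' Invariant to replicate order within each pair. Pairs with a missing
#' replicate are dropped.
#'
#' @param value_1,value_2 Replicate 1 and replicate 2 values (mg/dL), same
#'   subjects in the same order.
#' @return List with `sd` (mg/dL) and `k` (number of complete pairs).
#' @export
#' @examples
#' duplicate_sd(c(1.0, 2.0, 3.0), c(1.2, 2.0, 2.6))$sd # 0.18257...
duplicate_sd <- function(value_1, value_2) {
  if (length(value_1) != length(value_2))
    stop("replicate vectors must have equal length", call. = FALSE)
  ok <- is.finite(value_1) & is.finite(value_2)
  k <- sum(ok)
  if (k == 0)
    stop("empty group: no complete replicate pairs", call. = FALSE)
  d <- value_2[ok] - value_1[ok]
  list(sd = sqrt(mean(d^2 / 2)), k = k)
}

#' Percent coefficient of variation
#'
#' @param sd Standard deviation (mg/dL), >= 0.
#' @param mean Mean concentration (mg/dL), > 0.
#' @return `100 * sd / mean`.
#' @export
percent_cv <- function(sd, mean) {
  if (any(mean <= 0)) stop("mean must be > 0", call. = FALSE)
  if (any(sd < 0)) stop("sd must be >= 0", call. = FALSE)
  100 * sd / mean
}

#' SD ratio of candidate to primary specimen with bootstrap CI
#'
#' Ratio of duplicate-based SDs ([duplicate_sd()]) for the same subjects
#' measured on a candidate and the primary specimen. The CI is a
#' subject-level paired bootstrap: subjects are resampled with replacement,
#' both SDs and their ratio recomputed, and the percentile interval taken.
#'
#' @param candidate_pairs,primary_pairs Data frames with columns
#'   `subject_id`, `value_1`, `value_2`; the same subject set in both.
#' @param iterations Bootstrap resamples.
#' @param seed Integer seed.
#' @param ci_level Confidence level.
#' @return List with `ratio`, `ratio_ci`, `sd_candidate`, `sd_primary`, `k`.
#' @export
sd_ratio_with_ci <- function(candidate_pairs, primary_pairs,
                             iterations = 1000, seed = 20230301,
                             ci_level = 0.95) {
  cp <- candidate_pairs[order(candidate_pairs$subject_id), ]
  pp <- primary_pairs[order(primary_pairs$subject_id), ]
  if (nrow(cp) != nrow(pp) || !identical(as.character(cp$subject_id),
                                         as.character(pp$subject_id)))
    stop("alignment error: candidate and primary subject sets differ",
         call. = FALSE)
  if (nrow(cp) < 2)
    stop("need at least two subjects per group", call. = FALSE)
  sd_c <- duplicate_sd(cp$value_1, cp$value_2)
  sd_p <- duplicate_sd(pp$value_1, pp$value_2)
  if (sd_p$sd == 0)
    stop("infinite ratio: primary-specimen duplicate SD is zero", call. = FALSE)
  ratio <- sd_c$sd / sd_p$sd
  draws <- boot_draws(nrow(cp), iterations, seed, function(idx) {
    num <- duplicate_sd(cp$value_1[idx], cp$value_2[idx])$sd
    den <- duplicate_sd(pp$value_1[idx], pp$value_2[idx])$sd
    num / den
  })
  alpha <- (1 - ci_level) / 2
  list(ratio = ratio,
       ratio_ci = unname(stats::quantile(draws, c(alpha, 1 - alpha))),
       sd_candidate = sd_c$sd, sd_primary = sd_p$sd, k = sd_c$k)
}

#' Three-tier SD-ratio acceptance decision
#'
#' Clinical acceptability of a candidate specimen's imprecision relative to
#' the primary specimen, evaluated in order:
#' \describe{
#'   \item{(i)}{the SD ratio is <= 1.00;}
#'   \item{(ii)}{the ratio is > 1.00 but its CI includes 1.00;}
#'   \item{(iii)}{the ratio and the lower CI bound are > 1.00, but the
#'     candidate's imprecision at the decision level is within the allowable
#'     CV.}
#' }
#' The first satisfied criterion is returned; if none holds the verdict is
#' `"unacceptable"` with criterion `"none"`.
#'
#' @param ratio SD ratio (candidate / primary), >= 0.
#' @param ratio_ci Length-2 confidence interval for the ratio.
#' @param cv_percent Candidate-specimen %CV in the subinterval.
#' @param allowable_cv_percent Allowable imprecision, percent.
#' @return List with `verdict` (`"acceptable"`/`"unacceptable"`) and
#'   `criterion` (`"i"`, `"ii"`, `"iii"`, or `"none"`).
#' @export
#' @examples
#' acceptance_decision(1.41, c(1.09, 1.84), 1.89, 2.3) # acceptable via (iii)
acceptance_decision <- function(ratio, ratio_ci, cv_percent,
                                allowable_cv_percent) {
  stopifnot(ratio >= 0, length(ratio_ci) == 2, ratio_ci[1] <= ratio_ci[2])
  if (ratio <= 1) {
    list(verdict = "acceptable", criterion = "i")
  } else if (ratio_ci[1] <= 1 && ratio_ci[2] >= 1) {
    list(verdict = "acceptable", criterion = "ii")
  } else if (ratio_ci[1] > 1 && cv_percent <= allowable_cv_percent) {
    list(verdict = "acceptable", criterion = "iii")
  } else {
    list(verdict = "unacceptable", criterion = "none")
  }
}

#' Assign subjects to concentration subintervals
#'
#' Splits subjects into low / mid / high groups at the two cutoffs: low if
#' value < b1, mid if b1 <= value <= b2 (closed on both ends), high if
#' value > b2. The grouping value should be the primary-specimen duplicate
#' mean; the subject then carries its group across all specimen types so SD
#' ratios compare identical subject sets.
#'
#' @param values Grouping concentrations, mg/dL (one per subject).
#' @param bounds Strictly increasing numeric pair (b1, b2).
#' @return Factor with levels `"low"`, `"mid"`, `"high"`.
#' @export
assign_subintervals <- function(values, bounds) {
  if (length(bounds) != 2 || diff(bounds) <= 0)
    stop("bounds must be a strictly increasing pair", call. = FALSE)
  out <- ifelse(values < bounds[1], "low",
                ifelse(values <= bounds[2], "mid", "high"))
  factor(out, levels = c("low", "mid", "high"))
}

subinterval_labels <- function(bounds) {
  c(low  = sprintf("<%g", bounds[1]),
    mid  = sprintf("%g-%g", bounds[1], bounds[2]),
    high = sprintf(">%g", bounds[2]),
    total = "total")
}
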