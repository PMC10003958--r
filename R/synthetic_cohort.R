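# Synthetic paired-duplicate cohort generator. Emulates the study design:
# each subject contributes three simultaneously collected specimen types
# measured in duplicate on the device under test, with specimen-specific
# proportional (slope) and constant (intercept) bias and constant-CV
# replicate noise, plus optional comparator analyzers measured on serum.

#' Parameters for a synthetic paired-measurement cohort
#'
#' The concentration distribution is a three-component mixture with exact
#' per-subinterval subject counts (matching the skewed clinical case mix):
#' within each subinterval, true concentrations are drawn log-uniformly.
#' Sampling intervals abutting a subinterval cutoff are shrunk by a
#' multiplicative boundary guard of `boundary_guard` duplicate-mean noise
#' SDs, so the observed primary-specimen duplicate mean classifies each
#' subject into its configured group with near-certainty and the configured
#' counts are reproduced by construction.
#'
#' Defaults are the study conditions: 105 subjects; Cr counts 34/56/15
#' below/within/above (0.7, 1.7) mg/dL with range (0.3, 8); BUN counts
#' 62/22/21 at cutoffs (20, 30) mg/dL with range (4, 80); identity specimen
#' effects; 2% replicate CV for every specimen.
#'
#' @param analyte `"Cr"` or `"BUN"`.
#' @param n_subjects Number of subjects (>= 3).
#' @param group_counts Integer triple (low, mid, high) summing to
#'   `n_subjects`.
#' @param subinterval_bounds Cutoffs (b1, b2) in mg/dL.
#' @param concentration_range Overall range (lo, hi) of true concentrations.
#' @param specimen_effects Named list mapping specimen type to
#'   `c(slope, intercept)` relative to the primary specimen.
#' @param replicate_cv Named numeric vector, percent CV of replicate noise
#'   per specimen.
#' @param system Identifier of the device under test.
#' @param system_effects Optional named list mapping comparator-analyzer
#'   identifiers to `c(slope, intercept)`; each is simulated in duplicate on
#'   serum from the same true concentrations.
#' @param noise `"proportional"` (constant CV, default) or `"additive"`.
#' @param additive_sd Named numeric vector of per-specimen SDs (mg/dL), used
#'   when `noise = "additive"`.
#' @param boundary_guard Width of the boundary guard in duplicate-mean noise
#'   SDs (default 6).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return List of class `"cohort_params"`.
#' @export
cohort_params <- function(analyte = c("Cr", "BUN"),
                          n_subjects = 105L,
                          group_counts = NULL,
                          subinterval_bounds = NULL,
                          concentration_range = NULL,
                          specimen_effects = NULL,
                          replicate_cv = NULL,
                          system = "ABL90",
                          system_effects = NULL,
                          noise = c("proportional", "additive"),
                          additive_sd = NULL,
                          boundary_guard = 6,
                          seed = 20230301L) {
  analyte <- match.arg(analyte)
  noise <- match.arg(noise)
  defaults <- list(
    Cr  = list(counts = c(34L, 56L, 15L), bounds = c(0.7, 1.7), range = c(0.3, 8)),
    BUN = list(counts = c(62L, 22L, 21L), bounds = c(20, 30), range = c(4, 80))
  )[[analyte]]
  n_subjects <- as.integer(n_subjects)
  group_counts <- as.integer(group_counts %||%
    if (n_subjects == 105L) defaults$counts
    else round(defaults$counts * n_subjects / 105))
  # rounding may leave a remainder; absorb it into the largest group
  if (sum(group_counts) != n_subjects)
    group_counts[which.max(group_counts)] <-
      group_counts[which.max(group_counts)] + n_subjects - sum(group_counts)
  p <- structure(list(
    analyte = analyte,
    n_subjects = n_subjects,
    group_counts = group_counts,
    subinterval_bounds = subinterval_bounds %||% defaults$bounds,
    concentration_range = concentration_range %||% defaults$range,
    specimen_effects = specimen_effects %||% list(
      `H-WB` = c(slope = 1, intercept = 0),
      serum  = c(slope = 1, intercept = 0),
      `C-WB` = c(slope = 1, intercept = 0)
    ),
    replicate_cv = replicate_cv %||%
      c(`H-WB` = 2, serum = 2, `C-WB` = 2),
    system = system,
    system_effects = system_effects,
    noise = noise,
    additive_sd = additive_sd,
    boundary_guard = boundary_guard,
    seed = as.integer(seed)
  ), class = "cohort_params")
  if (p$n_subjects < 3) stop("n_subjects must be >= 3", call. = FALSE)
  if (length(p$group_counts) != 3 || any(p$group_counts < 0) ||
      sum(p$group_counts) != p$n_subjects)
    stop("config error: group_counts must be three nonnegative counts summing to n_subjects",
         call. = FALSE)
  if (any(vapply(p$specimen_effects, function(e) e[[1]] <= 0, logical(1))))
    stop("specimen slopes must be > 0", call. = FALSE)
  if (any(p$replicate_cv < 0)) stop("replicate_cv must be >= 0", call. = FALSE)
  if (p$noise == "additive" && is.null(p$additive_sd))
    stop("additive noise requires additive_sd", call. = FALSE)
  p
}

#' Preset cohort parameters with realistic specimen biases
#'
#' `"cr-study"`: creatinine with serum slope 1.00 / intercept 0 and
#' citrated-whole-blood slope 0.89 / intercept -0.01 mg/dL relative to
#' heparinized whole blood. `"bun-study"`: BUN with serum (0.98, -1.12) and
#' C-WB (0.83, -0.18).
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [cohort_params()].
#' @return A `"cohort_params"`.
#' @export
preset_cohort <- function(name = c("cr-study", "bun-study"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    "cr-study" = list(
      analyte = "Cr",
      specimen_effects = list(
        `H-WB` = c(slope = 1, intercept = 0),
        serum  = c(slope = 1.00, intercept = 0),
        `C-WB` = c(slope = 0.89, intercept = -0.01)
      )
    ),
    "bun-study" = list(
      analyte = "BUN",
      specimen_effects = list(
        `H-WB` = c(slope = 1, intercept = 0),
        serum  = c(slope = 0.98, intercept = -1.12),
        `C-WB` = c(slope = 0.83, intercept = -0.18)
      )
    )
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_params, args)
}

# log-uniform draw on (lo, hi)
rloguniform <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Generate a synthetic paired-duplicate cohort
#'
#' For each subject a true primary-specimen concentration is drawn from the
#' subinterval mixture; each specimen's latent value is
#' `slope * c + intercept`; each replicate multiplies the latent value by
#' `(1 + eps)`, `eps ~ Normal(0, (cv/100)^2)` (or adds
#' `Normal(0, additive_sd^2)` in additive mode), redrawn if the result is
#' not positive. Two replicates per specimen; byte-identical output for the
#' same seed.
#'
#' @param params A [cohort_params()].
#' @return A validated measurement tibble (see [read_measurements()]) with
#'   attributes `"truth"` (tibble of `subject_id`, `true_value`, `group`)
#'   and `"params"`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  withr::with_seed(p$seed, {
    b <- p$subinterval_bounds
    rng <- p$concentration_range
    cv_max <- max(p$replicate_cv)
    guard <- 1 + p$boundary_guard * (cv_max / 100) / sqrt(2)
    intervals <- list(
      low  = c(rng[1], b[1] / guard),
      mid  = c(b[1] * guard, b[2] / guard),
      high = c(b[2] * guard, rng[2])
    )
    if (any(vapply(intervals, function(iv) iv[1] >= iv[2], logical(1))))
      stop("config error: boundary guard leaves an empty subinterval; ",
           "widen concentration_range or reduce replicate_cv", call. = FALSE)
    groups <- rep(c("low", "mid", "high"), times = p$group_counts)
    conc <- unlist(lapply(c("low", "mid", "high"), function(g) {
      iv <- intervals[[g]]
      rloguniform(p$group_counts[[match(g, c("low", "mid", "high"))]], iv[1], iv[2])
    }), use.names = FALSE)
    subjects <- sprintf("S%03d", seq_len(p$n_subjects))
    truth <- tibble::tibble(subject_id = subjects, true_value = conc,
                            group = factor(groups, levels = c("low", "mid", "high")))

    noisy_replicate <- function(latent, cv, add_sd) {
      vapply(latent, function(mu) {
        repeat {
          v <- if (p$noise == "proportional")
            mu * (1 + stats::rnorm(1, 0, cv / 100))
          else
            mu + stats::rnorm(1, 0, add_sd)
          if (v > 0) return(v)
        }
      }, numeric(1))
    }

    emit <- function(system, specimen, effect, cv, add_sd) {
      latent <- effect[[1]] * conc + effect[[2]]
      if (any(latent <= 0))
        stop("config error: specimen effect drives latent values nonpositive",
             call. = FALSE)
      do.call(rbind, lapply(c(1L, 2L), function(r) {
        data.frame(subject_id = subjects, analyte = p$analyte, system = system,
                   specimen = specimen, replicate = r,
                   value = noisy_replicate(latent, cv, add_sd),
                   stringsAsFactors = FALSE)
      }))
    }

    rows <- list()
    for (sp in names(p$specimen_effects)) {
      rows[[length(rows) + 1L]] <- emit(
        p$system, sp, p$specimen_effects[[sp]],
        p$replicate_cv[[sp]], p$additive_sd[[sp]] %||% NA_real_)
    }
    for (sys in names(p$system_effects)) {
      cv <- p$replicate_cv[["serum"]] %||% cv_max
      rows[[length(rows) + 1L]] <- emit(
        sys, "serum", p$system_effects[[sys]], cv,
        p$additive_sd[["serum"]] %||% NA_real_)
    }
    out <- validate_measurements(do.call(rbind, rows), source = "synthetic cohort")
    attr(out, "truth") <- truth
    attr(out, "params") <- p
    out
  })
}

#' Compare generator truth with pipeline estimates
#'
#' Parameter-recovery bookkeeping: tabulates the generator's true specimen
#' slopes, intercepts and replicate CVs against the fitted Passing-Bablok
#' coefficients and duplicate-SD %CVs from a [run_pipeline()] result on the
#' same cohort, flagging estimates outside the stated tolerances.
#'
#' @param params The [cohort_params()] used to generate the cohort.
#' @param result The [run_pipeline()] output for that cohort.
#' @param slope_tol,intercept_tol,cv_tol Absolute flagging tolerances
#'   (dimensionless, mg/dL, percentage points).
#' @return Tibble with columns `specimen`, `parameter`, `truth`, `estimate`,
#'   `abs_error`, `within_tol`.
#' @export
recovery_report <- function(params, result, slope_tol = 0.05,
                            intercept_tol = 0.1, cv_tol = 0.5) {
  stopifnot(inherits(params, "cohort_params"), inherits(result, "pipeline_result"))
  fits <- result$specimen_fits
  fits <- fits[fits$analyte == params$analyte, ]
  if (nrow(fits) == 0)
    stop("alignment error: result contains no specimen fits for analyte ",
         params$analyte, call. = FALSE)
  # use the (narrow) middle subinterval: the pooled SD/mean %CV over a wide
  # skewed range overstates a constant replicate CV
  prec <- result$precision
  prec <- prec[prec$analyte == params$analyte & prec$subinterval == "mid", ]
  rows <- list()
  primary <- result$provenance$config$primary_specimen
  for (sp in setdiff(names(params$specimen_effects), primary)) {
    f <- fits[fits$specimen == sp, ]
    if (nrow(f) != 1)
      stop("alignment error: no unique fit for specimen ", sp, call. = FALSE)
    eff <- params$specimen_effects[[sp]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      specimen = sp,
      parameter = c("slope", "intercept"),
      truth = c(eff[[1]], eff[[2]]),
      estimate = c(f$slope, f$intercept),
      tol = c(slope_tol, intercept_tol)
    )
  }
  for (sp in names(params$replicate_cv)) {
    pr <- prec[prec$specimen == sp, ]
    if (nrow(pr) != 1 || !is.finite(pr$cv_percent)) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      specimen = sp, parameter = "replicate_cv",
      truth = params$replicate_cv[[sp]], estimate = pr$cv_percent,
      tol = cv_tol
    )
  }
  out <- do.call(rbind, rows)
  out$abs_error <- abs(out$estimate - out$truth)
  out$within_tol <- out$abs_error <= out$tol
  out$tol <- NULL
  out
}
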