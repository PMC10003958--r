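# End-to-end orchestration: analyzer comparison -> specimen equivalence ->
# subinterval precision, returning report-shaped tables with provenance.
# Every number in the tables is produced by the module-level API; the
# pipeline only arranges calls and rows.

# deterministic per-comparison seed derived from the run seed (kept < 2^31)
derive_seed <- function(seed, k) as.integer((as.numeric(seed) + 7919 * k) %% 2147483647)

#' Run the full specimen-equivalence analysis
#'
#' Executes, per analyte present in the data:
#' \enumerate{
#'   \item analyzer comparison: the device under test on the primary
#'     specimen versus every other measuring system (each on its own
#'     specimen), with Passing-Bablok regression, Pearson correlation,
#'     Bland-Altman agreement, and an omnibus one-way ANOVA across systems;
#'   \item specimen equivalence on the device under test: every candidate
#'     specimen versus the primary specimen, with bootstrap-CI regression
#'     and systematic differences at the three medical decision levels
#'     judged against TEa, plus an omnibus ANOVA across specimens;
#'   \item subinterval precision: duplicate-based SD, %CV, and
#'     candidate/primary SD ratios with paired-bootstrap CIs and the
#'     three-tier acceptance decision, in subintervals defined by the
#'     primary-specimen duplicate means (plus a pooled "total" row).
#' }
#' Regression and agreement use the per-subject duplicate mean; subjects
#' with a single replicate keep that value there but are excluded from
#' duplicate-SD statistics. Deterministic given `config$random_seed`.
#'
#' @param measurements Validated measurement tibble
#'   (from [read_measurements()] or [generate_cohort()]).
#' @param config An [analysis_config()].
#' @param specs Named list of [performance_spec()] per analyte.
#' @return Object of class `"pipeline_result"`: tibbles `comparison`,
#'   `specimen_fits`, `bias`, `precision`, `anova`, and a `provenance` list
#'   (config, specs, seed, package version, input digest).
#' @export
run_pipeline <- function(measurements, config = analysis_config(),
                         specs = default_performance_specs()) {
  m <- validate_measurements(measurements, source = "pipeline input")
  pairs <- replicate_pairs(m)
  its <- config$bootstrap_iterations
  cl <- config$ci_level
  sk <- 0L

  comparison <- list(); fits_tab <- list(); bias <- list()
  precision <- list(); anova_tab <- list()

  for (an in intersect(ANALYTES, unique(pairs$analyte))) {
    pa <- pairs[pairs$analyte == an, ]
    spec <- specs[[an]]
    cand <- pa[pa$system == config$candidate_system &
                 pa$specimen == config$primary_specimen, ]
    if (nrow(cand) == 0)
      stop("config error: no measurements for pairing (",
           config$candidate_system, ", ", config$primary_specimen, ", ", an, ")",
           call. = FALSE)

    ## (a) analyzer-vs-analyzer comparison on each comparator's specimen
    other_systems <- setdiff(unique(pa$system), config$candidate_system)
    groups <- list()
    groups[[config$candidate_system]] <- cand$pair_mean
    for (sys in other_systems) {
      ps <- pa[pa$system == sys, ]
      if (length(unique(ps$specimen)) != 1)
        stop("config error: ambiguous specimen for comparator system ", sys,
             call. = FALSE)
      idx <- match(cand$subject_id, ps$subject_id)
      if (anyNA(idx))
        stop("config error: comparator system ", sys,
             " lacks subjects present on the candidate system", call. = FALSE)
      x <- ps$pair_mean[idx]   # comparator
      y <- cand$pair_mean      # device under test
      sk <- sk + 1L
      fit <- pb_regression(x, y, iterations = its,
                           seed = derive_seed(config$random_seed, sk),
                           ci_level = cl, comparator_label = sys,
                           candidate_label = config$candidate_system)
      ba <- bland_altman(x, y, ci_level = cl,
                         loa_multiplier = config$loa_multiplier)
      groups[[sys]] <- x
      comparison[[length(comparison) + 1L]] <- tibble::tibble(
        analyte = an, candidate_system = config$candidate_system,
        comparator_system = sys, n = fit$n,
        candidate_mean = mean(y), comparator_mean = mean(x),
        mean_difference = ba$mean_difference,
        mean_difference_ci_low = ba$mean_difference_ci[1],
        mean_difference_ci_high = ba$mean_difference_ci[2],
        mean_pct_difference = ba$mean_percent_difference,
        loa_low = ba$loa_low, loa_high = ba$loa_high,
        pearson_r = fit$pearson_r, slope = fit$slope,
        slope_ci_low = fit$slope_ci[1], slope_ci_high = fit$slope_ci[2],
        intercept = fit$intercept,
        intercept_ci_low = fit$intercept_ci[1],
        intercept_ci_high = fit$intercept_ci[2]
      )
    }
    if (length(groups) >= 2) {
      av <- one_way_anova(groups)
      anova_tab[[length(anova_tab) + 1L]] <- tibble::tibble(
        analyte = an, axis = "systems", n_groups = length(groups),
        f_statistic = av$f_statistic, p_value = av$p_value
      )
    }

    ## (b) specimen equivalence on the device under test
    dev <- pa[pa$system == config$candidate_system, ]
    cand_specimens <- setdiff(unique(dev$specimen), config$primary_specimen)
    spec_groups <- list()
    spec_groups[[config$primary_specimen]] <- cand$pair_mean
    for (sp in cand_specimens) {
      ps <- dev[dev$specimen == sp, ]
      idx <- match(cand$subject_id, ps$subject_id)
      if (anyNA(idx))
        stop("config error: specimen ", sp,
             " lacks subjects present on the primary specimen", call. = FALSE)
      x <- cand$pair_mean       # primary specimen (comparator)
      y <- ps$pair_mean[idx]    # candidate specimen
      sk <- sk + 1L
      fit <- pb_regression(x, y, iterations = its,
                           seed = derive_seed(config$random_seed, sk),
                           ci_level = cl,
                           comparator_label = config$primary_specimen,
                           candidate_label = sp)
      ba <- bland_altman(x, y, ci_level = cl,
                         loa_multiplier = config$loa_multiplier)
      spec_groups[[sp]] <- y
      fits_tab[[length(fits_tab) + 1L]] <- tibble::tibble(
        analyte = an, specimen = sp, n = fit$n,
        slope = fit$slope, slope_ci_low = fit$slope_ci[1],
        slope_ci_high = fit$slope_ci[2], intercept = fit$intercept,
        intercept_ci_low = fit$intercept_ci[1],
        intercept_ci_high = fit$intercept_ci[2],
        pearson_r = fit$pearson_r,
        mean_difference = ba$mean_difference,
        mean_difference_ci_low = ba$mean_difference_ci[1],
        mean_difference_ci_high = ba$mean_difference_ci[2],
        mean_pct_difference = ba$mean_percent_difference,
        loa_low = ba$loa_low, loa_high = ba$loa_high
      )
      for (i in seq_along(spec$decision_levels)) {
        sd_row <- systematic_difference(fit, spec$decision_levels[i],
                                        spec$tea_percent, ci_level = cl)
        bias[[length(bias) + 1L]] <- tibble::tibble(
          analyte = an, specimen = sp,
          level_label = c("low", "medium", "high")[i], sd_row
        )
      }
    }
    if (length(spec_groups) >= 2) {
      av <- one_way_anova(spec_groups)
      anova_tab[[length(anova_tab) + 1L]] <- tibble::tibble(
        analyte = an, axis = "specimens", n_groups = length(spec_groups),
        f_statistic = av$f_statistic, p_value = av$p_value
      )
    }

    ## (c) subinterval precision and SD ratios
    complete <- cand[!is.na(cand$value_1) & !is.na(cand$value_2), ]
    grp <- assign_subintervals(complete$pair_mean, spec$subinterval_bounds)
    labels <- subinterval_labels(spec$subinterval_bounds)
    members <- c(lapply(stats::setNames(nm = levels(grp)),
                        function(g) complete$subject_id[grp == g]),
                 list(total = complete$subject_id))
    all_specimens <- unique(dev$specimen)
    for (g in names(members)) {
      subj <- members[[g]]
      if (length(subj) == 0) {
        warning("empty subinterval '", labels[[g]], "' for ", an,
                "; reported as missing", call. = FALSE)
        for (sp in all_specimens)
          precision[[length(precision) + 1L]] <- tibble::tibble(
            analyte = an, subinterval = g, range = labels[[g]], specimen = sp,
            n_subjects = 0L, mean = NA_real_, sd = NA_real_,
            cv_percent = NA_real_, sd_ratio = NA_real_,
            ratio_ci_low = NA_real_, ratio_ci_high = NA_real_,
            verdict = NA_character_, criterion = NA_character_
          )
        next
      }
      prim_g <- cand[match(subj, cand$subject_id), ]
      for (sp in all_specimens) {
        ps <- dev[dev$specimen == sp, ]
        rows <- ps[match(subj, ps$subject_id), ]
        rows <- rows[!is.na(rows$value_1) & !is.na(rows$value_2), ]
        ds <- duplicate_sd(rows$value_1, rows$value_2)
        mn <- mean(c(rows$value_1, rows$value_2))
        cv <- percent_cv(ds$sd, mn)
        ratio <- ci <- c(NA_real_, NA_real_)
        verdict <- criterion <- NA_character_
        ratio_val <- NA_real_
        if (!identical(sp, config$primary_specimen)) {
          sk2 <- derive_seed(config$random_seed,
                             1000L + 13L * match(g, names(members)) +
                               131L * match(sp, all_specimens) +
                               7L * match(an, ANALYTES))
          sr <- tryCatch(
            sd_ratio_with_ci(
              rows[c("subject_id", "value_1", "value_2")],
              prim_g[match(rows$subject_id, prim_g$subject_id),
                     c("subject_id", "value_1", "value_2")],
              iterations = its, seed = sk2, ci_level = cl),
            error = function(e) {
              warning("SD ratio undefined for ", sp, " in subinterval '",
                      labels[[g]], "': ", conditionMessage(e), call. = FALSE)
              NULL
            })
          if (!is.null(sr)) {
            dec <- acceptance_decision(sr$ratio, sr$ratio_ci, cv,
                                       spec$allowable_cv_percent)
            ratio_val <- sr$ratio
            ci <- sr$ratio_ci
            verdict <- dec$verdict
            criterion <- dec$criterion
          }
        }
        precision[[length(precision) + 1L]] <- tibble::tibble(
          analyte = an, subinterval = g, range = labels[[g]], specimen = sp,
          n_subjects = ds$k, mean = mn, sd = ds$sd, cv_percent = cv,
          sd_ratio = ratio_val, ratio_ci_low = ci[1], ratio_ci_high = ci[2],
          verdict = verdict, criterion = criterion
        )
      }
    }
  }

  bind <- function(lst) if (length(lst)) do.call(rbind, lst) else tibble::tibble()
  structure(list(
    comparison = bind(comparison),
    specimen_fits = bind(fits_tab),
    bias = bind(bias),
    precision = bind(precision),
    anova = bind(anova_tab),
    provenance = list(
      config = unclass(config),
      specs = lapply(specs, unclass),
      package_version = as.character(utils::packageVersion("specimeq")),
      input_digest = input_digest(m),
      n_rows = nrow(m)
    )
  ), class = "pipeline_result")
}

# order-independent lightweight digest of the input table
input_digest <- function(m) {
  s <- paste(m$subject_id, m$analyte, m$system, m$specimen, m$replicate,
             format(m$value, digits = 15), sep = "|")
  s <- sort(s)
  sum((seq_along(s) * as.numeric(vapply(s, function(z)
    sum(utf8ToInt(z)), numeric(1)))) %% 2147483647) %% 2147483647
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Specimen-equivalence pipeline result\n")
  cat("  comparison rows:", nrow(x$comparison),
      "| specimen fits:", nrow(x$specimen_fits),
      "| bias rows:", nrow(x$bias),
      "| precision rows:", nrow(x$precision), "\n")
  if (nrow(x$bias)) {
    bad <- x$bias[x$bias$verdict == "inequivalent", ]
    cat("  inequivalent (specimen, level):",
        if (nrow(bad)) paste(bad$specimen, bad$level_label, collapse = "; ")
        else "none", "\n")
  }
  if (nrow(x$precision)) {
    un <- x$precision[!is.na(x$precision$verdict) &
                        x$precision$verdict == "unacceptable", ]
    cat("  unacceptable SD ratios:",
        if (nrow(un)) paste(un$specimen, un$range, collapse = "; ") else "none",
        "\n")
  }
  invisible(x)
}
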