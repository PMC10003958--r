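#' specimeq: specimen equivalence and method comparison for POC Cr/BUN
#'
#' Tools for comparing a point-of-care analyzer against reference chemistry
#' analyzers and for assessing whether candidate specimen types (serum,
#' citrated whole blood) are equivalent to the primary specimen (heparinized
#' whole blood) for creatinine (Cr) and blood urea nitrogen (BUN), following
#' the CLSI EP09/EP35 framework: Passing-Bablok regression, Bland-Altman
#' agreement, systematic differences at medical decision levels versus total
#' allowable error, and duplicate-based imprecision with SD-ratio acceptance.
#'
#' All concentrations are in mg/dL throughout; there is no unit-conversion
#' layer.
#'
#' @keywords internal
"_PACKAGE"

# Canonical long-format measurement columns: one replicate per row.
MEASUREMENT_COLS <- c("subject_id", "analyte", "system", "specimen",
                      "replicate", "value")
ANALYTES  <- c("Cr", "BUN")
SPECIMENS <- c("H-WB", "serum", "C-WB")

#' Performance specification for an analyte
#'
#' Bundles the quantities against which equivalence is judged: the three
#' medical decision levels, the total allowable error (TEa, as a percent of
#' the decision level), the allowable imprecision (%CV), and the two cutoffs
#' splitting the measuring range into low / mid / high subintervals used for
#' the duplicate-SD comparison.
#'
#' Defaults are the desirable specifications from the EFLM biological
#' variation database: Cr decision levels 0.6/1.6/6.0 mg/dL, TEa 7.4%,
#' allowable CV 2.3%, subinterval cutoffs 0.7 and 1.7 mg/dL; BUN decision
#' levels 6/26/50 mg/dL, TEa 17.8%, allowable CV 7.0%, cutoffs 20 and 30
#' mg/dL.
#'
#' @param analyte `"Cr"` or `"BUN"`.
#' @param decision_levels Strictly increasing numeric triple (mg/dL).
#' @param tea_percent Total allowable error at a decision level, in percent.
#' @param allowable_cv_percent Allowable imprecision, in percent.
#' @param subinterval_bounds Strictly increasing numeric pair (mg/dL); the
#'   middle subinterval is closed on both ends.
#' @return A list of class `"performance_spec"`.
#' @export
#' @examples
#' performance_spec("Cr")
performance_spec <- function(analyte = c("Cr", "BUN"),
                             decision_levels = NULL,
                             tea_percent = NULL,
                             allowable_cv_percent = NULL,
                             subinterval_bounds = NULL) {
  analyte <- match.arg(analyte)
  defaults <- list(
    Cr  = list(decision_levels = c(0.6, 1.6, 6.0), tea_percent = 7.4,
               allowable_cv_percent = 2.3, subinterval_bounds = c(0.7, 1.7)),
    BUN = list(decision_levels = c(6, 26, 50), tea_percent = 17.8,
               allowable_cv_percent = 7.0, subinterval_bounds = c(20, 30))
  )[[analyte]]
  spec <- list(
    analyte              = analyte,
    decision_levels      = decision_levels %||% defaults$decision_levels,
    tea_percent          = tea_percent %||% defaults$tea_percent,
    allowable_cv_percent = allowable_cv_percent %||% defaults$allowable_cv_percent,
    subinterval_bounds   = subinterval_bounds %||% defaults$subinterval_bounds
  )
  if (length(spec$decision_levels) != 3L || any(diff(spec$decision_levels) <= 0))
    stop("decision_levels must be a strictly increasing triple", call. = FALSE)
  if (spec$tea_percent <= 0) stop("tea_percent must be > 0", call. = FALSE)
  if (spec$allowable_cv_percent <= 0)
    stop("allowable_cv_percent must be > 0", call. = FALSE)
  if (length(spec$subinterval_bounds) != 2L || diff(spec$subinterval_bounds) <= 0)
    stop("subinterval_bounds must be a strictly increasing pair", call. = FALSE)
  structure(spec, class = "performance_spec")
}

#' Default performance specifications for both analytes
#'
#' @return A named list with elements `Cr` and `BUN`, each a
#'   [performance_spec()].
#' @export
default_performance_specs <- function() {
  list(Cr = performance_spec("Cr"), BUN = performance_spec("BUN"))
}

#' Analysis configuration
#'
#' Run-level settings shared by all pipeline stages.
#'
#' @param primary_specimen Primary (manufacturer-validated) specimen type;
#'   candidate specimens are judged against it. Default `"H-WB"`.
#' @param candidate_system Identifier of the device under test (the analyzer
#'   whose specimens are being compared). Default `"ABL90"`.
#' @param bootstrap_iterations Resamples for every bootstrap interval
#'   (default 1000).
#' @param random_seed Integer seed governing all bootstrap resampling.
#' @param ci_level Two-sided confidence level in (0, 1); default 0.95.
#' @param rounding_digits_report Digits used when writing reports; internal
#'   computation is always full precision and rounding happens only in
#'   [write_report()].
#' @param loa_multiplier Multiple of the SD of differences used for
#'   Bland-Altman limits of agreement (default 2).
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(primary_specimen = "H-WB",
                            candidate_system = "ABL90",
                            bootstrap_iterations = 1000L,
                            random_seed = 20230301L,
                            ci_level = 0.95,
                            rounding_digits_report = 2L,
                            loa_multiplier = 2) {
  if (bootstrap_iterations < 1) stop("bootstrap_iterations must be >= 1", call. = FALSE)
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must be in (0, 1)", call. = FALSE)
  structure(list(
    primary_specimen = primary_specimen,
    candidate_system = candidate_system,
    bootstrap_iterations = as.integer(bootstrap_iterations),
    random_seed = as.integer(random_seed),
    ci_level = ci_level,
    rounding_digits_report = as.integer(rounding_digits_report),
    loa_multiplier = loa_multiplier
  ), class = "analysis_config")
}

#' Read an analysis configuration from JSON or YAML
#'
#' The file maps onto [analysis_config()] fields, with an optional
#' `performance_specs` entry holding per-analyte overrides of
#' [performance_spec()] fields.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with elements `config` ([analysis_config()]) and `specs`
#'   (named list of [performance_spec()]).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported config format: .", ext, call. = FALSE)
  )
  spec_over <- raw$performance_specs
  raw$performance_specs <- NULL
  cfg <- do.call(analysis_config, raw)
  specs <- default_performance_specs()
  for (an in names(spec_over)) {
    specs[[an]] <- do.call(performance_spec, c(list(analyte = an), spec_over[[an]]))
  }
  list(config = cfg, specs = specs)
}

#' Read paired measurements from a long-format CSV
#'
#' The canonical input is one replicate per row with columns `subject_id`,
#' `analyte`, `system`, `specimen`, `replicate`, `value` (header required,
#' UTF-8, `.` decimal separator, values in mg/dL). All records are validated;
#' any violation is an error carrying row-level diagnostics.
#'
#' @param path CSV file path.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(subject_id = "patient", value = "conc")`.
#' @return A tibble of validated measurements.
#' @export
read_measurements <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(df))
        stop("schema error: mapped column '", src, "' absent from ", path, call. = FALSE)
      names(df)[names(df) == src] <- canon
    }
  }
  validate_measurements(df, source = path)
}

#' Validate a measurement table
#'
#' Enforces the data-model invariants: required columns present, known
#' analyte and specimen codes, replicate index in \{1, 2\}, strictly positive
#' finite values, and at most one row per
#' (subject, analyte, system, specimen, replicate) with no more than two
#' replicates per key.
#'
#' @param df A data frame of measurements.
#' @param source Label used in diagnostics (e.g. the file path).
#' @return The validated measurements as a tibble.
#' @export
validate_measurements <- function(df, source = "measurements") {
  missing <- setdiff(MEASUREMENT_COLS, names(df))
  if (length(missing))
    stop("schema error in ", source, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[MEASUREMENT_COLS]
  df$value <- suppressWarnings(as.numeric(df$value))
  df$replicate <- suppressWarnings(as.integer(df$replicate))
  problems <- character()
  row_ids <- seq_len(nrow(df))
  bad_val <- which(!is.finite(df$value) | df$value <= 0)
  if (length(bad_val))
    problems <- c(problems, paste0(
      "row ", bad_val, ": value must be a positive finite number (mg/dL)"))
  bad_rep <- which(!df$replicate %in% c(1L, 2L))
  if (length(bad_rep))
    problems <- c(problems, paste0("row ", bad_rep, ": replicate must be 1 or 2"))
  bad_an <- which(!df$analyte %in% ANALYTES)
  if (length(bad_an))
    problems <- c(problems, paste0(
      "row ", bad_an, ": analyte must be one of ", paste(ANALYTES, collapse = "/")))
  bad_sp <- which(!df$specimen %in% SPECIMENS)
  if (length(bad_sp))
    problems <- c(problems, paste0(
      "row ", bad_sp, ": specimen must be one of ", paste(SPECIMENS, collapse = "/")))
  key <- interaction(df$subject_id, df$analyte, df$system, df$specimen,
                     df$replicate, drop = TRUE)
  dup <- duplicated(key)
  if (any(dup))
    problems <- c(problems, paste0(
      "row ", row_ids[dup], ": duplicate replicate index for key (",
      df$subject_id[dup], ", ", df$analyte[dup], ", ", df$system[dup], ", ",
      df$specimen[dup], ", replicate ", df$replicate[dup], ")"))
  grp <- interaction(df$subject_id, df$analyte, df$system, df$specimen, drop = TRUE)
  n_rep <- table(grp)
  over <- names(n_rep)[n_rep > 2]
  if (length(over))
    problems <- c(problems, paste0(
      "duplication error: more than two replicates for key ", over))
  if (length(problems))
    stop("validation of ", source, " failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  tibble::as_tibble(df)
}

#' Collapse measurements to one row per replicate pair
#'
#' Pivots the long measurement table to one row per
#' (subject, analyte, system, specimen) with `value_1`, `value_2` and their
#' mean. Subjects missing replicate 2 are retained with `value_2 = NA` (and a
#' warning): they contribute their single replicate to regression and
#' agreement but are excluded from duplicate-SD analysis.
#'
#' @param measurements Validated measurement tibble.
#' @return A tibble with columns `subject_id`, `analyte`, `system`,
#'   `specimen`, `value_1`, `value_2`, `pair_mean`.
#' @export
replicate_pairs <- function(measurements) {
  m <- measurements
  key <- interaction(m$subject_id, m$analyte, m$system, m$specimen, drop = TRUE)
  first <- !duplicated(key)
  out <- tibble::tibble(
    subject_id = m$subject_id[first], analyte = m$analyte[first],
    system = m$system[first], specimen = m$specimen[first],
    value_1 = NA_real_, value_2 = NA_real_
  )
  idx <- match(key, key[first])
  for (r in c(1L, 2L)) {
    sel <- m$replicate == r
    out[[paste0("value_", r)]][idx[sel]] <- m$value[sel]
  }
  n_incomplete <- sum(is.na(out$value_1) | is.na(out$value_2))
  if (n_incomplete > 0)
    warning(n_incomplete, " replicate pair(s) incomplete; affected subjects are ",
            "excluded from duplicate-SD analysis but keep their single ",
            "replicate elsewhere", call. = FALSE)
  out$pair_mean <- rowMeans(cbind(out$value_1, out$value_2), na.rm = TRUE)
  out
}

#' Write measurements to the canonical CSV format
#'
#' @param measurements Measurement tibble.
#' @param path Output CSV path.
#' @export
write_measurements <- function(measurements, path) {
  utils::write.csv(as.data.frame(measurements)[MEASUREMENT_COLS], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Write pipeline results as machine-readable report tables
#'
#' Emits the comparison, regression/bias, precision and ANOVA tables of a
#' [run_pipeline()] result. Values are rounded here and only here (to
#' `digits`); everything upstream is full precision.
#'
#' @param results A `pipeline_result` (from [run_pipeline()]) or a named list
#'   of data frames.
#' @param path Output directory for `format = "csv"` (one file per table plus
#'   `provenance.json`), or a single file path for `format = "json"`.
#' @param format `"csv"` or `"json"`.
#' @param digits Rounding digits; defaults to the result's configured
#'   `rounding_digits_report` (or 2).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, path, format = c("csv", "json"), digits = NULL) {
  format <- match.arg(format)
  provenance <- results$provenance
  tables <- results[setdiff(names(results), "provenance")]
  tables <- Filter(is.data.frame, tables)
  digits <- digits %||% provenance$config$rounding_digits_report %||% 2L
  tables <- lapply(tables, round_df, digits = digits)
  if (format == "csv") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    paths <- character()
    for (nm in names(tables)) {
      f <- file.path(path, paste0(nm, ".csv"))
      utils::write.csv(as.data.frame(tables[[nm]]), f, row.names = FALSE,
                       fileEncoding = "UTF-8")
      paths <- c(paths, f)
    }
    if (!is.null(provenance)) {
      f <- file.path(path, "provenance.json")
      jsonlite::write_json(provenance, f, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
      paths <- c(paths, f)
    }
    invisible(paths)
  } else {
    payload <- c(tables, if (!is.null(provenance)) list(provenance = provenance))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE, null = "null")
    invisible(path)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.performance_spec <- function(x, ...) {
  cat("Performance specification -", x$analyte, "\n")
  cat("  decision levels (mg/dL):", paste(x$decision_levels, collapse = ", "), "\n")
  cat("  TEa:", x$tea_percent, "%  allowable CV:", x$allowable_cv_percent, "%\n")
  cat("  subintervals: <", x$subinterval_bounds[1], ", [",
      x$subinterval_bounds[1], ", ", x$subinterval_bounds[2], "], >",
      x$subinterval_bounds[2], " mg/dL\n", sep = "")
  invisible(x)
}
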