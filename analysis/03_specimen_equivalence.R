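#!/usr/bin/env Rscript
# Narrate the specimen-equivalence stage: Passing-Bablok coefficients for
# each candidate specimen against heparinized whole blood, and the
# systematic differences at the medical decision levels judged against TEa
# (7.4% Cr, 17.8% BUN). Reads the tables written by 02_run_pipeline.R.

fits <- read.csv("results/tables/specimen_fits.csv", check.names = FALSE)
bias <- read.csv("results/tables/bias.csv", check.names = FALSE)

message("Candidate-specimen regressions versus H-WB:")
for (i in seq_len(nrow(fits))) {
  f <- fits[i, ]
  message(sprintf(
    "  %-3s %-5s: slope %.2f (%.2f, %.2f), intercept %.2f (%.2f, %.2f), r %.3f",
    f$analyte, f$specimen, f$slope, f$slope_ci_low, f$slope_ci_high,
    f$intercept, f$intercept_ci_low, f$intercept_ci_high, f$pearson_r))
}

message("\nSystematic differences at the medical decision levels:")
for (i in seq_len(nrow(bias))) {
  b <- bias[i, ]
  message(sprintf(
    "  %-3s %-5s @ %4.1f mg/dL: %+0.2f mg/dL (%+0.2f%%), TEa %.1f%% -> %s",
    b$analyte, b$specimen, b$decision_level, b$systematic_difference,
    b$systematic_difference_pct, b$tea_percent, b$verdict))
}

ineq <- bias[bias$verdict == "inequivalent", ]
ok <- bias[bias$verdict == "acceptable", ]
message(sprintf(
  "\nFinding: %d of %d level checks acceptable; inequivalent combinations: %s",
  nrow(ok), nrow(bias),
  if (nrow(ineq)) paste(unique(paste(ineq$analyte, ineq$specimen)), collapse = ", ")
  else "none"))
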