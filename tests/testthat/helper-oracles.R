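# Independent oracles, written deliberately as plain loops so they share no
# code path with the package implementation.

# Exhaustive Passing-Bablok oracle: enumerate all pairwise slopes with
# explicit loops, apply the exclusion rules (x ties dropped, slopes exactly
# -1 dropped), take the shifted median with offset K = #(slopes < -1)
# (indices clamped to the valid range), intercept = median(y - b x).
pb_oracle <- function(x, y) {
  n <- length(x)
  slopes <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]
      if (dx == 0) next
      s <- (y[j] - y[i]) / dx
      if (s == -1) next
      slopes <- c(slopes, s)
    }
  }
  slopes <- sort(slopes)
  N <- length(slopes)
  K <- sum(slopes < -1)
  clamp <- function(k) min(max(k, 1), N)
  b <- if (N %% 2 == 1) {
    slopes[clamp((N + 1) %/% 2 + K)]
  } else {
    (slopes[clamp(N %/% 2 + K)] + slopes[clamp(N %/% 2 + 1 + K)]) / 2
  }
  central <- if (N %% 2 == 1) rep(slopes[clamp((N + 1) %/% 2 + K)], 2) else
    c(slopes[clamp(N %/% 2 + K)], slopes[clamp(N %/% 2 + 1 + K)])
  raw_idx <- if (N %% 2 == 1) (N + 1) %/% 2 + K else
    c(N %/% 2 + K, N %/% 2 + 1 + K)
  list(slope = b, intercept = median(y - b * x), n_slopes = N, K = K,
       central = central, clamped = any(raw_idx < 1 | raw_idx > N))
}

# Sort-and-index oracle for the rank CI: direct order-statistic lookup.
pb_rank_ci_oracle <- function(x, y, ci_level = 0.95) {
  n <- length(x)
  slopes <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]
      if (dx == 0) next
      s <- (y[j] - y[i]) / dx
      if (s == -1) next
      slopes <- c(slopes, s)
    }
  }
  slopes <- sort(slopes)
  N <- length(slopes)
  K <- sum(slopes < -1)
  C <- qnorm(1 - (1 - ci_level) / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - C) / 2)
  M2 <- N - M1 + 1
  c(slopes[M1 + K], slopes[M2 + K])
}

# Paired data with a known line and multiplicative noise on both axes.
make_pairs <- function(n, slope = 1, intercept = 0, cv = 0.02,
                       range = c(0.5, 5)) {
  cc <- exp(runif(n, log(range[1]), log(range[2])))
  x <- cc * (1 + rnorm(n, 0, cv))
  y <- (slope * cc + intercept) * (1 + rnorm(n, 0, cv))
  list(x = x, y = y)
}

# Small valid measurement table: one subject block in long format.
make_measurements <- function(values, subject = "S001", analyte = "Cr",
                              system = "ABL90", specimen = "H-WB") {
  data.frame(
    subject_id = subject, analyte = analyte, system = system,
    specimen = specimen, replicate = seq_along(values), value = values,
    stringsAsFactors = FALSE
  )
}
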