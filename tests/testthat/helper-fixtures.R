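# fixtures built in code; no data files

# a single-subject epoch series with the package's timestamp conventions
make_series <- function(counts, epoch_seconds = 30,
                        start = "2000-01-03 00:00:00", subject_id = "T01",
                        off_wrist = FALSE) {
  n <- length(counts)
  data.frame(
    subject_id = subject_id,
    timestamp = as.POSIXct(start, tz = "UTC") +
      (seq_len(n) - 1L) * epoch_seconds,
    activity_count = counts,
    off_wrist = rep_len(off_wrist, n),
    stringsAsFactors = FALSE)
}

# deterministic latent-to-count transform used as an independent oracle for
# the generator (re-derived from first principles, not via package code)
oracle_count <- function(x) pmax(0, round(exp(x) - 1))

# noiseless config: every stochastic component switched off
noiseless_config <- function(...) {
  sim_config(subject_intercept_sd = 0, day_phase_jitter_sd = 0,
             noise_sd = 0, ...)
}

# a small profile matrix object without running the whole epoch pipeline
make_pm <- function(values, bin_minutes = 30, subject_id = "T01") {
  structure(list(subject_id = subject_id, bin_minutes = bin_minutes,
                 values = values,
                 dates = as.Date("2000-01-03") + seq_len(nrow(values)) - 1,
                 day_valid = rep(TRUE, nrow(values)), excluded = FALSE),
            class = "rar_profile_matrix")
}

# brute-force cosinor: profile the acrophase on a fine grid, solving the
# 2-parameter OLS (mesor, amplitude) in closed form for each candidate
grid_search_cosinor <- function(t, y, period = 24) {
  best <- list(sse = Inf)
  for (step in c(0.01, 1e-4)) {
    phis <- if (step == 0.01) seq(0, period - step, by = step) else
      seq(best$phi - 0.02, best$phi + 0.02, by = step)
    for (phi in phis) {
      z <- cos(2 * pi * (t - phi) / period)
      A <- sum((z - mean(z)) * (y - mean(y))) / sum((z - mean(z))^2)
      M <- mean(y) - A * mean(z)
      sse <- sum((y - M - A * z)^2)
      if (sse < best$sse) best <- list(sse = sse, phi = phi, A = A, M = M)
    }
  }
  if (best$A < 0) {  # negative amplitude = phase off by half a period
    best$A <- -best$A
    best$phi <- (best$phi + period / 2) %% period
  }
  best
}
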