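#' Log-transform epoch activity counts
#'
#' Applies the natural-log transform `log(AC + 1)` to every epoch's activity
#' count, adding a `log_activity` column. The +1 offset keeps zero counts
#' finite; natural log is used throughout the package.
#'
#' @param series data.frame with columns `timestamp`, `activity_count` and
#'   optionally `off_wrist` (a single subject's epoch series).
#' @return the same data.frame with a `log_activity` column appended.
#' @export
log_transform <- function(series) {
  ac <- series$activity_count
  bad <- which(is.na(ac) | ac < 0)
  if (length(bad))
    stop_stage("preprocessing", "negative or missing activity count at epoch ",
               bad[1], " (timestamp ", format(series$timestamp[bad[1]]), ")")
  series$log_activity <- log(ac + 1)
  series
}

#' Bin one subject's log-transformed epochs into daily profiles
#'
#' Averages `log_activity` within non-overlapping clock-time bins
#' (`1440 / bin_minutes` per day; 48 bins at the default 30 minutes),
#' separately for each calendar day. Days are anchored midnight-to-midnight
#' in the timestamps' clock time; bins are half-open `[start, end)`.
#' Off-wrist epochs are excluded; a cell with no wearable epochs is `NA`.
#'
#' @param series a single subject's epoch data.frame containing
#'   `log_activity` (see [log_transform()]); epochs must be regularly spaced.
#' @param bin_minutes bin width in minutes; must divide 1440.
#' @return an object of class `rar_profile_matrix`: list with `subject_id`,
#'   `bin_minutes`, `values` (days × bins matrix of mean log activity),
#'   `dates` (one per row), `day_valid` (all TRUE; see
#'   [filter_valid_days()]), and `excluded` (FALSE until filtering).
#' @export
bin_profiles <- function(series, bin_minutes = 30) {
  if (1440 %% bin_minutes != 0)
    stop_stage("preprocessing", "bin_minutes must divide 1440")
  if (is.null(series$log_activity))
    stop_stage("preprocessing",
               "series has no log_activity column; run log_transform() first")
  ts <- as.numeric(series$timestamp)
  if (nrow(series) > 1) {
    spacing <- diff(ts)
    if (any(abs(spacing - spacing[1]) > 1e-6))
      stop_stage("preprocessing", "irregular epoch spacing for subject ",
                 series$subject_id[1])
  }
  off <- if (is.null(series$off_wrist)) rep(FALSE, nrow(series)) else
    series$off_wrist
  n_bins <- 1440L %/% as.integer(bin_minutes)
  secs <- ts %% 86400
  day <- floor(ts / 86400)
  day <- day - min(day)
  bin <- floor(secs / (bin_minutes * 60))
  n_days <- max(day) + 1L

  keep <- !off
  # column-major cell index of the days x bins matrix
  idx <- bin[keep] * n_days + day[keep] + 1L
  sums <- rowsum(series$log_activity[keep], idx)
  counts <- rowsum(rep(1, sum(keep)), idx)
  values <- matrix(NA_real_, n_days, n_bins)
  values[as.integer(rownames(sums))] <- sums / counts

  dates <- as.Date(as.POSIXct(
    (seq_len(n_days) - 1L) * 86400 + min(floor(ts / 86400)) * 86400,
    origin = "1970-01-01", tz = "UTC"))
  structure(list(subject_id = series$subject_id[1],
                 bin_minutes = bin_minutes,
                 values = values,
                 dates = dates,
                 day_valid = rep(TRUE, n_days),
                 excluded = FALSE),
            class = "rar_profile_matrix")
}

#' Flag invalid days and subjects with too little valid wear time
#'
#' A day is invalid when the fraction of missing (all-off-wrist or
#' unrecorded) bins exceeds `max_missing_fraction`. A subject with fewer
#' than `min_valid_days` valid days is flagged `excluded` from rhythm
#' analyses (the standard "at least three valid days" rule); exclusion is a
#' flag, never an error.
#'
#' @param pm an `rar_profile_matrix` from [bin_profiles()].
#' @param max_missing_fraction maximum tolerated fraction of missing bins in
#'   a day (default 0.5).
#' @param min_valid_days minimum valid days required for inclusion
#'   (default 3).
#' @return the profile matrix with `day_valid` and `excluded` updated.
#' @export
filter_valid_days <- function(pm, max_missing_fraction = 0.5,
                              min_valid_days = 3) {
  miss <- rowMeans(is.na(pm$values))
  pm$day_valid <- miss <= max_missing_fraction
  pm$excluded <- sum(pm$day_valid) < min_valid_days
  pm
}

#' Subject-level mean and SD rest/activity profiles
#'
#' Collapses a daily profile matrix over its valid days into the subject's
#' mean 24-hour profile and across-day SD profile: per bin, the mean and the
#' sample SD (denominator n − 1) over valid days, skipping missing cells.
#' Bins with fewer than two contributing days get an `NA` SD with a warning.
#'
#' @param pm an `rar_profile_matrix`, normally after [filter_valid_days()].
#' @return an object of class `rar_subject`: list with `subject_id`,
#'   `bin_minutes`, `mean_profile`, `sd_profile`, `n_valid_days`,
#'   `excluded`, and `grid` (bin midpoint clock hours).
#' @export
subject_rar <- function(pm) {
  v <- pm$values[pm$day_valid, , drop = FALSE]
  n_obs <- colSums(!is.na(v))
  mean_profile <- colMeans(v, na.rm = TRUE)
  mean_profile[n_obs == 0] <- NA_real_
  sd_profile <- apply(v, 2, stats::sd, na.rm = TRUE)
  if (any(n_obs < 2)) {
    warning(sprintf("subject %s: %d bin(s) with < 2 valid days; SD set NA",
                    pm$subject_id, sum(n_obs < 2)))
    sd_profile[n_obs < 2] <- NA_real_
  }
  n_bins <- ncol(pm$values)
  structure(list(subject_id = pm$subject_id,
                 bin_minutes = pm$bin_minutes,
                 mean_profile = unname(mean_profile),
                 sd_profile = unname(sd_profile),
                 n_valid_days = sum(pm$day_valid),
                 excluded = pm$excluded,
                 grid = ((seq_len(n_bins) - 0.5) * pm$bin_minutes) / 60),
            class = "rar_subject")
}

#' Epoch table to per-subject profiles and RARs
#'
#' Convenience wrapper running [log_transform()], [bin_profiles()],
#' [filter_valid_days()] and [subject_rar()] for every subject in an epoch
#' table.
#'
#' @param epochs data.frame of all subjects' epochs (`subject_id`,
#'   `timestamp`, `activity_count`, `off_wrist`).
#' @param bin_minutes bin width in minutes.
#' @param max_missing_fraction,min_valid_days passed to
#'   [filter_valid_days()].
#' @return list with `profiles` (named list of `rar_profile_matrix`) and
#'   `rars` (named list of `rar_subject`).
#' @export
compute_rars <- function(epochs, bin_minutes = 30,
                         max_missing_fraction = 0.5, min_valid_days = 3) {
  by_subject <- split(epochs, epochs$subject_id)
  profiles <- lapply(by_subject, function(s)
    filter_valid_days(bin_profiles(log_transform(s), bin_minutes),
                      max_missing_fraction, min_valid_days))
  list(profiles = profiles, rars = lapply(profiles, subject_rar))
}
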