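## Sleep/wake scoring and sleep parameters.
##
## The scorer is a configurable weighted-moving-window threshold algorithm in
## the style of standard actigraphy software: an epoch is scored wake when
## the weighted sum of activity counts in a symmetric window around it
## exceeds a threshold. It is a documented stand-in for proprietary scorers,
## not a claim of equivalence to any of them.

# default weights for 30-second epochs: +/- 4 epochs (2 minutes), central
# weight largest, flanks down-weighted
default_sleep_weights <- function() {
  c(0.04, 0.04, 0.2, 0.2, 1, 0.2, 0.2, 0.04, 0.04)
}

#' Score epochs as sleep or wake
#'
#' For each epoch, computes the weighted sum of raw activity counts over a
#' symmetric window (default ±2 minutes at 30-s epochs, central weight
#' largest) and scores the epoch wake when the sum exceeds `threshold`
#' (default 40, a conventional "medium" sensitivity). Edge epochs use
#' truncated windows. Deterministic.
#'
#' @param series a single subject's epoch data.frame with `activity_count`.
#' @param threshold wake threshold (> 0) on the weighted activity sum.
#' @param weights odd-length numeric vector of window weights, centre in the
#'   middle.
#' @return logical vector, TRUE = wake, one element per epoch.
#' @export
score_sleep_wake <- function(series, threshold = 40,
                             weights = default_sleep_weights()) {
  if (threshold <= 0) stop_stage("sleep_metrics", "threshold must be > 0")
  if (length(weights) %% 2 != 1)
    stop_stage("sleep_metrics", "weights must have odd length")
  x <- series$activity_count
  half <- (length(weights) - 1L) %/% 2L
  padded <- c(rep(0, half), x, rep(0, half))  # zero-pad == truncated window
  n <- length(x)
  score <- numeric(n)
  for (k in seq_along(weights))
    score <- score + weights[k] * padded[seq_len(n) + (k - 1L)]
  score > threshold
}

#' Sleep parameters for one rest interval
#'
#' Computes the five standard actigraphic sleep parameters from scored
#' epochs inside one in-bed interval. Sleep onset is the start of the first
#' run of at least `onset_rule_min` consecutive sleep minutes after lights
#' out; SOL is onset minus lights-out; TST and WASO are the sleep and wake
#' minutes from onset to out-of-bed; SE is 100 × sleep minutes in the whole
#' interval / interval minutes; the average wake bout length is the mean
#' duration of maximal wake runs after onset. If no onset is found, SOL is
#' set to the interval length, TST and WASO to 0, and the night is flagged.
#'
#' @param series the subject's epoch data.frame (`timestamp`,
#'   `activity_count`); epochs must cover the interval.
#' @param wake logical vector from [score_sleep_wake()], aligned to
#'   `series`.
#' @param lights_out,out_of_bed POSIXct interval bounds
#'   (`out_of_bed > lights_out`, at most 24 h apart).
#' @param onset_rule_min consecutive sleep minutes defining onset
#'   (default 10).
#' @return one-row data.frame `TST`, `WASO`, `SE`, `SOL`, `avg_wake_bout`
#'   (minutes, SE in percent), plus `no_onset` flag.
#' @export
sleep_parameters <- function(series, wake, lights_out, out_of_bed,
                             onset_rule_min = 10) {
  if (out_of_bed <= lights_out)
    stop_stage("sleep_metrics", "out_of_bed must be after lights_out")
  if (as.numeric(difftime(out_of_bed, lights_out, units = "hours")) > 24)
    stop_stage("sleep_metrics", "rest interval longer than 24 h")
  sel <- series$timestamp >= lights_out & series$timestamp < out_of_bed
  if (!any(sel))
    stop_stage("sleep_metrics", "no epochs inside the rest interval")
  w <- wake[sel]
  ts <- series$timestamp[sel]
  epoch_min <- if (length(ts) > 1)
    as.numeric(difftime(ts[2], ts[1], units = "mins")) else 0.5
  interval_min <- as.numeric(difftime(out_of_bed, lights_out, units = "mins"))
  onset_epochs <- max(1L, round(onset_rule_min / epoch_min))

  r <- rle(!w)  # runs of sleep
  run_start <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
  onset_run <- which(r$values & r$lengths >= onset_epochs)[1]
  se <- 100 * sum(!w) * epoch_min / interval_min

  if (is.na(onset_run)) {
    return(data.frame(TST = 0, WASO = 0, SE = se, SOL = interval_min,
                      avg_wake_bout = NA_real_, no_onset = TRUE))
  }
  onset_idx <- run_start[onset_run]
  sol <- (onset_idx - 1L) * epoch_min
  after <- w[seq(onset_idx, length(w))]
  tst <- sum(!after) * epoch_min
  waso <- sum(after) * epoch_min
  wake_runs <- rle(after)
  bouts <- wake_runs$lengths[wake_runs$values]
  avg_bout <- if (length(bouts)) mean(bouts) * epoch_min else NA_real_
  data.frame(TST = tst, WASO = waso, SE = se, SOL = sol,
             avg_wake_bout = avg_bout, no_onset = FALSE)
}

#' Per-subject sleep parameters averaged over nights
#'
#' Scores each subject's epochs once, computes nightly sleep parameters for
#' every rest interval, and averages them over the subject's nights.
#'
#' @param epochs all subjects' epoch data.frame.
#' @param rest_intervals data.frame `subject_id`, `night`, `lights_out`,
#'   `out_of_bed`.
#' @param threshold,weights,onset_rule_min passed through to the scorer and
#'   [sleep_parameters()].
#' @return data.frame, one row per subject: mean `TST`, `WASO`, `SE`,
#'   `SOL`, `avg_wake_bout` and `n_nights`.
#' @export
sleep_summary <- function(epochs, rest_intervals, threshold = 40,
                          weights = default_sleep_weights(),
                          onset_rule_min = 10) {
  by_subject <- split(epochs, epochs$subject_id)
  rows <- lapply(split(rest_intervals, rest_intervals$subject_id),
                 function(ri) {
    id <- ri$subject_id[1]
    s <- by_subject[[id]]
    if (is.null(s)) return(NULL)
    wake <- score_sleep_wake(s, threshold, weights)
    epoch_sec <- as.numeric(difftime(s$timestamp[2], s$timestamp[1],
                                     units = "secs"))
    # keep only nights whose interval the recording actually covers
    covered <- vapply(seq_len(nrow(ri)), function(k) {
      inside <- sum(s$timestamp >= ri$lights_out[k] &
                      s$timestamp < ri$out_of_bed[k])
      need <- as.numeric(difftime(ri$out_of_bed[k], ri$lights_out[k],
                                  units = "secs")) / epoch_sec
      inside >= 0.95 * need
    }, TRUE)
    ri <- ri[covered, , drop = FALSE]
    if (nrow(ri) == 0) return(NULL)
    nights <- do.call(rbind, lapply(seq_len(nrow(ri)), function(k)
      sleep_parameters(s, wake, ri$lights_out[k], ri$out_of_bed[k],
                       onset_rule_min)))
    data.frame(subject_id = id,
               TST = mean(nights$TST), WASO = mean(nights$WASO),
               SE = mean(nights$SE), SOL = mean(nights$SOL),
               avg_wake_bout = mean(nights$avg_wake_bout, na.rm = TRUE),
               n_nights = nrow(nights), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
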