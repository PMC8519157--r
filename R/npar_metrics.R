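#' Interdaily stability (IS)
#'
#' Ratio of the variance explained by the average 24-hour pattern to the
#' total variance:
#' \deqn{IS = \frac{N \sum_h (\bar x_h - \bar x)^2}{p \sum_i (x_i - \bar x)^2}}
#' over all `N` cells of the days × bins matrix, with `p` bins and per-bin
#' means \eqn{\bar x_h}. IS is 1 for a perfectly repeated daily pattern and
#' 0 when days differ only by their overall level. Bins with any missing
#' day are dropped listwise before evaluation.
#'
#' @param values days × bins numeric matrix of binned log activity (e.g.
#'   the `values` of an `rar_profile_matrix`, valid days only).
#' @return IS in `[0, 1]`, or `NA` (with a warning) if total variance is 0.
#' @export
interdaily_stability <- function(values) {
  if (nrow(values) < 2)
    stop_stage("npar_metrics", "IS needs at least 2 days")
  values <- values[, colSums(is.na(values)) == 0, drop = FALSE]
  if (ncol(values) == 0)
    stop_stage("npar_metrics", "no complete bins for IS")
  x <- as.vector(values)
  N <- length(x)
  p <- ncol(values)
  xbar <- mean(x)
  total <- sum((x - xbar)^2)
  if (total == 0) {
    warning("zero total variance; IS undefined")
    return(NA_real_)
  }
  hourly <- colMeans(values)
  is_val <- (N * sum((hourly - xbar)^2)) / (p * total)
  # clip floating error only; the formula is bounded by 1 exactly
  min(max(is_val, 0), 1)
}

#' Intradaily variability (IV)
#'
#' Normalized mean squared successive difference,
#' \deqn{IV = \frac{N \sum (x_i - x_{i-1})^2 / n_d}{\sum (x_i - \bar x)^2}}
#' with `N` values and `n_d` successive differences. Differences are taken
#' only within contiguous runs: by default within each day (no artificial
#' midnight jump), never across missing cells. IV is about 2 for white
#' noise, at most 4 (perfect alternation), and small for smooth rhythms.
#'
#' @param values days × bins matrix, or a single numeric vector (treated as
#'   one run).
#' @param per_day when TRUE (default) successive differences stay within
#'   rows; when FALSE the rows are concatenated day after day and
#'   differences also cross midnight.
#' @return IV ≥ 0, or `NA` (with a warning) if total variance is 0.
#' @export
intradaily_variability <- function(values, per_day = TRUE) {
  if (is.matrix(values)) {
    runs <- if (per_day) asplit(values, 1) else list(as.vector(t(values)))
  } else {
    runs <- list(values)
  }
  # split runs further at missing cells
  runs <- unlist(lapply(runs, function(r) {
    r <- as.numeric(r)
    ok <- !is.na(r)
    split(r[ok], cumsum(!ok)[ok])
  }), recursive = FALSE)
  x <- unlist(runs)
  N <- length(x)
  if (N < 3) stop_stage("npar_metrics", "IV needs at least 3 values")
  total <- sum((x - mean(x))^2)
  if (total == 0) {
    warning("zero variance; IV undefined")
    return(NA_real_)
  }
  d2 <- sum(vapply(runs, function(r)
    if (length(r) >= 2) sum(diff(r)^2) else 0, 0))
  n_d <- sum(pmax(lengths(runs) - 1L, 0L))
  if (n_d == 0) stop_stage("npar_metrics", "no successive pairs for IV")
  (N * d2 / n_d) / total
}

#' Relative amplitude (RA) with M10 and L5
#'
#' Scans all circularly-wrapped windows of 10 h (most active, M10) and 5 h
#' (least active, L5) over the subject's mean 24-hour profile and reports
#' `RA = (M10 - L5) / (M10 + L5)`. Window onsets are the starting clock
#' times; ties are broken by the earliest onset.
#'
#' @param mean_profile numeric vector, one value per bin over 24 h.
#' @param bin_minutes bin width in minutes (window lengths in bins are
#'   `600 / bin_minutes` and `300 / bin_minutes`).
#' @return list with `RA`, `M10`, `L5`, `M10_onset`, `L5_onset` (hours).
#' @export
relative_amplitude <- function(mean_profile, bin_minutes = 30) {
  n_bins <- length(mean_profile)
  stopifnot(n_bins * bin_minutes == 1440)
  if (any(!is.finite(mean_profile)))
    stop_stage("npar_metrics", "mean profile must be finite for RA")
  w10 <- 600L %/% as.integer(bin_minutes)
  w5 <- 300L %/% as.integer(bin_minutes)
  wrapped <- c(mean_profile, mean_profile)
  win_mean <- function(w) {
    cs <- cumsum(c(0, wrapped))
    (cs[seq_len(n_bins) + w] - cs[seq_len(n_bins)]) / w
  }
  m10_all <- win_mean(w10)
  l5_all <- win_mean(w5)
  i10 <- which.max(m10_all)  # which.max/min take the first (earliest) tie
  i5 <- which.min(l5_all)
  M10 <- m10_all[i10]
  L5 <- l5_all[i5]
  RA <- if (M10 + L5 <= 0) {
    if (M10 == 0) NA_real_ else (M10 - L5) / (M10 + L5)
  } else (M10 - L5) / (M10 + L5)
  list(RA = RA, M10 = M10, L5 = L5,
       M10_onset = (i10 - 1) * bin_minutes / 60,
       L5_onset = (i5 - 1) * bin_minutes / 60)
}

#' Nonparametric rhythm metrics for one subject
#'
#' Computes IS (from the valid-day profile matrix), IV (within-day runs,
#' pooled) and RA/M10/L5 (from the mean profile) on the log-transformed
#' binned data — the same scale as the rest of the rhythm pipeline.
#'
#' @param pm an `rar_profile_matrix` after [filter_valid_days()].
#' @param per_day_iv passed to [intradaily_variability()].
#' @return one-row data.frame `IS`, `IV`, `RA`, `M10`, `L5`, `M10_onset`,
#'   `L5_onset`.
#' @export
npar_metrics <- function(pm, per_day_iv = TRUE) {
  v <- pm$values[pm$day_valid, , drop = FALSE]
  ra <- relative_amplitude(colMeans(v, na.rm = TRUE), pm$bin_minutes)
  data.frame(IS = interdaily_stability(v),
             IV = intradaily_variability(v, per_day = per_day_iv),
             RA = ra$RA, M10 = ra$M10, L5 = ra$L5,
             M10_onset = ra$M10_onset, L5_onset = ra$L5_onset)
}
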