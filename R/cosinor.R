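#' Fit a one-component cosinor model
#'
#' Ordinary least squares of activity values on
#' `{1, cos(2*pi*t/period), sin(2*pi*t/period)}`. The fitted rhythm is
#' `MESOR + amplitude * cos(2*pi*(t - acrophase)/period)`: MESOR is the
#' rhythm-adjusted mean, amplitude the cosine coefficient (half the
#' peak-to-trough excursion), and acrophase the clock time of the fitted
#' peak, mapped into `[0, period)`. A numerically zero amplitude leaves the
#' acrophase undefined (`NA`), never an arbitrary angle.
#'
#' @param time_hours numeric vector of clock times (hours).
#' @param values numeric vector of the same length (log activity).
#' @param period_hours rhythm period, fixed at 24 by default.
#' @return an object of class `cosinor_fit`: list with `mesor`, `amplitude`,
#'   `acrophase` (hours in `[0, 24)` or `NA`), `beta_cos`, `beta_sin`,
#'   `peak_to_trough` (= 2 × amplitude), `residual_sd`, `n_points`,
#'   `period_hours`.
#' @examples
#' t <- (0:47 + 0.5) / 2
#' y <- 3 + 2 * cos(2 * pi * (t - 14.72) / 24)
#' fit_cosinor(t, y)
#' @export
fit_cosinor <- function(time_hours, values, period_hours = 24) {
  keep <- stats::complete.cases(time_hours, values)
  t <- time_hours[keep]
  y <- values[keep]
  if (length(unique(t)) < 4)
    stop_stage("cosinor", "need at least 4 distinct time points")
  if (diff(range(t)) <= period_hours / 2)
    stop_stage("cosinor", "time points must span more than half the period")
  omega <- 2 * pi / period_hours
  X <- cbind(1, cos(omega * t), sin(omega * t))
  beta <- stats::lm.fit(X, y)$coefficients
  amp <- sqrt(beta[2]^2 + beta[3]^2)
  acro <- if (amp < 1e-10) NA_real_ else
    (atan2(beta[3], beta[2]) / omega) %% period_hours
  resid <- y - X %*% beta
  structure(list(mesor = unname(beta[1]),
                 amplitude = unname(amp),
                 acrophase = unname(acro),
                 beta_cos = unname(beta[2]),
                 beta_sin = unname(beta[3]),
                 peak_to_trough = 2 * unname(amp),
                 residual_sd = stats::sd(resid),
                 n_points = length(y),
                 period_hours = period_hours),
            class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "cosinor fit (period %g h): MESOR %.3f, amplitude %.3f, acrophase %s\n",
    x$period_hours, x$mesor, x$amplitude,
    ifelse(is.na(x$acrophase), "undefined", acrophase_to_clock(x$acrophase))))
  invisible(x)
}

#' Format an acrophase as a clock string
#'
#' @param acrophase_hours acrophase in hours since midnight, `[0, 24)`;
#'   `NA` (undefined acrophase) maps to `NA`.
#' @return "HH:MM" rounded to the nearest minute, wrapping at midnight.
#' @examples
#' acrophase_to_clock(14.7167)  # "14:43"
#' @export
acrophase_to_clock <- function(acrophase_hours) {
  clock_label(acrophase_hours)
}

#' Cosinor fit for one subject's binned rhythm data
#'
#' Pools all valid days of the subject's daily profile matrix (time = bin
#' midpoint clock hour, one observation per valid day and bin) and fits the
#' one-component cosinor on the pooled points.
#'
#' @param pm an `rar_profile_matrix` (after [filter_valid_days()]).
#' @param period_hours rhythm period.
#' @return a `cosinor_fit`.
#' @export
cosinor_rar <- function(pm, period_hours = 24) {
  v <- pm$values[pm$day_valid, , drop = FALSE]
  n_bins <- ncol(v)
  mid <- ((seq_len(n_bins) - 0.5) * pm$bin_minutes) / 60
  tt <- rep(mid, each = nrow(v))
  fit_cosinor(tt, as.vector(v), period_hours)
}
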