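#' Configuration for the synthetic two-group actigraphy cohort
#'
#' Builds the parameter set for [generate_cohort()]. The defaults emulate a
#' two-group amyloid study design: 26 biomarker-positive and 33
#' biomarker-negative older adults wearing a wrist actigraph for up to six
#' 24-hour periods at 30-second epochs, with a circadian mean structure on
#' the log-count scale, group mean differences up to 0.5 log units confined
#' to a few clock-time windows, and group differences in across-day
#' variability confined to windows.
#'
#' The latent process for subject *i*, day *d*, epoch at clock time *t* is
#' \deqn{x = \mu(t - J_{id}) + b_i + \delta(t)\,1[\mathrm{group}_i = pos] +
#'   \epsilon,}
#' where \eqn{\mu(t) = \mathrm{mesor} + A\cos(2\pi(t-\phi)/24) + } harmonics,
#' \eqn{b_i \sim N(0, \mathrm{subject\_intercept\_sd}^2)}, \eqn{J_{id}} is
#' day-specific phase jitter, and \eqn{\epsilon \sim N(0, \sigma_g(t)^2)}
#' with the positive group's SD inflated/deflated inside
#' `sd_effect_windows`. The emitted activity count is
#' `max(0, round(exp(x) - 1))`, i.e. the natural-log transform
#' `log(count + 1)` recovers the latent scale up to integer rounding.
#'
#' @param n_group_pos,n_group_neg subjects per group (positive / negative).
#' @param days_per_subject either a single integer (every subject wears the
#'   device that many full days) or a length-2 integer range within
#'   `[2, 6]`; a range is sampled with weights calibrated so that `c(2, 6)`
#'   reproduces a mean of about 5.7 days (SD about 0.8).
#' @param epoch_seconds epoch length in seconds; must divide 86400.
#' @param baseline_mesor,baseline_amplitude,baseline_acrophase fundamental
#'   cosinor parameters of the group-negative mean curve, in log-counts and
#'   clock hours. Defaults mirror typical older-adult wrist actigraphy
#'   (MESOR ~3.2, amplitude ~2.3 log-counts, peak mid-afternoon).
#' @param harmonics list of `list(order, amplitude, phase)` additional
#'   cosine harmonics of the 24 h fundamental.
#' @param mean_effect_bumps list of `list(center, width, height, sign)`
#'   Gaussian bumps (clock-hour center, SD width in hours, height in
#'   log-counts, sign ±1) added to the positive group's mean curve.
#'   Defaults place a negative bump overnight (~01:15) and positive bumps in
#'   the early morning (~06:30) and mid-afternoon (~15:00), each 0.5
#'   log-units high.
#' @param sd_effect_windows list of `list(start, end, multiplier)` clock
#'   windows (half-open, wrapping midnight) in which the positive group's
#'   epoch noise SD is multiplied by `multiplier`.
#' @param subject_intercept_sd SD of the subject-level random intercept
#'   (log-counts).
#' @param day_phase_jitter_sd SD of the day-specific phase shift (hours);
#'   the jitter shifts the latent curve, not the timestamps.
#' @param noise_sd epoch-level noise SD (log-counts) for the negative group.
#' @param age_mean,age_sd,prop_female,education_mean,education_sd covariate
#'   model (years, years, proportion, years, years).
#' @param rng_seed integer seed; [generate_cohort()] is deterministic given
#'   the config (the seed is part of it).
#' @return an object of class `rar_sim_config` (a named list).
#' @seealso [generate_cohort()], [cohort_truth()]
#' @export
sim_config <- function(n_group_pos = 26,
                       n_group_neg = 33,
                       days_per_subject = 6,
                       epoch_seconds = 30,
                       baseline_mesor = 3.16,
                       baseline_amplitude = 2.30,
                       baseline_acrophase = 14.72,
                       harmonics = list(list(order = 2, amplitude = 0.35,
                                             phase = 17.5)),
                       mean_effect_bumps = list(
                         list(center = 1.25, width = 1.0, height = 0.5, sign = -1),
                         list(center = 6.5,  width = 1.2, height = 0.5, sign = 1),
                         list(center = 15.0, width = 1.5, height = 0.5, sign = 1)),
                       sd_effect_windows = list(
                         list(start = 21.5, end = 1.0, multiplier = 1.5),
                         list(start = 4.5,  end = 8.5, multiplier = 1.5),
                         list(start = 2.5,  end = 3.5, multiplier = 0.6)),
                       subject_intercept_sd = 0.2,
                       day_phase_jitter_sd = 0.25,
                       noise_sd = 1.0,
                       age_mean = 71.3, age_sd = 4.6,
                       prop_female = 0.59,
                       education_mean = 16.6, education_sd = 2.4,
                       rng_seed = 1L) {
  config <- list(n_group_pos = n_group_pos, n_group_neg = n_group_neg,
                 days_per_subject = days_per_subject,
                 epoch_seconds = epoch_seconds,
                 baseline_mesor = baseline_mesor,
                 baseline_amplitude = baseline_amplitude,
                 baseline_acrophase = baseline_acrophase,
                 harmonics = harmonics,
                 mean_effect_bumps = mean_effect_bumps,
                 sd_effect_windows = sd_effect_windows,
                 subject_intercept_sd = subject_intercept_sd,
                 day_phase_jitter_sd = day_phase_jitter_sd,
                 noise_sd = noise_sd,
                 age_mean = age_mean, age_sd = age_sd,
                 prop_female = prop_female,
                 education_mean = education_mean, education_sd = education_sd,
                 rng_seed = rng_seed)
  class(config) <- "rar_sim_config"
  validate_sim_config(config)
  config
}

validate_sim_config <- function(config) {
  stopifnot(config$n_group_pos >= 1, config$n_group_neg >= 1)
  d <- config$days_per_subject
  if (!length(d) %in% c(1L, 2L) || any(d != round(d)) ||
      any(d < 2) || any(d > 6))
    stop_stage("synthetic_cohort",
               "days_per_subject must be an integer (or range) within [2, 6]")
  if (86400 %% config$epoch_seconds != 0)
    stop_stage("synthetic_cohort", "epoch_seconds must divide 86400")
  sds <- c(config$subject_intercept_sd, config$day_phase_jitter_sd,
           config$noise_sd)
  if (any(sds < 0))
    stop_stage("synthetic_cohort", "all SDs must be >= 0")
  for (b in config$mean_effect_bumps) {
    if (b$width <= 0) stop_stage("synthetic_cohort", "bump widths must be > 0")
    if (b$center < 0 || b$center >= 24)
      stop_stage("synthetic_cohort", "bump centers must lie in [0, 24)")
    if (!b$sign %in% c(-1, 1))
      stop_stage("synthetic_cohort", "bump sign must be -1 or 1")
  }
  for (w in config$sd_effect_windows)
    if (w$multiplier < 0)
      stop_stage("synthetic_cohort", "sd window multipliers must be >= 0")
  # overflow guard: exp() of the latent mean must stay representable
  peak <- config$baseline_mesor + abs(config$baseline_amplitude) +
    sum(vapply(config$harmonics, function(h) abs(h$amplitude), 0)) +
    sum(vapply(config$mean_effect_bumps, function(b) b$height, 0))
  if (peak > 20)
    stop_stage("synthetic_cohort",
               "latent mean exceeds 20 log-counts; exp() would overflow ",
               "the count scale")
  invisible(config)
}

# baseline (group-negative) latent mean curve at clock hours t, log-counts
rar_baseline_curve <- function(config, t) {
  omega <- 2 * pi / 24
  x <- config$baseline_mesor +
    config$baseline_amplitude * cos(omega * (t - config$baseline_acrophase))
  for (h in config$harmonics)
    x <- x + h$amplitude * cos(h$order * omega * (t - h$phase))
  x
}

# group mean difference delta(t): sum of signed Gaussian bumps in clock time
rar_delta_curve <- function(config, t) {
  d <- numeric(length(t))
  for (b in config$mean_effect_bumps) {
    u <- circ_dist_hours(t, b$center)
    d <- d + b$sign * b$height * exp(-0.5 * (u / b$width)^2)
  }
  d
}

# epoch-level noise SD at clock hours t for one group
rar_sigma_curve <- function(config, t, group = c("neg", "pos")) {
  group <- match.arg(group)
  s <- rep(config$noise_sd, length(t))
  if (group == "pos")
    for (w in config$sd_effect_windows)
      s[in_clock_window(t, w$start, w$end)] <-
        s[in_clock_window(t, w$start, w$end)] * w$multiplier
  s
}

# weights over 2..6 days calibrated to wear-time ~5.7 +/- 0.8 days
.days_weights <- c(`2` = 0.02, `3` = 0.02, `4` = 0.04, `5` = 0.12, `6` = 0.80)

#' Generate a synthetic two-group actigraphy cohort
#'
#' Simulates epoch-level activity counts for every subject under the latent
#' log-normal model described in [sim_config()], together with a covariate
#' table (age, sex, education, binary group status), nightly rest intervals,
#' and the closed-form ground-truth curves on the 30-minute bin grid that
#' downstream tests compare against. Deterministic given `config$rng_seed`.
#'
#' @param config an [sim_config()] object.
#' @return an object of class `rar_cohort`: a list with elements
#'   \describe{
#'     \item{epochs}{data.frame `subject_id`, `timestamp` (POSIXct, one value
#'       per `epoch_seconds`), `activity_count` (non-negative integer),
#'       `off_wrist` (logical).}
#'     \item{covariates}{data.frame `subject_id`, `age`, `sex` (`"F"`/`"M"`),
#'       `education_years`, `abeta` (`"pos"`/`"neg"`).}
#'     \item{rest_intervals}{data.frame `subject_id`, `night`, `lights_out`,
#'       `out_of_bed` (one in-bed interval per recorded night).}
#'     \item{truth}{ground truth from [cohort_truth()] at 30-minute bins.}
#'     \item{config}{the input config.}
#'   }
#' @examples
#' cohort <- generate_cohort(sim_config(n_group_pos = 2, n_group_neg = 2,
#'                                      days_per_subject = 2))
#' head(cohort$epochs)
#' cohort$covariates
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  with_local_seed(config$rng_seed, {
    n <- config$n_group_pos + config$n_group_neg
    ids <- sprintf("S%03d", seq_len(n))
    group <- c(rep("pos", config$n_group_pos), rep("neg", config$n_group_neg))
    covariates <- data.frame(
      subject_id = ids,
      age = round(stats::rnorm(n, config$age_mean, config$age_sd), 1),
      sex = ifelse(stats::runif(n) < config$prop_female, "F", "M"),
      education_years = as.integer(pmin(22, pmax(8, round(
        stats::rnorm(n, config$education_mean, config$education_sd))))),
      abeta = group,
      stringsAsFactors = FALSE)

    d <- config$days_per_subject
    if (length(d) == 1L) {
      days <- rep(as.integer(d), n)
    } else {
      support <- seq(d[1], d[2])
      w <- .days_weights[as.character(support)]
      days <- sample(support, n, replace = TRUE, prob = w / sum(w))
    }

    eps <- config$epoch_seconds
    per_day <- 86400L %/% as.integer(eps)
    t_day <- (seq_len(per_day) - 1L) * eps / 3600  # epoch-start clock hours
    origin <- as.POSIXct("2000-01-03 00:00:00", tz = "UTC")
    b_i <- stats::rnorm(n, 0, config$subject_intercept_sd)

    epoch_list <- vector("list", n)
    rest_list <- vector("list", n)
    for (i in seq_len(n)) {
      D <- days[i]
      jit <- stats::rnorm(D, 0, config$day_phase_jitter_sd)
      sig <- rar_sigma_curve(config, t_day, group[i])
      del <- if (group[i] == "pos") rar_delta_curve(config, t_day) else 0
      x <- numeric(D * per_day)
      for (dd in seq_len(D)) {
        idx <- (dd - 1L) * per_day + seq_len(per_day)
        x[idx] <- rar_baseline_curve(config, t_day - jit[dd]) + b_i[i] + del +
          stats::rnorm(per_day, 0, sig)
      }
      counts <- pmax(0, round(exp(x) - 1))
      epoch_list[[i]] <- data.frame(
        subject_id = ids[i],
        timestamp = origin + (seq_len(D * per_day) - 1L) * eps,
        activity_count = counts,
        off_wrist = FALSE,
        stringsAsFactors = FALSE)
      if (D >= 2L) {
        nights <- seq_len(D - 1L)
        lo <- origin + (nights - 1L) * 86400 +
          round((23 + stats::rnorm(D - 1L, 0, 0.5)) * 3600)
        ob <- origin + nights * 86400 +
          round((7 + stats::rnorm(D - 1L, 0, 0.5)) * 3600)
        rest_list[[i]] <- data.frame(subject_id = ids[i], night = nights,
                                     lights_out = lo, out_of_bed = ob,
                                     stringsAsFactors = FALSE)
      }
    }

    cohort <- list(epochs = do.call(rbind, epoch_list),
                   covariates = covariates,
                   rest_intervals = do.call(rbind, rest_list),
                   truth = cohort_truth(config, bin_minutes = 30),
                   config = config)
    class(cohort) <- "rar_cohort"
    cohort
  })
}

#' Ground-truth curves of a simulation config on the bin grid
#'
#' Evaluates the noiseless latent model on the analysis bin grid:
#' `mu_neg` is the negative group's latent mean log-activity averaged over
#' the epochs falling in each bin, `delta` the positive-group mean offset,
#' and `sigma_neg`/`sigma_pos` the within-bin average epoch-level noise SDs.
#' Phase jitter is not part of these curves; its (tiny) attenuation of
#' realized profiles is quantified in the vignette.
#'
#' With `observed = TRUE`, two further columns give the expected *observed*
#' binned log-activity per group, `mu_obs_neg` and `mu_obs_pos`, i.e.
#' `E[log(count + 1)]` under the latent Gaussian marginal (noise plus
#' subject intercept), accounting exactly for the integer rounding and
#' flooring of emitted counts. At low counts (night bins) this differs from
#' the latent mean by up to a few tenths of a log unit, so observed-scale
#' group profiles must be compared against these columns, not the latent
#' ones.
#'
#' @param config an [sim_config()] object.
#' @param bin_minutes analysis bin width; must divide 1440.
#' @param observed also compute the discretization-aware observed-scale
#'   means (slower; off by default).
#' @return data.frame with `bin_start_hours`, `bin_mid_hours`, `mu_neg`,
#'   `delta`, `sigma_neg`, `sigma_pos` (+ `mu_obs_neg`, `mu_obs_pos`), one
#'   row per bin.
#' @export
cohort_truth <- function(config, bin_minutes = 30, observed = FALSE) {
  stopifnot(1440 %% bin_minutes == 0)
  per_day <- 86400L %/% as.integer(config$epoch_seconds)
  t_day <- (seq_len(per_day) - 1L) * config$epoch_seconds / 3600
  bin <- floor(t_day / (bin_minutes / 60))
  mu <- rar_baseline_curve(config, t_day)
  out <- data.frame(
    bin_start_hours = tapply(t_day, bin, min),
    bin_mid_hours = tapply(t_day, bin, min) + bin_minutes / 120,
    mu_neg = as.numeric(tapply(mu, bin, mean)),
    delta = as.numeric(tapply(rar_delta_curve(config, t_day), bin, mean)),
    sigma_neg = as.numeric(tapply(rar_sigma_curve(config, t_day, "neg"),
                                  bin, mean)),
    sigma_pos = as.numeric(tapply(rar_sigma_curve(config, t_day, "pos"),
                                  bin, mean)),
    row.names = NULL)
  if (observed) {
    tau <- config$subject_intercept_sd
    s_neg <- sqrt(rar_sigma_curve(config, t_day, "neg")^2 + tau^2)
    s_pos <- sqrt(rar_sigma_curve(config, t_day, "pos")^2 + tau^2)
    e_neg <- expected_log1p_count(mu, s_neg)
    e_pos <- expected_log1p_count(mu + rar_delta_curve(config, t_day), s_pos)
    out$mu_obs_neg <- as.numeric(tapply(e_neg, bin, mean))
    out$mu_obs_pos <- as.numeric(tapply(e_pos, bin, mean))
  }
  out
}

# E[log(max(0, round(exp(x) - 1)) + 1)] for x ~ N(mu, sigma^2), exact up to
# a truncation at count K = exp(mu + 4 sigma) with a log(c+1) ~ x tail
# approximation; for mu > 4 the discretization bias is negligible (< 1e-3)
# and mu is returned directly.
expected_log1p_count <- function(mu, sigma) {
  out <- mu
  for (i in which(mu <= 4)) {
    m <- mu[i]; s <- sigma[i]
    if (s == 0) {
      out[i] <- log(max(0, round(exp(m) - 1)) + 1)
      next
    }
    K <- ceiling(exp(m + 4 * s))
    k <- seq_len(K)
    cuts <- stats::pnorm((log(c(1.5, k + 1.5)) - m) / s)
    z <- (log(K + 1.5) - m) / s
    out[i] <- sum(log(k + 1) * diff(cuts)) +
      m * stats::pnorm(z, lower.tail = FALSE) + s * stats::dnorm(z)
  }
  out
}

#' Write a cohort to plain-text files
#'
#' Emits `epochs.csv` (one row per epoch: subject, ISO-8601 timestamp,
#' count, off-wrist flag), `covariates.csv`, `rest_intervals.csv` (if
#' present) and `truth.csv` into `directory`. The epoch and covariate files
#' round-trip losslessly through [read_cohort()].
#'
#' @param cohort an `rar_cohort` (or any list with `epochs` and
#'   `covariates` data.frames).
#' @param directory output directory, created if needed.
#' @param overwrite logical; refuse to clobber existing files unless TRUE.
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, directory, overwrite = FALSE) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(directory, c("epochs.csv", "covariates.csv"))
  if (!overwrite && any(file.exists(files)))
    stop_stage("synthetic_cohort", "refusing to overwrite existing files in ",
               directory, " (set overwrite = TRUE)")
  ep <- cohort$epochs
  ep$timestamp <- format(ep$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  ep$off_wrist <- as.integer(ep$off_wrist)
  utils::write.csv(ep, files[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$covariates, files[2], row.names = FALSE,
                   quote = FALSE)
  if (!is.null(cohort$rest_intervals)) {
    ri <- cohort$rest_intervals
    ri$lights_out <- format(ri$lights_out, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    ri$out_of_bed <- format(ri$out_of_bed, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    f <- file.path(directory, "rest_intervals.csv")
    utils::write.csv(ri, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  if (!is.null(cohort$truth)) {
    f <- file.path(directory, "truth.csv")
    utils::write.csv(cohort$truth, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory directory containing `epochs.csv` and `covariates.csv`.
#' @return a list with `epochs`, `covariates` and, when present,
#'   `rest_intervals` and `truth`, with timestamps parsed back to POSIXct.
#' @export
read_cohort <- function(directory) {
  ep <- utils::read.csv(file.path(directory, "epochs.csv"),
                        stringsAsFactors = FALSE)
  ep$timestamp <- as.POSIXct(ep$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                             tz = "UTC")
  ep$activity_count <- as.numeric(ep$activity_count)
  ep$off_wrist <- as.logical(ep$off_wrist)
  out <- list(epochs = ep,
              covariates = utils::read.csv(
                file.path(directory, "covariates.csv"),
                stringsAsFactors = FALSE))
  ri_file <- file.path(directory, "rest_intervals.csv")
  if (file.exists(ri_file)) {
    ri <- utils::read.csv(ri_file, stringsAsFactors = FALSE)
    ri$lights_out <- as.POSIXct(ri$lights_out,
                                format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    ri$out_of_bed <- as.POSIXct(ri$out_of_bed,
                                format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    out$rest_intervals <- ri
  }
  tr_file <- file.path(directory, "truth.csv")
  if (file.exists(tr_file))
    out$truth <- utils::read.csv(tr_file, stringsAsFactors = FALSE)
  out
}

#' @export
print.rar_cohort <- function(x, ...) {
  cat(sprintf("rar_cohort: %d subjects (%d pos / %d neg), %d epochs\n",
              nrow(x$covariates), sum(x$covariates$abeta == "pos"),
              sum(x$covariates$abeta == "neg"), nrow(x$epochs)))
  invisible(x)
}
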