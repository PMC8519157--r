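## Scalar group comparisons and end-to-end orchestration.

#' Two-sample t-test from group summary statistics
#'
#' Pooled-variance (default) or Welch two-sample t-test computed from group
#' sizes, means and SDs — the form needed to check published summary
#' tables, where raw values are unavailable.
#'
#' @param n1,mean1,sd1,n2,mean2,sd2 group summaries.
#' @param var_equal pooled variance (TRUE, default) or Welch.
#' @return list with `statistic`, `df`, `p.value`.
#' @examples
#' t_test_summary(26, 416.82, 49.99, 33, 424.60, 54.07)$p.value  # ~0.57
#' @export
t_test_summary <- function(n1, mean1, sd1, n2, mean2, sd2,
                           var_equal = TRUE) {
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tt <- (mean1 - mean2) / se
  list(statistic = tt, df = df, p.value = 2 * stats::pt(-abs(tt), df))
}

#' Compare a continuous outcome between two groups
#'
#' Two-sample t-test (pooled variance by default, Welch optional) of a
#' per-subject outcome between the positive and negative groups.
#'
#' @param values numeric outcome vector.
#' @param group factor/character with two levels; the *second* sorted level
#'   is treated as the reference (so `"pos"` vs `"neg"` compares pos − neg
#'   when levels are given as c("pos","neg") order via `ref`).
#' @param ref reference group label (default `"neg"`).
#' @param var_equal pooled variance (default) or Welch.
#' @return one-row data.frame: group means/SDs/sizes, `statistic`, `df`,
#'   `p`.
#' @export
compare_continuous <- function(values, group, ref = "neg",
                               var_equal = TRUE) {
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- as.character(group[keep])
  lv <- unique(group)
  if (length(lv) != 2) stop_stage("pipeline", "need exactly two groups")
  g1 <- setdiff(lv, ref)
  x1 <- values[group == g1]; x2 <- values[group == ref]
  if (length(x1) < 2 || length(x2) < 2)
    stop_stage("pipeline", "need >= 2 observations per group")
  if (stats::var(x1) + stats::var(x2) == 0)
    stop_stage("pipeline", "degenerate (zero) variance in both groups")
  ht <- stats::t.test(x1, x2, var.equal = var_equal)
  data.frame(mean_pos = mean(x1), sd_pos = stats::sd(x1), n_pos = length(x1),
             mean_neg = mean(x2), sd_neg = stats::sd(x2), n_neg = length(x2),
             statistic = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value)
}

#' Compare a categorical outcome between two groups
#'
#' Two-sided Fisher exact test of a 2×2 contingency table (p-value by
#' summing the probabilities of all tables no more likely than the observed
#' one under the hypergeometric null).
#'
#' @param tab 2×2 matrix of non-negative integer counts.
#' @return one-row data.frame with `p` and the odds-ratio estimate.
#' @export
compare_categorical <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab != round(tab)) || any(tab < 0))
    stop_stage("pipeline", "contingency cells must be non-negative integers")
  ht <- stats::fisher.test(tab)
  data.frame(p = ht$p.value, odds_ratio = unname(ht$estimate))
}

#' Covariate-adjusted group effect on a scalar outcome
#'
#' OLS of the outcome on group status adjusting for age, sex and education;
#' reports the group coefficient B with its standard error and two-sided
#' t-based p-value.
#'
#' @param data data.frame containing the outcome and `abeta`, `age`, `sex`,
#'   `education_years`.
#' @param outcome name of the outcome column.
#' @return one-row data.frame `outcome`, `B`, `SE`, `p`, `n`.
#' @export
adjusted_regression <- function(data, outcome) {
  d <- data[!is.na(data[[outcome]]), ]
  if (nrow(d) <= 5) stop_stage("pipeline", "need n > 5 for adjustment")
  d$.y <- d[[outcome]]
  d$.abeta <- as.numeric(d$abeta == "pos")
  d$.sex <- as.numeric(d$sex == "F")
  X <- cbind(1, d$.abeta, d$age, d$.sex, d$education_years)
  if (qr(X)$rank < ncol(X))
    stop_stage("pipeline", "collinear adjustment design for outcome ",
               outcome)
  fit <- stats::lm(.y ~ .abeta + age + .sex + education_years, data = d)
  cf <- summary(fit)$coefficients[".abeta", ]
  data.frame(outcome = outcome, B = cf[1], SE = cf[2], p = cf[4],
             n = nrow(d), row.names = NULL)
}

#' Per-subject metrics table
#'
#' Runs preprocessing and all scalar metric modules, returning one row per
#' subject: covariates, valid-day bookkeeping, cosinor metrics (MESOR,
#' amplitude, acrophase), nonparametric metrics (IS, IV, RA, M10, L5) and —
#' when rest intervals are supplied — night-averaged sleep parameters.
#' Subjects excluded by the valid-day rule keep their row with `NA` rhythm
#' metrics.
#'
#' @param epochs epoch data.frame for all subjects.
#' @param covariates covariate data.frame.
#' @param rest_intervals optional rest-interval data.frame for sleep
#'   parameters.
#' @param bin_minutes analysis bin width (30 default, 60 for the
#'   sensitivity analysis).
#' @param min_valid_days,max_missing_fraction valid-day rule.
#' @return data.frame, one row per subject, with an `rars` attribute
#'   holding the per-subject RAR objects for the functional analysis.
#' @export
metrics_table <- function(epochs, covariates, rest_intervals = NULL,
                          bin_minutes = 30, min_valid_days = 3,
                          max_missing_fraction = 0.5) {
  pr <- compute_rars(epochs, bin_minutes, max_missing_fraction,
                     min_valid_days)
  rows <- lapply(names(pr$profiles), function(id) {
    pm <- pr$profiles[[id]]
    rar <- pr$rars[[id]]
    base <- data.frame(subject_id = id, n_valid_days = rar$n_valid_days,
                       excluded = rar$excluded, stringsAsFactors = FALSE)
    if (rar$excluded) {
      cbind(base, data.frame(mesor = NA_real_, amplitude = NA_real_,
                             acrophase = NA_real_, acrophase_clock = NA,
                             IS = NA_real_, IV = NA_real_, RA = NA_real_,
                             M10 = NA_real_, L5 = NA_real_,
                             M10_onset = NA_real_, L5_onset = NA_real_))
    } else {
      cs <- cosinor_rar(pm)
      np <- npar_metrics(pm)
      cbind(base,
            data.frame(mesor = cs$mesor, amplitude = cs$amplitude,
                       acrophase = cs$acrophase,
                       acrophase_clock = acrophase_to_clock(cs$acrophase),
                       stringsAsFactors = FALSE),
            np[, c("IS", "IV", "RA", "M10", "L5", "M10_onset", "L5_onset")])
    }
  })
  out <- do.call(rbind, rows)
  out <- merge(covariates, out, by = "subject_id", sort = TRUE)
  if (!is.null(rest_intervals)) {
    sl <- sleep_summary(epochs, rest_intervals)
    out <- merge(out, sl, by = "subject_id", all.x = TRUE, sort = TRUE)
  }
  attr(out, "rars") <- pr$rars
  out
}

#' Group comparison table for scalar outcomes
#'
#' For each outcome: group means ± SD with the unadjusted two-sample t-test
#' p-value, and the covariate-adjusted group coefficient B (SE) with its
#' p-value — the standard layout of cohort comparison tables.
#'
#' @param metrics a [metrics_table()] data.frame.
#' @param outcomes character vector of outcome column names.
#' @param var_equal pooled-variance t (default) or Welch.
#' @return data.frame, one row per outcome.
#' @export
group_comparison_table <- function(metrics, outcomes, var_equal = TRUE) {
  rows <- lapply(outcomes, function(oc) {
    cc <- compare_continuous(metrics[[oc]], metrics$abeta,
                             var_equal = var_equal)
    ar <- adjusted_regression(metrics, oc)
    data.frame(outcome = oc, cc[, c("mean_pos", "sd_pos", "mean_neg",
                                    "sd_neg", "p")],
               B_adjusted = ar$B, SE_adjusted = ar$SE, p_adjusted = ar$p,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration: simulate (or accept) a cohort, preprocess to
#' profiles and RARs, compute the per-subject metrics table and its group
#' comparisons, fit the FOSR models for the mean and SD outcomes at the
#' main 30-minute resolution and the 60-minute sensitivity resolution, and
#' write every table, the significant-window reports, the F-test results
#' and a machine-readable run manifest into `out_dir`. Rerunning with the
#' same config and seed reproduces byte-identical outputs.
#'
#' @param config an [sim_config()]; ignored when `cohort` is given.
#' @param cohort optionally, an existing cohort (as from
#'   [generate_cohort()] or [read_cohort()]).
#' @param out_dir output directory.
#' @param bin_minutes resolutions to analyse (default `c(30, 60)`).
#' @param alpha band significance level.
#' @param n_sim draws for simultaneous bands.
#' @param n_perm permutations for the global F-test (0 disables).
#' @param seed seed for band simulation and permutations (the cohort's own
#'   seed lives in its config).
#' @param overwrite allow writing into a non-empty directory.
#' @return invisibly, a list with `metrics`, `comparisons`, `fosr` (nested
#'   by resolution and outcome) and `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), cohort = NULL,
                         out_dir, bin_minutes = c(30, 60), alpha = 0.05,
                         n_sim = 10000, n_perm = 999, seed = 1,
                         overwrite = FALSE) {
  if (is.null(cohort)) cohort <- generate_cohort(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_file <- file.path(out_dir, "manifest.json")
  if (!overwrite && file.exists(manifest_file))
    stop_stage("pipeline", "output directory already holds a run ",
               "(set overwrite = TRUE)")

  num <- function(d) {  # stable numeric formatting for byte-identical reruns
    for (k in seq_along(d)) if (is.numeric(d[[k]])) d[[k]] <- signif(d[[k]], 12)
    d
  }
  wcsv <- function(d, name) utils::write.csv(
    num(d), file.path(out_dir, name), row.names = FALSE)

  metrics <- metrics_table(cohort$epochs, cohort$covariates,
                           cohort$rest_intervals, bin_minutes = bin_minutes[1])
  wcsv(metrics, "metrics.csv")

  rhythm_outcomes <- c("mesor", "amplitude", "acrophase", "IS", "IV", "RA")
  sleep_outcomes <- intersect(c("TST", "WASO", "SE", "SOL", "avg_wake_bout"),
                              names(metrics))
  comparisons <- group_comparison_table(
    metrics, c(sleep_outcomes, rhythm_outcomes))
  wcsv(comparisons, "comparisons.csv")

  fosr_out <- list()
  for (bm in bin_minutes) {
    rars <- if (bm == bin_minutes[1]) attr(metrics, "rars") else
      compute_rars(cohort$epochs, bm)$rars
    for (oc in c("mean", "sd")) {
      res <- fosr_rar(rars, cohort$covariates, outcome = oc,
                      alpha = alpha, n_sim = n_sim, n_perm = n_perm,
                      seed = seed)
      tag <- sprintf("%s_%dmin", oc, bm)
      coef_tab <- data.frame(t = res$fit$grid,
                             estimate = res$pointwise$estimate,
                             se = res$pointwise$se,
                             pointwise_lower = res$pointwise$lower,
                             pointwise_upper = res$pointwise$upper,
                             simultaneous_lower = res$simultaneous$lower,
                             simultaneous_upper = res$simultaneous$upper)
      wcsv(coef_tab, sprintf("fosr_abeta_%s.csv", tag))
      wcsv(res$windows_simultaneous,
           sprintf("windows_simultaneous_%s.csv", tag))
      wcsv(res$windows_pointwise, sprintf("windows_pointwise_%s.csv", tag))
      fosr_out[[tag]] <- res
    }
  }

  f_tests <- lapply(fosr_out, function(r) if (is.null(r$f_test)) NULL else
    list(F = signif(r$f_test$F, 12), p = r$f_test$p,
         n_perm = r$f_test$n_perm))
  manifest <- list(package_version = "0.1.0",
                   cohort_seed = cohort$config$rng_seed,
                   analysis_seed = seed,
                   n_subjects = nrow(cohort$covariates),
                   bin_minutes = bin_minutes, alpha = alpha,
                   n_sim = n_sim, n_perm = n_perm,
                   f_tests = f_tests)
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(metrics = metrics, comparisons = comparisons,
                 fosr = fosr_out, manifest = manifest))
}
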