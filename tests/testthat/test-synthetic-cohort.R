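test_that("config invariants are enforced", {
  expect_error(sim_config(days_per_subject = 8), "within \\[2, 6\\]")
  expect_error(sim_config(epoch_seconds = 7), "divide 86400")
  expect_error(sim_config(noise_sd = -1), "SDs")
  expect_error(sim_config(mean_effect_bumps = list(
    list(center = 3, width = 0, height = 0.5, sign = 1))), "width")
  expect_error(sim_config(baseline_mesor = 25), "overflow")
})

test_that("a constant latent process emits a constant count everywhere", {
  cfg <- noiseless_config(n_group_pos = 2, n_group_neg = 2,
                          days_per_subject = 2, baseline_amplitude = 0,
                          harmonics = list(), mean_effect_bumps = list())
  co <- generate_cohort(cfg)
  expect_true(all(co$epochs$activity_count ==
                    oracle_count(cfg$baseline_mesor)))
})

test_that("generation is reproducible given the seed and varies across seeds", {
  cfg1 <- sim_config(n_group_pos = 2, n_group_neg = 2, days_per_subject = 2,
                     rng_seed = 11)
  a <- generate_cohort(cfg1)
  b <- generate_cohort(cfg1)
  expect_identical(a$epochs, b$epochs)
  expect_identical(a$covariates, b$covariates)
  cfg2 <- sim_config(n_group_pos = 2, n_group_neg = 2, days_per_subject = 2,
                     rng_seed = 12)
  expect_false(identical(generate_cohort(cfg2)$epochs$activity_count,
                         a$epochs$activity_count))
})

test_that("the emitted dataset satisfies its invariants", {
  co <- generate_cohort(sim_config(n_group_pos = 3, n_group_neg = 4,
                                   days_per_subject = 2, rng_seed = 5))
  expect_true(all(co$epochs$activity_count >= 0))
  expect_true(all(co$epochs$activity_count ==
                    round(co$epochs$activity_count)))
  expect_equal(nrow(co$covariates), 7)
  expect_equal(anyDuplicated(co$covariates$subject_id), 0)
  expect_equal(sum(co$covariates$abeta == "pos"), 3)
  # ground truth carries one value per 30-minute bin
  expect_equal(nrow(co$truth), 48)
  # every subject's epochs appear, evenly spaced
  expect_setequal(unique(co$epochs$subject_id), co$covariates$subject_id)
})

test_that("noiseless binned profiles reproduce the ground truth curves", {
  cfg <- noiseless_config(n_group_pos = 1, n_group_neg = 1,
                          days_per_subject = 2, rng_seed = 3)
  co <- generate_cohort(cfg)
  # independent oracle: rebuild the latent curve from the config fields,
  # push it through the count transform, and bin the log counts by hand
  t_epoch <- (0:2879) * 30 / 3600
  omega <- 2 * pi / 24
  mu <- cfg$baseline_mesor +
    cfg$baseline_amplitude * cos(omega * (t_epoch - cfg$baseline_acrophase))
  for (h in cfg$harmonics)
    mu <- mu + h$amplitude * cos(h$order * omega * (t_epoch - h$phase))
  delta <- rep(0, length(t_epoch))
  for (b in cfg$mean_effect_bumps) {
    d <- pmin(abs(t_epoch - b$center), 24 - abs(t_epoch - b$center))
    delta <- delta + b$sign * b$height * exp(-0.5 * (d / b$width)^2)
  }
  bin <- rep(1:48, each = 60)
  for (id in co$covariates$subject_id) {
    grp <- co$covariates$abeta[co$covariates$subject_id == id]
    latent <- mu + if (grp == "pos") delta else 0
    oracle_bins <- as.numeric(
      tapply(log(oracle_count(latent) + 1), bin, mean))
    s <- co$epochs[co$epochs$subject_id == id, ]
    pm <- bin_profiles(log_transform(s))
    expect_equal(dim(pm$values), c(2, 48))
    for (d in 1:2)
      expect_equal(unname(pm$values[d, ]), oracle_bins, tolerance = 1e-12)
  }
})

test_that("group profiles coincide when no mean bumps are injected", {
  cfg <- noiseless_config(n_group_pos = 1, n_group_neg = 1,
                          days_per_subject = 2, mean_effect_bumps = list(),
                          rng_seed = 3)
  co <- generate_cohort(cfg)
  prof <- lapply(split(co$epochs, co$epochs$subject_id),
                 function(s) colMeans(bin_profiles(log_transform(s))$values))
  expect_equal(prof[[1]], prof[[2]], tolerance = 1e-12)
})

test_that("raising a bump height raises the noiseless group contrast at its center", {
  contrast_at_center <- function(height) {
    cfg <- noiseless_config(
      n_group_pos = 1, n_group_neg = 1, days_per_subject = 2,
      mean_effect_bumps = list(list(center = 15, width = 1.5,
                                    height = height, sign = 1)),
      rng_seed = 3)
    co <- generate_cohort(cfg)
    prof <- lapply(split(co$epochs, co$epochs$subject_id), function(s)
      colMeans(bin_profiles(log_transform(s))$values))
    grp <- co$covariates$abeta[match(names(prof), co$covariates$subject_id)]
    bin_15h <- 31  # bin covering 15:00-15:30
    prof[[which(grp == "pos")]][bin_15h] - prof[[which(grp == "neg")]][bin_15h]
  }
  expect_gt(contrast_at_center(0.6), contrast_at_center(0.3))
  expect_gt(contrast_at_center(0.3), 0)
})

test_that("empirical group mean profiles match the observed-scale truth (3 MC SE)", {
  cfg <- sim_config(n_group_pos = 30, n_group_neg = 30, rng_seed = 42)
  co <- generate_cohort(cfg)
  tr <- cohort_truth(cfg, observed = TRUE)
  prof <- t(vapply(compute_rars(co$epochs)$rars,
                   function(r) r$mean_profile, numeric(48)))
  pos <- rownames(prof) %in%
    co$covariates$subject_id[co$covariates$abeta == "pos"]
  for (g in c(TRUE, FALSE)) {
    emp <- colMeans(prof[pos == g, ])
    se <- apply(prof[pos == g, ], 2, stats::sd) / sqrt(sum(pos == g))
    truth <- if (g) tr$mu_obs_pos else tr$mu_obs_neg
    expect_true(all(abs(emp - truth) <= 3 * se))
  }
})

test_that("a written cohort round-trips losslessly through the reader", {
  cfg <- sim_config(n_group_pos = 1, n_group_neg = 1, days_per_subject = 2,
                    rng_seed = 8)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_error(write_cohort(co, dir), "overwrite")
  back <- read_cohort(dir)
  # one calendar day of 30-s epochs = 2880 rows per subject-day
  expect_equal(nrow(back$epochs), 2 * 2 * 2880)
  expect_identical(back$epochs$activity_count, co$epochs$activity_count)
  expect_identical(back$epochs$timestamp, co$epochs$timestamp)
  expect_identical(back$covariates, co$covariates)
  expect_equal(back$rest_intervals$lights_out, co$rest_intervals$lights_out)
})

test_that("the reader recovers every subject with the right group label at scale", {
  cfg <- sim_config(days_per_subject = 2, rng_seed = 21)  # 26 + 33 subjects
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  series <- split(back$epochs, back$epochs$subject_id)
  expect_length(series, 59)
  expect_identical(back$covariates$abeta, co$covariates$abeta)
  expect_true(all(vapply(series, nrow, 0L) == 2 * 2880))
})
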