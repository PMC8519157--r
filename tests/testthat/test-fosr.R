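grid48 <- (1:48 - 0.5) / 2

test_that("the spline basis is a partition of unity and can saturate the grid", {
  for (periodic in c(FALSE, TRUE)) {
    B <- build_basis(grid48, 8, periodic = periodic)
    expect_equal(rowSums(B), rep(1, 48), tolerance = 1e-10)
  }
  Bsat <- build_basis(grid48, 48)
  expect_equal(qr(Bsat)$rank, 48)
  expect_error(build_basis(grid48, 3), "at least 4")
  expect_error(fit_fosr(matrix(rnorm(60), 5, 12), cbind(1, rnorm(5)),
                        n_basis = 13), "exceed")
})

test_that("the periodic basis wraps: fitted values agree at 0 and 24", {
  set.seed(51)
  coefs <- rnorm(8)
  B <- build_basis(c(0, 24), 8, periodic = TRUE)
  expect_equal(as.numeric(B[1, ] %*% coefs), as.numeric(B[2, ] %*% coefs),
               tolerance = 1e-10)
  # non-periodic basis does not
  Bn <- build_basis(c(0, 24), 8, periodic = FALSE)
  expect_false(isTRUE(all.equal(as.numeric(Bn[1, ] %*% coefs),
                                as.numeric(Bn[2, ] %*% coefs))))
})

test_that("noiseless spline-representable coefficients are recovered", {
  set.seed(52)
  n <- 25; q <- 3
  Theta <- build_basis(grid48, 8)
  A <- matrix(rnorm(8 * q), 8, q)
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  Btrue <- t(Theta %*% A)
  Y <- X %*% Btrue
  fit <- fit_fosr(Y, X, grid = grid48, cov = "identity")
  expect_lt(max(abs(fit$beta - Btrue)), 1e-6)
})

test_that("saturated, unpenalized, identity-covariance FOSR is per-bin OLS", {
  set.seed(53)
  n <- 15; Tn <- 8; q <- 3
  X <- cbind(1, rnorm(n), rnorm(n))
  Y <- matrix(rnorm(n * Tn), n, Tn)
  fit <- fit_fosr(Y, X, n_basis = Tn, lambda = 0, cov = "identity")
  ols <- sapply(seq_len(Tn), function(t) lm.fit(X, Y[, t])$coefficients)
  expect_lt(max(abs(fit$beta - ols)), 1e-8)
})

test_that("simultaneous bands contain pointwise bands; exclusion is algebraic", {
  set.seed(54)
  n <- 40
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  Y <- matrix(rnorm(n * 48), n, 48) +
    outer(rep(1, n), 2 * cos(2 * pi * grid48 / 24))
  fit <- fit_fosr(Y, X, grid = grid48)
  pw <- pointwise_band(fit, 2)
  sim <- simultaneous_band(fit, 2, n_sim = 2000, seed = 9)
  expect_true(all(sim$lower <= pw$lower + 1e-12))
  expect_true(all(sim$upper >= pw$upper - 1e-12))
  expect_gte(attr(sim, "q_star"), qnorm(0.975))
  # pointwise band excludes 0 exactly when |estimate|/se > z
  excl <- pw$lower > 0 | pw$upper < 0
  expect_identical(excl, abs(pw$estimate) / pw$se > qnorm(0.975))
  # alpha -> 1 collapses the pointwise band to zero width
  pw1 <- pointwise_band(fit, 2, alpha = 1 - 1e-12)
  expect_lt(max(pw1$upper - pw1$lower), 1e-10)
})

test_that("a rank-one covariance collapses the sup-statistic to one test", {
  se <- runif(48, 0.5, 2)
  C <- outer(se, se)          # perfectly correlated, rank 1
  q_star <- rarfosr:::max_stat_quantile(C, se, alpha = 0.05,
                                        n_sim = 40000, seed = 5)
  expect_equal(q_star, qnorm(0.975), tolerance = 0.03)
})

test_that("collinear designs are rejected with a clear error", {
  set.seed(55)
  n <- 30
  x <- rnorm(n)
  X <- cbind(1, x, x)   # duplicated covariate
  Y <- matrix(rnorm(n * 48), n, 48)
  expect_error(fit_fosr(Y, X), "rank deficient")
  expect_error(global_f_test(Y, X, j = 3), "rank deficient")
})

test_that("the permutation F-test detects a strong localized effect", {
  set.seed(56)
  n <- 40
  X <- cbind(1, c(rep(1, 20), rep(0, 20)))
  bump <- 1.0 * exp(-0.5 * ((grid48 - 15) / 1.5)^2)
  Y <- outer(rep(1, n), 3 + 2 * cos(2 * pi * (grid48 - 14) / 24)) +
    outer(X[, 2], bump) + matrix(rnorm(n * 48, 0, 0.2), n, 48)
  ft <- global_f_test(Y, X, j = 2, n_perm = 199, seed = 3)
  expect_lte(ft$p, 0.01)
  expect_gt(ft$F, 1)
  # determinism given the seed
  ft2 <- global_f_test(Y, X, j = 2, n_perm = 199, seed = 3)
  expect_identical(ft, ft2)
  expect_warning(global_f_test(Y, X, j = 2, n_perm = 50, seed = 1),
                 "unstable")
})

test_that("significant windows merge across midnight and respect signs", {
  t_mid <- grid48
  zero <- data.frame(t = t_mid, estimate = 0, se = 1,
                     lower = -1, upper = 1)
  expect_equal(nrow(significant_windows(zero)), 0)

  # bins covering 23:30-24:00 and 00:00-03:00 exclude zero positively
  band <- zero
  hot <- c(48, 1:6)
  band$lower[hot] <- 0.2; band$upper[hot] <- 1
  w <- significant_windows(band)
  expect_equal(nrow(w), 1)
  expect_equal(w$start_hours, 23.5)
  expect_equal(w$end_hours, 3)
  expect_equal(w$label, "23:30-03:00")
  expect_equal(w$sign, 1L)

  # one isolated negative bin -> a single one-bin window
  band2 <- zero
  band2$upper[20] <- -0.1; band2$lower[20] <- -1
  w2 <- significant_windows(band2)
  expect_equal(nrow(w2), 1)
  expect_equal(w2$sign, -1L)
  expect_equal(w2$end_hours - w2$start_hours, 0.5)
})

test_that("a simulated cohort effect is localized near its injected bump", {
  cfg <- sim_config(n_group_pos = 30, n_group_neg = 30,
                    mean_effect_bumps = list(
                      list(center = 15, width = 0.85, height = 0.5, sign = 1)),
                    rng_seed = 77)
  co <- generate_cohort(cfg)
  rars <- compute_rars(co$epochs)$rars
  res <- fosr_rar(rars, co$covariates, outcome = "mean",
                  n_sim = 1000, n_perm = 0, seed = 2)
  est <- res$fit$beta["abeta", ]
  t_hat <- res$fit$grid[which.max(est)]
  expect_lte(min(abs(t_hat - 15), 24 - abs(t_hat - 15)), 1)
})

test_that("integrated squared error of the group effect shrinks with n", {
  ise <- vapply(c(10, 40), function(n_per) {
    cfg <- sim_config(n_group_pos = n_per, n_group_neg = n_per,
                      rng_seed = 100 + n_per)
    co <- generate_cohort(cfg)
    tr <- cohort_truth(cfg, observed = TRUE)
    delta_obs <- tr$mu_obs_pos - tr$mu_obs_neg
    rars <- compute_rars(co$epochs)$rars
    res <- suppressWarnings(  # n = 20 < 48 bins at the small end by design
      fosr_rar(rars, co$covariates, outcome = "mean",
               n_sim = 100, n_perm = 0, seed = 2))
    mean((res$fit$beta["abeta", ] - delta_obs)^2)
  }, 0)
  expect_lt(ise[2], ise[1])
})
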