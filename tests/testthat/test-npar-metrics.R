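# direct double-loop evaluation of the IS formula, independent of the
# vectorised implementation
oracle_is <- function(m) {
  x <- as.vector(m)
  xbar <- mean(x)
  num <- 0
  for (h in seq_len(ncol(m))) num <- num + (mean(m[, h]) - xbar)^2
  den <- 0
  for (i in seq_along(x)) den <- den + (x[i] - xbar)^2
  length(x) * num / (ncol(m) * den)
}

# direct evaluation of the IV formula over explicit runs
oracle_iv <- function(runs) {
  x <- unlist(runs)
  d2 <- 0; nd <- 0
  for (r in runs) for (i in seq_len(length(r) - 1)) {
    d2 <- d2 + (r[i + 1] - r[i])^2
    nd <- nd + 1
  }
  (length(x) * d2 / nd) / sum((x - mean(x))^2)
}

test_that("IS is 1 for identical days and 0 for day-level shifts only", {
  day <- sin((1:48) / 4) + 2
  expect_equal(interdaily_stability(rbind(day, day, day, day)), 1)
  flat <- matrix(rep(c(1, 2, 3, 4, 5), each = 48), 5, 48, byrow = TRUE)
  expect_equal(interdaily_stability(flat), 0)
})

test_that("IS matches its double-loop oracle and is shift/permutation invariant", {
  set.seed(31)
  m <- matrix(rnorm(5 * 48), 5, 48)
  expect_equal(interdaily_stability(m), oracle_is(m), tolerance = 1e-12)
  expect_equal(interdaily_stability(m + 7), interdaily_stability(m),
               tolerance = 1e-12)
  expect_equal(interdaily_stability(m[sample(5), ]),
               interdaily_stability(m), tolerance = 1e-12)
  expect_warning(expect_true(is.na(
    interdaily_stability(matrix(1, 3, 48)))), "undefined")
})

test_that("IV attains 4 for a strictly alternating sequence", {
  # hand computation: differences all Delta, sum (N-1) Delta^2; centred values
  # +/- Delta/2 give sum of squares N Delta^2 / 4; formula value = 4 exactly
  x <- rep(c(0, 1), 24)
  expect_equal(intradaily_variability(x), 4, tolerance = 1e-12)
  expect_equal(intradaily_variability(x), oracle_iv(list(x)),
               tolerance = 1e-12)
})

test_that("IV of a sampled 24-h cosine matches the lag-1 identity", {
  tt <- (0:47) * 0.5
  x <- cos(2 * pi * tt / 24)
  iv <- intradaily_variability(x)
  # identity via centred first/second moments: S1 + S2 - 2C form
  xc <- x - mean(x)
  S <- sum(xc^2)
  S1 <- sum(xc[-1]^2); S2 <- sum(xc[-48]^2); C <- sum(xc[-1] * xc[-48])
  expect_equal(iv, 48 * (S1 + S2 - 2 * C) / (47 * S), tolerance = 1e-12)
  # and approximately 2(1 - cos(omega * dt)) for a densely sampled period
  # (finite-sample edge effects are O(1/N), so a 5% relative tolerance)
  expect_equal(iv, 2 * (1 - cos(2 * pi * 0.5 / 24)), tolerance = 0.05)
  expect_equal(iv, oracle_iv(list(x)), tolerance = 1e-12)
})

test_that("IV handles runs, missing gaps and degenerate input", {
  expect_warning(expect_true(is.na(intradaily_variability(rep(2, 10)))),
                 "undefined")
  set.seed(32)
  m <- matrix(rnorm(3 * 48, sd = 1) + rep(c(0, 3, 6), 48), 3, 48)
  # per-day runs: matches the oracle fed with the rows
  expect_equal(intradaily_variability(m, per_day = TRUE),
               oracle_iv(asplit(m, 1)), tolerance = 1e-12)
  # concatenated: includes midnight jumps, so differs when days differ in level
  expect_false(isTRUE(all.equal(intradaily_variability(m, per_day = TRUE),
                                intradaily_variability(m, per_day = FALSE))))
  # a missing cell splits the run instead of contributing a difference
  x <- rnorm(20); x_na <- x; x_na[10] <- NA
  expect_equal(intradaily_variability(x_na),
               oracle_iv(list(x[1:9], x[11:20])), tolerance = 1e-12)
})

test_that("RA closed forms: block profile gives RA 1, constant gives RA 0", {
  prof <- c(rep(4, 20), rep(0, 28))   # 10 h active, 14 h at zero
  ra <- relative_amplitude(prof)
  expect_equal(ra$RA, 1)
  expect_equal(ra$M10, 4)
  expect_equal(ra$L5, 0)
  expect_equal(relative_amplitude(rep(3, 48))$RA, 0)
})

test_that("RA matches an exhaustive circular window scan with earliest-tie rule", {
  scan_ra <- function(p, w) {
    best <- Inf; worst <- -Inf; bi <- wi <- NA
    for (s in seq_along(p)) {
      idx <- ((s - 1 + 0:(w - 1)) %% length(p)) + 1
      m <- mean(p[idx])
      if (m > worst + 1e-15) { worst <- m; wi <- s }
      if (m < best - 1e-15) { best <- m; bi <- s }
    }
    list(max = worst, max_onset = (wi - 1) / 2,
         min = best, min_onset = (bi - 1) / 2)
  }
  set.seed(33)
  for (rep in 1:3) {
    p <- abs(rnorm(48)) + 0.5
    ra <- relative_amplitude(p)
    o10 <- scan_ra(p, 20)
    o5 <- scan_ra(p, 10)
    expect_equal(ra$M10, o10$max, tolerance = 1e-12)
    expect_equal(ra$L5, o5$min, tolerance = 1e-12)
    expect_equal(ra$M10_onset, o10$max_onset)
    expect_equal(ra$L5_onset, o5$min_onset)
    expect_equal(ra$RA, (o10$max - o5$min) / (o10$max + o5$min),
                 tolerance = 1e-12)
  }
})

test_that("L5 windows wrap midnight", {
  # trough centred on midnight: bins 44..48 and 1..5 are the low block
  prof <- rep(5, 48)
  prof[c(44:48, 1:5)] <- 0.1
  ra <- relative_amplitude(prof)
  expect_equal(ra$L5, 0.1)
  expect_gte(ra$L5_onset, 21.5)  # window must start before midnight
})

test_that("the subject-level wrapper computes all metrics on one object", {
  set.seed(34)
  day <- 3 + 2 * cos(2 * pi * ((1:48 - 0.5) / 2 - 15) / 24)
  v <- rbind(day, day, day) + matrix(rnorm(3 * 48, 0, 0.05), 3, 48)
  out <- npar_metrics(make_pm(v))
  expect_true(out$IS > 0.9)           # nearly identical days
  expect_true(out$IV < 0.2)           # smooth rhythm
  expect_true(out$RA > 0 && out$RA <= 1)
  expect_true(out$L5 <= out$M10)
})
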