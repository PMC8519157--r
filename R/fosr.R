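## Function-on-scalar regression (FOSR) by penalized generalized least
## squares on a spline basis.
##
## Model: Y[i, t] = sum_j X[i, j] * beta_j(t) + e_i(t), with each
## coefficient function beta_j(t) = Theta(t) %*% a_j expanded in a common
## K-dimensional spline basis and a roughness penalty on each a_j. The
## Kronecker structure of the normal equations keeps every solve at
## (q*K) x (q*K), so fits are cheap even inside permutation loops.

#' Spline basis for coefficient functions
#'
#' Cubic B-spline basis on the 24-hour clock, evaluated on the bin-midpoint
#' grid. The non-periodic default mirrors the common FOSR practice of
#' ignoring the circularity of the day; the periodic variant wraps the
#' basis so every representable function satisfies f(0) = f(24).
#'
#' @param grid numeric vector of evaluation points (clock hours in
#'   `[0, 24]`).
#' @param n_basis number of basis functions (≥ 4 for cubic splines).
#' @param periodic wrap the basis around midnight?
#' @param degree spline degree (default cubic).
#' @param period period in hours (default 24).
#' @return `length(grid)` × `n_basis` basis matrix.
#' @export
build_basis <- function(grid, n_basis = 8, periodic = FALSE, degree = 3,
                        period = 24) {
  if (n_basis < degree + 1)
    stop_stage("fosr", "n_basis must be at least ", degree + 1,
               " for degree-", degree, " splines")
  if (!periodic) {
    B <- splines::bs(grid, df = n_basis, degree = degree, intercept = TRUE,
                     Boundary.knots = c(0, period))
    return(unname(matrix(as.numeric(B), nrow = length(grid))))
  }
  h <- period / n_basis
  knots <- seq(-degree * h, period + degree * h, by = h)
  B <- splines::splineDesign(knots, x = grid %% period, ord = degree + 1,
                             outer.ok = TRUE)
  # fold the overhanging columns back onto the first ones (period wrap)
  out <- B[, seq_len(n_basis), drop = FALSE]
  extra <- ncol(B) - n_basis
  if (extra > 0)
    out[, seq_len(extra)] <- out[, seq_len(extra)] +
      B[, n_basis + seq_len(extra), drop = FALSE]
  unname(out)
}

# difference-based roughness penalty on the basis coefficients
penalty_matrix <- function(n_basis, order = 2, periodic = FALSE) {
  if (!periodic) {
    D <- diff(diag(n_basis), differences = order)
  } else {
    D <- matrix(0, n_basis, n_basis)
    coefs <- choose(order, 0:order) * (-1)^(0:order)
    for (i in seq_len(n_basis))
      for (k in 0:order)
        D[i, ((i + k - 1) %% n_basis) + 1] <-
          D[i, ((i + k - 1) %% n_basis) + 1] + coefs[k + 1]
  }
  crossprod(D)
}

# penalized (generalized) least-squares solve; returns coefficients and the
# quantities GCV needs. lambda is a length-q vector of per-coefficient
# smoothing parameters.
fosr_solve <- function(Y, X, Theta, P, lambda, W) {
  q <- ncol(X)
  K <- ncol(Theta)
  XtX <- crossprod(X)
  TW <- crossprod(Theta, W)        # K x T
  M <- TW %*% Theta                # K x K
  Cmat <- TW %*% crossprod(Y, X)   # K x q
  G <- kronecker(XtX, M) + kronecker(diag(lambda, q), P)
  Ginv <- tryCatch(solve(G), error = function(e)
    stop_stage("fosr", sprintf(
      "singular penalized normal equations (condition number %.3g)",
      kappa(G))))
  alpha <- Ginv %*% as.vector(Cmat)
  A <- matrix(alpha, K, q)
  B <- t(Theta %*% A)              # q x T coefficient functions
  E <- Y - X %*% B
  edf <- sum(Ginv * kronecker(XtX, M))  # tr(Ginv %*% (XtX (x) M))
  rss_w <- sum(E * (E %*% W))
  list(A = A, B = B, E = E, edf = edf, rss_w = rss_w, Ginv = Ginv,
       XtX = XtX, M = M)
}

# GCV selection of a common smoothing parameter over a log-spaced grid
fosr_gcv <- function(Y, X, Theta, P, lambda_grid, W) {
  nT <- length(Y)
  scores <- vapply(lambda_grid, function(l) {
    s <- fosr_solve(Y, X, Theta, P, rep(l, ncol(X)), W)
    nT * s$rss_w / (nT - s$edf)^2
  }, 0)
  list(lambda = lambda_grid[which.min(scores)],
       table = data.frame(lambda = lambda_grid, gcv = scores))
}

# cluster-robust (by-subject) sandwich covariance of the stacked basis
# coefficients: G^-1 [ sum_i (x_i x_i') (x) (Theta' W e_i e_i' W Theta) ] G^-1
# with an n/(n - q) small-sample factor. Valid for any working weight W.
fosr_sandwich <- function(X, Theta, W, E, Ginv) {
  n <- nrow(X); q <- ncol(X); K <- ncol(Theta)
  Gc <- crossprod(Theta, W %*% t(E))        # K x n, col i = Theta' W e_i
  U <- matrix(0, n, q * K)
  for (j in seq_len(q))
    U[, (j - 1) * K + seq_len(K)] <- X[, j] * t(Gc)
  S <- crossprod(U) * n / max(n - q, 1)
  Ginv %*% S %*% Ginv
}

#' Fit a function-on-scalar regression by penalized GLS
#'
#' Three-step estimator. Step 1: penalized OLS of the outcome functions on
#' the scalar design, with a difference roughness penalty on each
#' coefficient function and a common smoothing parameter chosen by
#' generalized cross-validation. Step 2: estimate the residual covariance
#' over the grid from the Step-1 residual functions and shrink it toward
#' its diagonal. Step 3: re-estimate by penalized GLS with the inverse
#' shrunk covariance as the working weight (GCV re-run in the weighted
#' metric). Standard errors come from a cluster-robust sandwich over
#' subjects' residual functions, which stays valid whatever the working
#' weight.
#'
#' The default `cov_shrink = 1` weights bins by their inverse residual
#' variance but treats them as working-independent, in the GEE tradition.
#' Full inverse-covariance weighting (`cov_shrink` near 0) is only
#' advisable when subjects far outnumber bins: with as many bins as
#' subjects the empirical covariance inverse is dominated by noise, the
#' fit chases it, and confidence bands undercover badly (the vignette
#' quantifies this).
#'
#' @param Y subjects × bins outcome matrix (mean or SD profiles); no
#'   missing cells.
#' @param X subjects × q design matrix (first column the intercept);
#'   must be full column rank.
#' @param grid bin-midpoint clock hours (default equally spaced midpoints
#'   over 24 h).
#' @param n_basis number of spline basis functions (default 8).
#' @param periodic use the midnight-wrapped basis and penalty?
#' @param lambda optional fixed smoothing parameter (scalar or length-q);
#'   `NULL` (default) selects it by GCV. `0` gives an unpenalized fit.
#' @param lambda_grid GCV search grid.
#' @param cov `"gls"` (default) for the three-step estimator, or
#'   `"identity"` to stop after Step 1 (unit working weight, classical
#'   model-based covariance) — the mode used by the per-bin OLS oracle
#'   identity and by noiseless recovery checks, where a residual
#'   covariance cannot be estimated.
#' @param cov_shrink diagonal shrinkage weight in `[0, 1]` for the working
#'   covariance (default 1: inverse-variance bin weights).
#' @param penalty_order difference order of the roughness penalty
#'   (default 2, so linear coefficient functions are unpenalized).
#' @return an object of class `fosr_fit`: list with `beta` (q × bins
#'   coefficient functions), `se` (q × bins pointwise standard errors),
#'   `alpha` (basis coefficients), `Valpha` (their covariance), `Theta`,
#'   `grid`, `lambda`, `edf`, `Sigma` (shrunk residual covariance, GLS
#'   only), `gcv` (search table), plus the inputs `X`, `Y`.
#' @seealso [pointwise_band()], [simultaneous_band()], [global_f_test()],
#'   [significant_windows()]
#' @export
fit_fosr <- function(Y, X, grid = NULL, n_basis = 8, periodic = FALSE,
                     lambda = NULL,
                     lambda_grid = 10^seq(-8, 8, length.out = 33),
                     cov = c("gls", "identity"), cov_shrink = 1,
                     penalty_order = 2) {
  cov <- match.arg(cov)
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  n <- nrow(Y); Tn <- ncol(Y); q <- ncol(X)
  stopifnot(nrow(X) == n)
  if (anyNA(Y)) stop_stage("fosr", "Y must have no missing cells")
  if (n_basis > Tn)
    stop_stage("fosr", "n_basis cannot exceed the number of bins")
  if (qr(X)$rank < q)
    stop_stage("fosr", "design matrix is rank deficient (collinear columns)")
  if (is.null(grid)) grid <- (seq_len(Tn) - 0.5) * 24 / Tn
  Theta <- build_basis(grid, n_basis, periodic)
  P <- penalty_matrix(n_basis, penalty_order, periodic)
  I_T <- diag(Tn)

  pick <- function(W) {
    if (!is.null(lambda)) {
      list(lambda = if (length(lambda) == 1) rep(lambda, q) else lambda,
           table = NULL)
    } else {
      g <- fosr_gcv(Y, X, Theta, P, lambda_grid, W)
      list(lambda = rep(g$lambda, q), table = g$table)
    }
  }

  sel1 <- pick(I_T)
  s1 <- fosr_solve(Y, X, Theta, P, sel1$lambda, I_T)

  if (cov == "identity") {
    nT <- n * Tn
    sigma2 <- sum(s1$E^2) / max(nT - s1$edf, 1)
    Valpha <- sigma2 * s1$Ginv %*% kronecker(s1$XtX, s1$M) %*% s1$Ginv
    fit <- list(beta = s1$B, alpha = s1$A, Valpha = Valpha, lambda = sel1$lambda,
                edf = s1$edf, Sigma = NULL, gcv = sel1$table, W = I_T)
  } else {
    Sigma <- crossprod(s1$E) / max(n - q, 1)
    Sigma_s <- (1 - cov_shrink) * Sigma +
      cov_shrink * diag(diag(Sigma), Tn)
    ch <- tryCatch(chol(Sigma_s), error = function(e)
      stop_stage("fosr", "residual covariance not positive definite after ",
                 "diagonal shrinkage; increase cov_shrink"))
    W <- chol2inv(ch)
    sel2 <- pick(W)
    s2 <- fosr_solve(Y, X, Theta, P, sel2$lambda, W)
    Valpha <- fosr_sandwich(X, Theta, W, s2$E, s2$Ginv)
    fit <- list(beta = s2$B, alpha = s2$A, Valpha = Valpha,
                lambda = sel2$lambda, edf = s2$edf, Sigma = Sigma_s,
                gcv = sel2$table, W = W)
  }

  K <- n_basis
  se <- matrix(NA_real_, q, Tn)
  for (j in seq_len(q)) {
    Vjj <- fit$Valpha[(j - 1) * K + seq_len(K), (j - 1) * K + seq_len(K)]
    se[j, ] <- sqrt(pmax(rowSums((Theta %*% Vjj) * Theta), 0))
  }
  nm <- colnames(X)
  if (!is.null(nm)) rownames(fit$beta) <- rownames(se) <- nm
  structure(c(fit, list(se = se, Theta = Theta, grid = grid, X = X, Y = Y,
                        n_basis = n_basis, periodic = periodic,
                        penalty_order = penalty_order, cov = cov)),
            class = "fosr_fit")
}

#' @export
print.fosr_fit <- function(x, ...) {
  cat(sprintf(
    "fosr_fit: %d subjects, %d bins, %d covariates, %d basis fns (%s), edf %.1f\n",
    nrow(x$X), ncol(x$Y), nrow(x$beta), x$n_basis,
    if (x$periodic) "periodic" else "non-periodic", x$edf))
  invisible(x)
}

# grid covariance of one coefficient function
coef_cov <- function(fit, j) {
  K <- fit$n_basis
  idx <- (j - 1) * K + seq_len(K)
  fit$Theta %*% fit$Valpha[idx, idx] %*% t(fit$Theta)
}

#' Pointwise confidence band for a coefficient function
#'
#' `beta_j(t) ± z_(1−α/2) · SE_j(t)` at every grid point.
#'
#' @param fit a `fosr_fit`.
#' @param j coefficient index (1 = intercept).
#' @param alpha significance level (default 0.05).
#' @return data.frame `t`, `estimate`, `se`, `lower`, `upper`.
#' @export
pointwise_band <- function(fit, j, alpha = 0.05) {
  z <- stats::qnorm(1 - alpha / 2)
  data.frame(t = fit$grid, estimate = fit$beta[j, ], se = fit$se[j, ],
             lower = fit$beta[j, ] - z * fit$se[j, ],
             upper = fit$beta[j, ] + z * fit$se[j, ])
}

# (1-alpha) quantile of max_t |Z(t)|/se(t) for Z ~ N(0, C), by simulation
max_stat_quantile <- function(C, se, alpha, n_sim, seed) {
  eig <- eigen(C, symmetric = TRUE)
  tol <- -1e-8 * max(abs(eig$values))
  if (any(eig$values < tol))
    stop_stage("fosr", "coefficient covariance is not positive semidefinite")
  vals <- pmax(eig$values, 0)
  L <- eig$vectors %*% diag(sqrt(vals), length(vals))
  with_local_seed(seed, {
    Z <- L %*% matrix(stats::rnorm(length(se) * n_sim), ncol = n_sim)
    maxes <- apply(abs(Z) / se, 2, max)
    unname(stats::quantile(maxes, 1 - alpha))
  })
}

#' Simultaneous confidence band for a coefficient function
#'
#' Parametric max-statistic construction: draws `n_sim` Gaussian vectors
#' from the estimated covariance of the coefficient function on the grid,
#' takes the `1−α` quantile `q*` of the standardized sup-statistic
#' `max_t |Z(t)|/SE(t)`, and reports `beta_j(t) ± q* · SE_j(t)`. The band
#' has joint (familywise) coverage over the whole grid and always contains
#' the pointwise band. Deterministic given `seed`.
#'
#' @inheritParams pointwise_band
#' @param n_sim number of Gaussian draws (default 10000).
#' @param seed RNG seed for the draws (required for reproducibility).
#' @return data.frame `t`, `estimate`, `se`, `lower`, `upper`, with the
#'   critical value in `attr(, "q_star")`.
#' @export
simultaneous_band <- function(fit, j, alpha = 0.05, n_sim = 10000,
                              seed = 1) {
  se <- fit$se[j, ]
  if (any(se <= 0))
    stop_stage("fosr", "zero standard error; simultaneous band undefined")
  q_star <- max_stat_quantile(coef_cov(fit, j), se, alpha, n_sim, seed)
  out <- data.frame(t = fit$grid, estimate = fit$beta[j, ], se = se,
                    lower = fit$beta[j, ] - q_star * se,
                    upper = fit$beta[j, ] + q_star * se)
  attr(out, "q_star") <- q_star
  out
}

#' Global permutation F-test for one covariate's functional effect
#'
#' Compares the full fit against the fit without covariate `j` through the
#' residual sum of squares integrated over the grid,
#' `F = [(RSS_r − RSS_f)/df1] / [RSS_f/df2]` with effective degrees of
#' freedom from the penalized fits. The p-value is obtained by permuting
#' covariate `j`'s column across subjects and recomputing F each time
#' (smoothing parameters and the GLS weight are held at their observed-data
#' values), so it does not rely on an asymptotic reference distribution.
#' Deterministic given `seed`.
#'
#' @inheritParams fit_fosr
#' @param j index of the covariate column to test (not the intercept).
#' @param n_perm number of permutations (default 999; fewer than 99 gives
#'   an unstable p-value and a warning).
#' @param seed RNG seed for the permutations.
#' @return list with `F`, `p`, `df1`, `df2`, `n_perm`.
#' @export
global_f_test <- function(Y, X, j, grid = NULL, n_basis = 8,
                          periodic = FALSE, cov = c("gls", "identity"),
                          cov_shrink = 1, penalty_order = 2,
                          n_perm = 999, seed = 1) {
  cov <- match.arg(cov)
  Y <- as.matrix(Y); X <- as.matrix(X)
  q <- ncol(X)
  if (j == 1) stop_stage("fosr", "j must index a non-intercept covariate")
  if (qr(X)$rank < q)
    stop_stage("fosr", "design matrix is rank deficient (collinear columns)",
               "; cannot attribute the effect to column ", j)
  if (n_perm < 99) warning("n_perm < 99: permutation p-value is unstable")

  full <- fit_fosr(Y, X, grid, n_basis, periodic, cov = cov,
                   cov_shrink = cov_shrink, penalty_order = penalty_order)
  W <- full$W
  lam <- full$lambda
  Theta <- full$Theta
  P <- penalty_matrix(n_basis, penalty_order, periodic)

  f_stat <- function(Xp) {
    sf <- fosr_solve(Y, Xp, Theta, P, lam, W)
    sr <- fosr_solve(Y, Xp[, -j, drop = FALSE], Theta, P, lam[-j], W)
    rss_f <- sum((Y - Xp %*% sf$B)^2)
    rss_r <- sum((Y - Xp[, -j, drop = FALSE] %*% sr$B)^2)
    df1 <- max(sf$edf - sr$edf, .Machine$double.eps)
    df2 <- max(length(Y) - sf$edf, 1)
    ((rss_r - rss_f) / df1) / (rss_f / df2)
  }

  F_obs <- f_stat(X)
  F_perm <- with_local_seed(seed, vapply(seq_len(n_perm), function(b) {
    Xp <- X
    Xp[, j] <- X[sample(nrow(X)), j]
    f_stat(Xp)
  }, 0))
  sf <- fosr_solve(Y, X, Theta, P, lam, W)
  sr <- fosr_solve(Y, X[, -j, drop = FALSE], Theta, P, lam[-j], W)
  list(F = F_obs, p = (1 + sum(F_perm >= F_obs)) / (1 + n_perm),
       df1 = sf$edf - sr$edf, df2 = length(Y) - sf$edf, n_perm = n_perm)
}

#' Clock-time windows where a band excludes zero
#'
#' Finds maximal runs of consecutive bins whose confidence band lies
#' entirely above (sign +1) or below (sign −1) zero, merging runs across
#' the midnight wrap, and reports them as clock-time windows covering the
#' full bin extents.
#'
#' @param band data.frame from [pointwise_band()] or
#'   [simultaneous_band()].
#' @return data.frame `start_hours`, `end_hours`, `sign`, `label`
#'   ("HH:MM-HH:MM"; `start > end` indicates a window wrapping midnight).
#'   Zero rows when the band nowhere excludes zero.
#' @export
significant_windows <- function(band) {
  n <- nrow(band)
  sgn <- ifelse(band$lower > 0, 1L, ifelse(band$upper < 0, -1L, 0L))
  empty <- data.frame(start_hours = numeric(0), end_hours = numeric(0),
                      sign = integer(0), label = character(0))
  if (all(sgn == 0)) return(empty)
  w <- if (n > 1) diff(band$t)[1] else 24
  r <- rle(sgn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  runs <- data.frame(first = starts[keep], last = ends[keep],
                     sign = r$values[keep])
  # merge across midnight when the first and last bins continue a run
  if (nrow(runs) > 1 && runs$first[1] == 1L && runs$last[nrow(runs)] == n &&
      runs$sign[1] == runs$sign[nrow(runs)]) {
    runs$first[1] <- runs$first[nrow(runs)]
    runs <- runs[-nrow(runs), , drop = FALSE]
  }
  start_h <- (band$t[runs$first] - w / 2) %% 24
  end_h <- (band$t[runs$last] + w / 2) %% 24
  data.frame(start_hours = start_h, end_hours = end_h, sign = runs$sign,
             label = paste0(clock_label(start_h), "-", clock_label(end_h)),
             stringsAsFactors = FALSE)
}

#' FOSR of subject RAR profiles on cohort covariates
#'
#' Assembles the functional design from per-subject RARs and the covariate
#' table — outcome rows are mean (or across-day SD) profiles of included
#' subjects; design columns are intercept, mean-centred age, sex
#' (1 = female), mean-centred education years, and group status
#' (1 = positive) — then fits the penalized-GLS FOSR and computes both
#' bands, their significant windows, and the permutation F-test for the
#' group effect.
#'
#' @param rars named list of `rar_subject` objects (see [compute_rars()]).
#' @param covariates covariate data.frame (`subject_id`, `age`, `sex`,
#'   `education_years`, `abeta`).
#' @param outcome `"mean"` or `"sd"` profile.
#' @param alpha significance level for bands.
#' @param n_sim Gaussian draws for the simultaneous band.
#' @param n_perm permutations for the F-test (0 skips the test).
#' @param seed RNG seed for band simulation and permutations.
#' @inheritParams fit_fosr
#' @return list with `fit`, `pointwise`, `simultaneous`,
#'   `windows_pointwise`, `windows_simultaneous`, `f_test`, `subjects`.
#' @export
fosr_rar <- function(rars, covariates, outcome = c("mean", "sd"),
                     n_basis = 8, periodic = FALSE, alpha = 0.05,
                     n_sim = 10000, n_perm = 999, seed = 1,
                     cov_shrink = 1) {
  outcome <- match.arg(outcome)
  rars <- Filter(function(r) !r$excluded, rars)
  if (!length(rars)) stop_stage("fosr", "no included subjects")
  ids <- vapply(rars, `[[`, "", "subject_id")
  Y <- do.call(rbind, lapply(rars, function(r)
    if (outcome == "mean") r$mean_profile else r$sd_profile))
  rownames(Y) <- ids
  cv <- covariates[match(ids, covariates$subject_id), ]
  X <- cbind(intercept = 1,
             age = cv$age - mean(cv$age),
             sex = as.numeric(cv$sex == "F"),
             education = cv$education_years - mean(cv$education_years),
             abeta = as.numeric(cv$abeta == "pos"))
  if (ncol(Y) >= nrow(Y))
    warning(sprintf(
      "%d bins >= %d subjects: FOSR may be numerically unstable; %s",
      ncol(Y), nrow(Y), "consider coarser bins"))
  grid <- rars[[1]]$grid
  fit <- fit_fosr(Y, X, grid = grid, n_basis = n_basis, periodic = periodic,
                  cov_shrink = cov_shrink)
  j <- which(colnames(X) == "abeta")
  pw <- pointwise_band(fit, j, alpha)
  sim <- simultaneous_band(fit, j, alpha, n_sim = n_sim, seed = seed)
  ft <- if (n_perm > 0)
    global_f_test(Y, X, j, grid = grid, n_basis = n_basis,
                  periodic = periodic, cov_shrink = cov_shrink,
                  n_perm = n_perm, seed = seed) else NULL
  list(fit = fit, pointwise = pw, simultaneous = sim,
       windows_pointwise = significant_windows(pw),
       windows_simultaneous = significant_windows(sim),
       f_test = ft, subjects = ids)
}
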