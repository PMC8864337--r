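#' Circular mean direction
#'
#' Angle of the vector sum of the unit vectors of a circular sample.
#'
#' @param angles numeric vector of angles, radians.
#' @return the mean direction in `(-pi, pi]`; errors when the resultant
#'   length is numerically zero (the direction is then undefined).
#' @export
circular_mean <- function(angles) {
  s <- mean(sin(angles)); c <- mean(cos(angles))
  if (sqrt(s^2 + c^2) < 1e-12) stop("mean direction undefined: zero resultant")
  atan2(s, c)
}

# Recentre angles to (-pi, pi] around `centre` and return values on the
# natural scale near the centre (centre + wrapped deviation). Prevents
# +/-pi wrap artifacts in linear summaries of location chains.
recentre_angles <- function(x, centre = circular_mean(x)) {
  centre + wrap_pi(x - centre)
}

# which chain columns hold location angles (treated circularly)
mu_columns <- function(p) if (p == 2L) "mu" else c("mu1", "mu2")

# argmax of a kernel density estimate: the zero-one-loss (mode) estimator.
kde_mode <- function(x) {
  if (stats::sd(x) < 1e-12) return(x[1L])
  d <- stats::density(x, n = 512, bw = "nrd0")
  d$x[which.max(d$y)]
}

#' Loss-based chain summaries
#'
#' Per-parameter posterior mean, sd, quartiles and KDE mode of the kept
#' states: the mean, median and mode are the Bayes estimators under
#' squared-error, absolute-error and zero-one loss. Location angles are
#' recentred to the chain's circular mean before the linear statistics are
#' taken, so chains straddling +/-pi summarize correctly. Quantiles use
#' linear interpolation of order statistics (type 7); the mode is the
#' argmax of a Gaussian KDE on a 512-point grid with Silverman bandwidth.
#'
#' @param chain an `sfvml_chain`.
#' @return data.frame with one row per parameter and columns
#'   `parameter, mean, sd, q1, median, q3, mode`.
#' @export
summarize_chain <- function(chain) {
  ks <- kept_states(chain)
  if (nrow(ks) < 10) stop("need at least 10 kept states")
  mu_cols <- mu_columns(chain$p)
  out <- lapply(colnames(ks), function(nm) {
    v <- ks[, nm]
    if (nm %in% mu_cols) v <- recentre_angles(v)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(parameter = nm, mean = mean(v), sd = stats::sd(v),
               q1 = q[1L], median = q[2L], q3 = q[3L], mode = kde_mode(v))
  })
  do.call(rbind, out)
}

#' Running mean of a chain parameter
#'
#' Cumulative means over the kept states (location angles recentred as in
#' [summarize_chain()], so the final value equals the summary mean
#' exactly). The standard within-chain convergence diagnostic: the series
#' should settle quickly at the overall mean.
#'
#' @param chain an `sfvml_chain`.
#' @param parameter column name, e.g. `"mu"`, `"tau"`, `"gamma"`.
#' @return numeric vector of cumulative means.
#' @export
running_mean <- function(chain, parameter) {
  v <- kept_states(chain)[, parameter]
  if (parameter %in% mu_columns(chain$p)) v <- recentre_angles(v)
  cumsum(v) / seq_along(v)
}

#' Whole-chain versus tail density comparison
#'
#' Kernel density tables of the whole kept chain and of its last fraction
#' on a common grid, with their L1 distance as a scalar mixing indicator
#' (0 when the tail samples the same distribution as the whole chain).
#'
#' @param chain an `sfvml_chain`.
#' @param parameter column name.
#' @param tail_fraction fraction of the kept chain forming the tail,
#'   in `(0, 1]`.
#' @return list with `table` (data.frame `grid`, `whole`, `tail`) and `l1`.
#' @export
compare_partial <- function(chain, parameter, tail_fraction = 0.1) {
  stopifnot(tail_fraction > 0, tail_fraction <= 1)
  v <- kept_states(chain)[, parameter]
  if (parameter %in% mu_columns(chain$p)) v <- recentre_angles(v)
  ntail <- max(2L, ceiling(tail_fraction * length(v)))
  tail_v <- v[(length(v) - ntail + 1L):length(v)]
  if (stats::sd(v) < 1e-12) {
    grid <- seq(v[1L] - 1, v[1L] + 1, length.out = 512L)
    return(list(table = data.frame(grid = grid, whole = 0, tail = 0), l1 = 0))
  }
  rng <- range(v)
  pad <- 0.2 * diff(rng)
  grid <- seq(rng[1L] - pad, rng[2L] + pad, length.out = 512L)
  dw <- stats::density(v, n = 512L, from = grid[1L], to = grid[512L])$y
  dt <- stats::density(tail_v, n = 512L, from = grid[1L], to = grid[512L])$y
  if (tail_fraction == 1) dt <- dw
  l1 <- sum(abs(dw - dt)) * (grid[2L] - grid[1L])
  list(table = data.frame(grid = grid, whole = dw, tail = dt), l1 = l1)
}

#' Large-sample test of circular reflective symmetry
#'
#' Second-sine-moment test: `b2 = mean(sin 2(theta - mean direction))` is 0
#' under reflective symmetry about the mean direction; the standardized
#' statistic is compared with the standard normal quantiles. The variance
#' of `b2` accounts for estimation of the mean direction via the delta
#' method and is built from the sample trigonometric moments
#' `a_k = mean(cos k(theta - mean direction))`:
#' `n var(b2) = (1 - a4)/2 + 2 a2^2 (1 - a2)/a1^2 - 2 a2 (a1 - a3)/a1`.
#'
#' @param angles numeric vector of angles, radians (`n >= 10`).
#' @return list of class `symmetry_test` with `b2bar`, `z`, `p_value`,
#'   `n` and the mean direction.
#' @export
pewsey_symmetry_test <- function(angles) {
  n <- length(angles)
  stopifnot(n >= 10)
  thbar <- circular_mean(angles)
  d <- angles - thbar
  b2 <- mean(sin(2 * d))
  a1 <- mean(cos(d)); a2 <- mean(cos(2 * d))
  a3 <- mean(cos(3 * d)); a4 <- mean(cos(4 * d))
  v <- (1 - a4) / 2 + 2 * a2^2 * (1 - a2) / a1^2 - 2 * a2 * (a1 - a3) / a1
  v <- max(v, 1e-12)
  z <- sqrt(n) * b2 / sqrt(v)
  structure(list(b2bar = b2, z = z, p_value = 2 * stats::pnorm(-abs(z)),
                 n = n, mean_direction = thbar),
            class = "symmetry_test")
}

#' @export
print.symmetry_test <- function(x, ...) {
  cat(sprintf("Reflective symmetry test (second sine moment), n = %d\n", x$n))
  cat(sprintf("  b2bar = %.5f, z = %.4f, p-value = %.4f\n",
              x$b2bar, x$z, x$p_value))
  invisible(x)
}

#' Maximum likelihood fit of the skew-FvML model
#'
#' Numerical maximization of the probit-skewed log-likelihood over
#' `(mu_angles, log tau, gamma)` from moment initial values (mean
#' direction, moment concentration). The symmetric fit is an exact
#' stationary point of the skewed likelihood (the skewness score vanishes
#' when the sine moment about the fitted location is zero), so the
#' optimizer is multi-started from symmetric and skewed initial values and
#' the best optimum kept. Non-convergence is flagged on the result, not
#' raised.
#'
#' @param data a [direction_sample()].
#' @param fix_gamma optional value at which to fix the skewness (e.g. 0 for
#'   the symmetric FvML fit).
#' @return list with `params` (an [sfvml_params()]), `loglik`, `converged`,
#'   and asymptotic standard errors `se` (from the numerical Hessian; `NA`
#'   where the Hessian is not positive definite).
#' @export
mle_fit <- function(data, fix_gamma = NULL) {
  p <- unit_p(data)
  n <- nrow(data)
  stopifnot(n >= p + 2)
  init <- auto_init(data, NULL)
  d_mu <- p - 1L
  free_gamma <- is.null(fix_gamma)
  unpack <- function(th) {
    gamma <- if (free_gamma) th[(d_mu + 2L):(2L * d_mu + 1L)]
             else rep_len(fix_gamma, d_mu)
    sfvml_params(mu = th[seq_len(d_mu)], tau = exp(th[d_mu + 1L]),
                 gamma = gamma)
  }
  negll <- function(th) -log_likelihood(data, unpack(th))
  lo <- c(rep(-2 * pi, d_mu), log(1e-4), if (free_gamma) rep(-50, d_mu))
  hi <- c(rep(2 * pi, d_mu), log(1e4), if (free_gamma) rep(50, d_mu))
  # Skewness pulls the mean direction away from the location parameter, so
  # the moment init can sit in the wrong basin; multi-start over location
  # offsets and skewness signs and keep the best optimum.
  gamma_starts <- if (free_gamma) c(-2, 0, 2) else 0
  mu_offsets <- if (free_gamma) c(-1, 0, 1) else 0
  fit <- NULL
  for (g0 in gamma_starts) {
    for (dm in mu_offsets) {
      theta0 <- c(init$mu + dm * c(1, rep(0, d_mu - 1L)), log(init$tau),
                  if (free_gamma) rep(g0, d_mu))
      f <- stats::optim(theta0, negll, method = "L-BFGS-B",
                        lower = lo, upper = hi,
                        control = list(maxit = 500))
      if (is.null(fit) || f$value < fit$value) fit <- f
    }
  }
  se <- rep(NA_real_, length(theta0))
  H <- try(stats::optimHess(fit$par, negll), silent = TRUE)
  if (!inherits(H, "try-error")) {
    Hi <- try(solve(H), silent = TRUE)
    if (!inherits(Hi, "try-error")) {
      dg <- diag(Hi)
      se[dg > 0] <- sqrt(dg[dg > 0])
    }
  }
  params <- unpack(fit$par)
  # report se on the natural tau scale (delta method from log tau)
  se_nat <- se
  se_nat[d_mu + 1L] <- se[d_mu + 1L] * params$tau
  names(se_nat) <- c(mu_columns(p), "tau",
                     if (free_gamma) paste0("gamma", if (p == 3L) 1:2 else ""))
  list(params = params, loglik = -fit$value,
       converged = fit$convergence == 0, se = se_nat)
}

# squared estimation error with angular wrapping on location components
estimation_sq_error <- function(est, truth, p) {
  err <- est - truth
  idx <- seq_len(p - 1L)
  err[idx] <- wrap_pi(err[idx])
  err^2
}

#' Relative efficiency of Bayes estimators versus maximum likelihood
#'
#' Monte-Carlo study: over `reps` independent datasets per sample size,
#' computes the MSE of the posterior mean (squared-error loss) and
#' posterior median (absolute-error loss) from a Gibbs chain, and of the
#' MLE, then reports `RE1 = MSE(mean)/MSE(MLE)` and
#' `RE2 = MSE(median)/MSE(MLE)` per parameter and sample size. Values
#' below 1 favour the Bayes estimator.
#'
#' @param truth an [sfvml_params()], the generating parameters.
#' @param spec a [scenario_spec()].
#' @param n_list sample sizes.
#' @param reps Monte-Carlo replications per sample size.
#' @param B,N,k chain configuration passed to [run_chain()].
#' @param seed optional integer seed.
#' @return data.frame with columns `n, parameter, re1, re2, mse_mle,
#'   mse_mean, mse_median`.
#' @export
relative_efficiency <- function(truth, spec, n_list, reps, B = 400, N = 250,
                                k = 150, seed = NULL) {
  stopifnot(inherits(truth, "sfvml_params"), reps >= 2)
  p <- truth$p
  pn <- param_names(p)
  truth_vec <- c(truth$mu, truth$tau, truth$gamma)
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1L)
  res <- list()
  for (n in n_list) {
    sq <- matrix(0, 3, length(pn), dimnames = list(NULL, pn))
    for (r in seq_len(reps)) {
      s_data <- derive_seed(seed, sprintf("re-data-%d-%d", n, r))
      s_chain <- derive_seed(seed, sprintf("re-chain-%d-%d", n, r))
      data <- sample_sfvml(n, truth, seed = s_data)
      ml <- mle_fit(data)
      ml_vec <- c(ml$params$mu, ml$params$tau, ml$params$gamma)
      ch <- run_chain(data, spec, B = B, N = N, k = k, seed = s_chain)
      sm <- summarize_chain(ch)
      sq[1, ] <- sq[1, ] + estimation_sq_error(ml_vec, truth_vec, p)
      sq[2, ] <- sq[2, ] + estimation_sq_error(sm$mean, truth_vec, p)
      sq[3, ] <- sq[3, ] + estimation_sq_error(sm$median, truth_vec, p)
    }
    mse <- sq / reps
    res[[length(res) + 1L]] <- data.frame(
      n = n, parameter = pn,
      re1 = mse[2, ] / mse[1, ], re2 = mse[3, ] / mse[1, ],
      mse_mle = mse[1, ], mse_mean = mse[2, ], mse_median = mse[3, ],
      row.names = NULL)
  }
  do.call(rbind, res)
}
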