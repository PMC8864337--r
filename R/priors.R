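# Mean resultant length of the FvML law: A_p(tau) = I_{p/2}(tau) / I_{p/2-1}(tau).
fvml_mean_resultant <- function(tau, p) {
  out <- numeric(length(tau))
  pos <- tau > 1e-10
  out[pos] <- besselI(tau[pos], p / 2, expon.scaled = TRUE) /
    besselI(tau[pos], p / 2 - 1, expon.scaled = TRUE)
  out
}

# Moment estimate of tau: solves A_p(tau) = rbar.
fvml_concentration_from_rbar <- function(rbar, p, tau_max = 1e4) {
  if (rbar <= 1e-6) return(1e-3)
  if (rbar >= fvml_mean_resultant(tau_max, p)) return(tau_max)
  stats::uniroot(function(t) fvml_mean_resultant(t, p) - rbar,
                 c(1e-6, tau_max), tol = 1e-10)$root
}

#' Prior scenario specification
#'
#' Bundles the hyperparameters of one of the four prior scenarios for the
#' skew-FvML parameters `(mu, tau, gamma)`:
#' * scenarios 1-2 place the joint non-conjugate prior
#'   `pi(mu, tau) prop. (tau^(p/2-1)/I_{p/2-1}(tau))^zeta exp(eta tau mu.mu0)`
#'   on location and concentration ("nag" type, `0 < eta < zeta`);
#' * scenarios 3-4 use independent FvML(`mu0`, `tau0`) and
#'   Gamma(`alpha`, rate `beta`) priors ("fvml_gamma" type);
#' * odd scenarios give the skewness `gamma` a componentwise normal prior
#'   `N(xi, sigma^2)`, even scenarios a skew-normal prior with slant
#'   `lambda`;
#' * `scenario = 0` is the non-informative baseline used by the prior-impact
#'   study: `mu` uniform on the sphere, `pi(tau)` flat on `(0, tau_max]`
#'   (default 50), `gamma` normal.
#'
#' Scenarios 1-2 supplied with FvML-Gamma hyperparameters (`tau0`, `alpha`,
#' `beta`) instead of (`zeta`, `eta`) are accepted under the FvML-Gamma
#' reading with a warning, since both conventions occur in applied use. For
#' `p = 3`, `mu_prior_mode = "angles"` switches the location prior to
#' independent von Mises priors on the two spherical coordinates with
#' hyperparameters `mu0` (length 2) and `tau0` (length 2).
#'
#' @param scenario integer 0-4.
#' @param p ambient dimension (2 or 3).
#' @param mu0 prior location, as angles (length `p - 1`).
#' @param zeta,eta hyperparameters of the joint "nag" prior.
#' @param tau0,alpha,beta hyperparameters of the FvML-Gamma prior.
#' @param xi,sigma mean and sd of the gamma prior (length `p - 1`,
#'   recycled).
#' @param lambda slant of the skew-normal gamma prior (scenarios 2 and 4).
#' @param tau_max upper truncation for concentration candidates (defaults
#'   to 1e4, and to 50 for the flat scenario-0 prior).
#' @param mu_prior_mode `"joint"` (single FvML prior on `mu`) or `"angles"`
#'   (independent priors per spherical coordinate, `p = 3` only).
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario, p = 2, mu0 = NULL, zeta = NULL,
                          eta = NULL, tau0 = NULL, alpha = NULL, beta = NULL,
                          xi = 0, sigma = 1, lambda = NULL, tau_max = NULL,
                          mu_prior_mode = c("joint", "angles")) {
  mu_prior_mode <- match.arg(mu_prior_mode)
  stopifnot(scenario %in% 0:4, p %in% c(2L, 3L))
  xi <- rep_len(xi, p - 1)
  sigma <- rep_len(sigma, p - 1)
  stopifnot(all(sigma > 0))
  gamma_prior_type <- if (scenario %in% c(2, 4) ||
                          (scenario == 0 && !is.null(lambda)))
    "skew_normal" else "normal"
  if (gamma_prior_type == "skew_normal") {
    if (is.null(lambda)) stop("scenarios 2 and 4 need lambda")
    lambda <- rep_len(lambda, p - 1)
  } else if (!is.null(lambda)) {
    stop("lambda is only used by the skew-normal gamma prior")
  }

  if (scenario == 0) {
    mu_prior_type <- "flat"
    if (is.null(tau_max)) tau_max <- 50
  } else if (scenario %in% 1:2) {
    if (is.null(zeta) && !is.null(tau0)) {
      warning("scenario ", scenario, " given FvML-Gamma hyperparameters; ",
              "using the FvML-Gamma reading of the location-concentration prior")
      mu_prior_type <- "fvml_gamma"
    } else {
      mu_prior_type <- "nag"
      stopifnot(!is.null(zeta), !is.null(eta))
      if (!(0 < eta && eta < zeta)) stop("the nag prior needs 0 < eta < zeta")
    }
  } else {
    mu_prior_type <- "fvml_gamma"
  }
  if (mu_prior_type == "fvml_gamma") {
    stopifnot(!is.null(tau0), !is.null(alpha), !is.null(beta),
              all(tau0 >= 0), alpha > 0, beta > 0)
  }
  if (mu_prior_mode == "angles") {
    if (p != 3L || mu_prior_type != "fvml_gamma") {
      stop("mu_prior_mode = \"angles\" needs p = 3 and an FvML-Gamma scenario")
    }
    stopifnot(length(mu0) == 2L, length(tau0) == 2L)
    mu_prior_type <- "angles"
  }
  if (mu_prior_type != "flat") {
    stopifnot(length(mu0) == p - 1)
  }
  if (is.null(tau_max)) tau_max <- 1e4
  structure(list(scenario = scenario, p = p,
                 mu_prior_type = mu_prior_type,
                 gamma_prior_type = gamma_prior_type,
                 mu0 = mu0,
                 mu0_cart = if (!is.null(mu0) && mu_prior_type != "angles")
                   to_cartesian(mu0) else NULL,
                 zeta = zeta, eta = eta, tau0 = tau0, alpha = alpha,
                 beta = beta, xi = xi, sigma = sigma, lambda = lambda,
                 tau_max = tau_max),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("scenario_spec %d (p = %d): mu/tau prior \"%s\", gamma prior \"%s\"\n",
              x$scenario, x$p, x$mu_prior_type, x$gamma_prior_type))
  invisible(x)
}

#' Log-likelihood of the skew-FvML model
#'
#' `n log 2 + n log C(tau) + tau * mu . sum(x_i) + sum_i log Phi(arg_i)`
#' with `arg_i = gamma . Ups_mu' x_i` and `Phi` the standard normal CDF
#' (the probit skew used by all Bayesian machinery).
#'
#' @param data a [direction_sample()].
#' @param params an [sfvml_params()] (the `skewing` field is ignored; the
#'   likelihood model is probit-skewed).
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(data, params) {
  stopifnot(inherits(data, "direction_sample"),
            inherits(params, "sfvml_params"))
  Xc <- as_cartesian(data)
  n <- nrow(Xc)
  if (params$p != ncol(Xc)) stop("dimension mismatch between data and params")
  fr <- tangent_frame(params$mu_cart)
  arg <- drop(Xc %*% (fr$upsilon %*% params$gamma))
  n * log(2) + n * log_norm_const(params$tau, params$p) +
    params$tau * sum(Xc %*% params$mu_cart) +
    sum(stats::pnorm(arg, log.p = TRUE))
}

# log prior of the gamma block alone (unnormalized only through dropped
# skew-normal constant 2^(p-1)).
log_gamma_prior <- function(gamma, spec) {
  z <- (gamma - spec$xi) / spec$sigma
  out <- sum(stats::dnorm(z, log = TRUE) - log(spec$sigma))
  if (spec$gamma_prior_type == "skew_normal") {
    out <- out + sum(stats::pnorm(spec$lambda * z, log.p = TRUE))
  }
  out
}

# log prior of the (mu, tau) block alone, unnormalized.
log_mu_tau_prior <- function(mu, tau, spec) {
  if (tau <= 0) return(-Inf)
  p <- spec$p
  nu <- p / 2 - 1
  logI <- function(x) log(besselI(x, nu, expon.scaled = TRUE)) + x
  switch(spec$mu_prior_type,
    nag = {
      mu_c <- to_cartesian(mu)
      spec$zeta * (nu * log(tau) - logI(tau)) +
        spec$eta * tau * sum(mu_c * spec$mu0_cart)
    },
    fvml_gamma = {
      mu_c <- to_cartesian(mu)
      spec$tau0 * sum(mu_c * spec$mu0_cart) +
        (spec$alpha - 1) * log(tau) - spec$beta * tau
    },
    angles = {
      sum(spec$tau0 * cos(mu - spec$mu0)) +
        (spec$alpha - 1) * log(tau) - spec$beta * tau
    },
    flat = if (tau <= spec$tau_max) 0 else -Inf
  )
}

#' Unnormalized log-prior of a parameter state
#'
#' Sum of the location-concentration prior and the skewness prior of the
#' scenario; `tau <= 0` returns `-Inf`.
#'
#' @param params an [sfvml_params()].
#' @param spec a [scenario_spec()].
#' @return scalar unnormalized log prior density.
#' @export
log_prior <- function(params, spec) {
  stopifnot(inherits(params, "sfvml_params"), inherits(spec, "scenario_spec"),
            params$p == spec$p)
  if (params$tau <= 0) return(-Inf)
  log_mu_tau_prior(params$mu, params$tau, spec) +
    log_gamma_prior(params$gamma, spec)
}

#' Unnormalized log-posterior
#'
#' `log_likelihood + log_prior`; proportional to the scenario posterior
#' kernels of the four prior scenarios.
#'
#' @inheritParams log_likelihood
#' @param spec a [scenario_spec()].
#' @return scalar unnormalized log posterior density.
#' @export
log_posterior <- function(data, params, spec) {
  lp <- log_prior(params, spec)
  if (!is.finite(lp)) return(lp)
  lp + log_likelihood(data, params)
}

# --- prior samplers ----------------------------------------------------------

# Marginal log-density of tau under the joint "nag" prior, obtained by
# integrating mu analytically: pi(tau) prop.
# (tau^{p/2-1}/I_{p/2-1}(tau))^zeta / C_p(eta * tau).
nag_tau_logmarg <- function(tau, spec) {
  nu <- spec$p / 2 - 1
  logI <- function(x) log(besselI(x, nu, expon.scaled = TRUE)) + x
  et <- spec$eta * tau
  out <- spec$zeta * (nu * log(tau) - logI(tau)) - nu * log(et) + logI(et)
  out[tau <= 0 | tau > spec$tau_max] <- -Inf
  out
}

# Pool of m independent slice chains targeting the tau marginal of the nag
# prior. Chains are warm-started once; each advance() of a few sweeps then
# yields m mutually independent draws (the chains never interact).
nag_tau_pool <- function(spec, m, warm_sweeps = 64) {
  env <- new.env(parent = emptyenv())
  env$tau <- stats::rexp(m) + 0.02
  env$tau_max <- spec$tau_max
  env$logf <- function(x) nag_tau_logmarg(x, spec)
  for (i in seq_len(warm_sweeps)) {
    env$tau <- slice_sweep_vec(env$tau, env$logf, width = 1,
                               lower = 1e-8, upper = env$tau_max)
  }
  env
}

nag_tau_pool_advance <- function(pool, sweeps = 4) {
  for (i in seq_len(sweeps)) {
    pool$tau <- slice_sweep_vec(pool$tau, pool$logf, width = 1,
                                lower = 1e-8, upper = pool$tau_max)
  }
  pool$tau
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# k draws of mu given tau under the nag prior: FvML(mu0, eta * tau), exact.
nag_mu_given_tau <- function(tau, spec) {
  k <- length(tau)
  kap <- spec$eta * tau
  if (spec$p == 2L) {
    matrix(rvonmises_angle(k, spec$mu0, kap), ncol = 1L)
  } else {
    tt <- rfvml_t_s2(k, kap)
    psi <- stats::runif(k, 0, 2 * pi)
    fr <- tangent_frame(spec$mu0_cart)
    s <- sqrt(pmax(0, 1 - tt^2))
    X <- tt %o% spec$mu0_cart +
      (s * cos(psi)) %o% fr$upsilon[, 1L] +
      (s * sin(psi)) %o% fr$upsilon[, 2L]
    to_angles(X)
  }
}

# k draws from the gamma prior of the scenario, as a k x (p-1) matrix.
sample_gamma_prior <- function(spec, k) {
  d <- spec$p - 1L
  if (spec$gamma_prior_type == "normal") {
    z <- matrix(stats::rnorm(k * d), k, d)
  } else {
    delta <- spec$lambda / sqrt(1 + spec$lambda^2)
    z0 <- abs(matrix(stats::rnorm(k * d), k, d))
    z1 <- matrix(stats::rnorm(k * d), k, d)
    z <- sweep(z0, 2, delta, "*") +
      sweep(z1, 2, sqrt(1 - delta^2), "*")
  }
  sweep(sweep(z, 2, spec$sigma, "*"), 2, spec$xi, "+")
}

# k draws of (mu, tau) from the scenario prior (used for standalone prior
# sampling; the Gibbs engine keeps its own persistent nag pool).
sample_mu_tau_prior <- function(spec, k) {
  p <- spec$p
  switch(spec$mu_prior_type,
    nag = {
      pool <- nag_tau_pool(spec, k)
      tau <- pool$tau
      list(mu = nag_mu_given_tau(tau, spec), tau = tau)
    },
    fvml_gamma = {
      tau <- stats::rgamma(k, shape = spec$alpha, rate = spec$beta)
      mu <- if (p == 2L) {
        matrix(rvonmises_angle(k, spec$mu0, spec$tau0), ncol = 1L)
      } else {
        tt <- rfvml_t_s2(k, rep(spec$tau0, k))
        psi <- stats::runif(k, 0, 2 * pi)
        fr <- tangent_frame(spec$mu0_cart)
        s <- sqrt(pmax(0, 1 - tt^2))
        to_angles(tt %o% spec$mu0_cart +
                    (s * cos(psi)) %o% fr$upsilon[, 1L] +
                    (s * sin(psi)) %o% fr$upsilon[, 2L])
      }
      list(mu = mu, tau = tau)
    },
    angles = {
      tau <- stats::rgamma(k, shape = spec$alpha, rate = spec$beta)
      mu <- cbind(rvonmises_angle(k, spec$mu0[1L], spec$tau0[1L]),
                  rvonmises_angle(k, spec$mu0[2L], spec$tau0[2L]))
      list(mu = mu, tau = tau)
    },
    flat = {
      tau <- stats::runif(k, 0, spec$tau_max)
      mu <- matrix(stats::runif(k * (p - 1L), -pi, pi), k, p - 1L)
      list(mu = mu, tau = tau)
    }
  )
}

#' Sample parameter states from a scenario prior
#'
#' Independent draws of `(mu, tau, gamma)` from the prior of the scenario.
#' FvML-Gamma priors are sampled exactly; the joint "nag" prior is sampled
#' by drawing `tau` from its analytic 1-d marginal with `k` independent
#' slice-sampling chains and `mu | tau` exactly from FvML(`mu0`,
#' `eta * tau`).
#'
#' @param spec a [scenario_spec()].
#' @param k number of draws.
#' @param seed optional integer seed.
#' @return list with `mu` (`k x (p-1)` angles), `tau` (length `k`),
#'   `gamma` (`k x (p-1)`).
#' @export
sample_prior <- function(spec, k, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), k >= 1)
  with_seed(seed, {
    mt <- sample_mu_tau_prior(spec, k)
    list(mu = mt$mu, tau = mt$tau, gamma = sample_gamma_prior(spec, k))
  })
}

# sum_i log Phi(gamma . Ups_mu' x_i) for a single (mu, gamma).
phi_product_term <- function(Xc, mu_cart, gamma) {
  fr <- tangent_frame(mu_cart)
  sum(stats::pnorm(drop(Xc %*% (fr$upsilon %*% gamma)), log.p = TRUE))
}

#' Scenario full conditionals
#'
#' Unnormalized log full-conditional density of one parameter block given
#' the others and the data, exactly as listed for the four scenarios:
#' the `mu` block couples the linear term `tau * mu.(sum x_i + prior pull)`
#' with the probit product; the `tau` block is the concentration kernel
#' plus the linear term (no probit product); the `gamma` block is its prior
#' times the probit product. Each equals `log_likelihood + log_prior` up to
#' an additive constant in the block variable.
#'
#' @param block `"mu"`, `"tau"` or `"gamma"`.
#' @param value the block value (`mu`: angles of length `p - 1`; `tau`:
#'   positive scalar; `gamma`: length `p - 1`).
#' @param state list with the current `mu` (angles), `tau`, `gamma`.
#' @param data a [direction_sample()].
#' @param spec a [scenario_spec()].
#' @return scalar unnormalized log conditional density.
#' @export
log_full_conditional <- function(block, value, state, data, spec) {
  block <- match.arg(block, c("mu", "tau", "gamma"))
  stopifnot(inherits(data, "direction_sample"), inherits(spec, "scenario_spec"))
  Xc <- as_cartesian(data)
  n <- nrow(Xc)
  Sx <- colSums(Xc)
  nu <- spec$p / 2 - 1
  logI <- function(x) log(besselI(x, nu, expon.scaled = TRUE)) + x
  if (block == "mu") {
    mu_c <- to_cartesian(value)
    lin <- state$tau * sum(mu_c * Sx)
    pull <- switch(spec$mu_prior_type,
      nag = spec$eta * state$tau * sum(mu_c * spec$mu0_cart),
      fvml_gamma = spec$tau0 * sum(mu_c * spec$mu0_cart),
      angles = sum(spec$tau0 * cos(value - spec$mu0)),
      flat = 0)
    lin + pull + phi_product_term(Xc, mu_c, state$gamma)
  } else if (block == "tau") {
    tau <- value
    if (tau <= 0) return(-Inf)
    mu_c <- to_cartesian(state$mu)
    lin <- tau * sum(mu_c * Sx)
    switch(spec$mu_prior_type,
      nag = (spec$zeta + n) * (nu * log(tau) - logI(tau)) + lin +
        spec$eta * tau * sum(mu_c * spec$mu0_cart),
      fvml_gamma = ,
      angles = (n * spec$p / 2 + spec$alpha - n - 1) * log(tau) -
        n * logI(tau) + lin - spec$beta * tau,
      flat = if (tau > spec$tau_max) -Inf else
        n * (nu * log(tau) - logI(tau)) + lin)
  } else {
    mu_c <- to_cartesian(state$mu)
    log_gamma_prior(value, spec) + phi_product_term(Xc, mu_c, value)
  }
}
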