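test_that("scenario specifications enforce their invariants", {
  expect_s3_class(ref_spec2(), "scenario_spec")
  expect_error(scenario_spec(1, mu0 = 1, zeta = 1, eta = 2, xi = 0, sigma = 1),
               "0 < eta < zeta")
  expect_error(scenario_spec(2, mu0 = 1, zeta = 10, eta = 0.5), "lambda")
  expect_error(scenario_spec(3, mu0 = 1, tau0 = 9, alpha = 0.5, beta = 5,
                             lambda = -1), "skew-normal")
  # the tabulated convention: scenario 1 with FvML-Gamma hyperparameters is
  # accepted under that reading, with a warning
  expect_warning(s1 <- scenario_spec(1, mu0 = 1, tau0 = 9, alpha = 0.5,
                                     beta = 5, xi = -4, sigma = 1),
                 "FvML-Gamma")
  expect_identical(s1$mu_prior_type, "fvml_gamma")
  expect_identical(ref_spec2()$mu_prior_type, "nag")
  expect_identical(ref_spec4()$gamma_prior_type, "skew_normal")
})

test_that("log priors match their closed forms in special cases", {
  # gamma shape 1: the tau part is linear, tau0 mu.mu0 - beta tau
  sp <- scenario_spec(3, mu0 = 0.3, tau0 = 2, alpha = 1, beta = 5,
                      xi = 0, sigma = 1)
  f <- function(tau) log_prior(sfvml_params(1, tau, 0), sp)
  expect_equal(f(2) - f(1), -5, tolerance = 1e-12)
  # skew-normal with lambda = 0 is the normal prior shifted by log(1/2)
  spn <- scenario_spec(3, mu0 = 0.3, tau0 = 2, alpha = 1, beta = 5,
                       xi = 0.5, sigma = 2)
  spz <- scenario_spec(4, mu0 = 0.3, tau0 = 2, alpha = 1, beta = 5,
                       xi = 0.5, sigma = 2, lambda = 0)
  pg <- sfvml_params(1, 1, 0.7)
  expect_equal(log_prior(pg, spz), log_prior(pg, spn) + log(1 / 2))
  # the joint location-concentration prior is maximized at mu = mu0
  sp2 <- ref_spec2()
  lp <- vapply(seq(-pi, pi, length.out = 41), function(m) {
    log_prior(sfvml_params(m, 0.7, 0), sp2)
  }, 0)
  expect_equal(which.max(lp), which.min(abs(seq(-pi, pi, length.out = 41) - 1)))
  expect_identical(log_prior(sfvml_params(1, 0, 0), sp2), -Inf)
})

test_that("prior draws reproduce known moments and shapes", {
  k <- 50000
  pr3 <- sample_prior(ref_spec3(), k, seed = 41)
  expect_lt(abs(mean(pr3$tau) - 0.5 / 5), 3 * sqrt(0.5 / 25) / sqrt(k))
  # skew-normal draws carry the sign of lambda
  pr2 <- sample_prior(ref_spec2(), k, seed = 43)
  g <- pr2$gamma
  expect_lt(mean((g - mean(g))^3) / sd(g)^3, -0.05)
  # nag tau marginal against its quadrature CDF
  f <- function(t) exp(10 * (-log(besselI(t, 0, TRUE)) - t) +
                         log(besselI(0.5 * t, 0, TRUE)) + 0.5 * t)
  Z <- integrate(f, 0, 50)$value
  for (q in c(0.1, 0.3, 0.8)) {
    expect_lt(abs(mean(pr2$tau < q) - integrate(f, 0, q)$value / Z), 0.015)
  }
  # mu concentrates at mu0 as eta grows (circular variance decreasing)
  cvar <- vapply(c(0.5, 3, 9), function(eta) {
    sp <- scenario_spec(1, mu0 = 1, zeta = 10, eta = eta, xi = 0, sigma = 1)
    pr <- sample_prior(sp, 5000, seed = 47)
    1 - sqrt(mean(cos(pr$mu))^2 + mean(sin(pr$mu))^2)
  }, 0)
  expect_true(all(diff(cvar) < 0))
})

test_that("the likelihood agrees with per-point density sums", {
  pp <- sfvml_params(3, 0.6, 1)
  d <- sample_sfvml(50, pp, seed = 53)
  expect_equal(log_likelihood(d, pp),
               sum(sfvml_logpdf(as_cartesian(d), pp)), tolerance = 1e-10)
  p0 <- sfvml_params(3, 0.6, 0)
  expect_equal(log_likelihood(d, p0),
               sum(fvml_logpdf(as_cartesian(d), p0$mu_cart, 0.6)),
               tolerance = 1e-10)
  # single observation at the location: the tangent argument is exactly 0
  d1 <- direction_sample(3)
  expect_equal(log_likelihood(d1, pp),
               log(2) + log_norm_const(0.6, 2) + 0.6 + pnorm(0, log.p = TRUE))
})

scenario_grid_specs <- function() {
  list(`2` = ref_spec2(), `4` = ref_spec4(), `3` = ref_spec3(),
       `1` = scenario_spec(1, mu0 = 0.8, zeta = 4, eta = 1.5,
                           xi = 0.2, sigma = 1.5))
}

test_that("each full conditional is proportional to the joint posterior", {
  pp <- sfvml_params(3, 0.6, 1)
  d <- sample_sfvml(40, pp, seed = 59)
  state <- list(mu = 2.8, tau = 0.7, gamma = 0.9)
  for (sp in scenario_grid_specs()) {
    for (block in c("mu", "tau", "gamma")) {
      grid <- switch(block,
                     mu = seq(-pi + 0.1, pi, length.out = 50),
                     tau = seq(0.05, 4, length.out = 50),
                     gamma = seq(-3, 3, length.out = 50))
      diffs <- vapply(grid, function(v) {
        st <- state
        st[[block]] <- v
        log_full_conditional(block, v, state, d, sp) -
          log_posterior(d, sfvml_params(st$mu, st$tau, st$gamma), sp)
      }, 0)
      expect_lt(sd(diffs), 1e-9)
    }
  }
})

test_that("the concentration conditional peaks where its gradient vanishes", {
  pp <- sfvml_params(3, 0.6, 1)
  d <- sample_sfvml(200, pp, seed = 61)
  sp <- ref_spec3()
  state <- list(mu = 3, tau = 1, gamma = 1)
  f <- function(t) log_full_conditional("tau", t, state, d, sp)
  opt <- optimize(f, c(0.01, 5), maximum = TRUE)$maximum
  eps <- 1e-5
  expect_lt(abs((f(opt + eps) - f(opt - eps)) / (2 * eps)), 0.01)
})

test_that("scenario pairs differ only through the skewness prior", {
  pp <- sfvml_params(3, 0.6, 1)
  d <- sample_sfvml(30, pp, seed = 67)
  sp3 <- ref_spec3()
  sp4 <- scenario_spec(4, mu0 = 1, tau0 = 9, alpha = 0.5, beta = 5,
                       xi = -4, sigma = 1, lambda = 2)
  # difference of log posteriors is a function of gamma alone
  for (g in c(-1, 0.5)) {
    delta <- vapply(seq(0.2, 2, length.out = 10), function(tau) {
      log_posterior(d, sfvml_params(2, tau, g), sp4) -
        log_posterior(d, sfvml_params(2, tau, g), sp3)
    }, 0)
    expect_lt(diff(range(delta)), 1e-10)
  }
})
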