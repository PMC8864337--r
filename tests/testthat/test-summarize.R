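test_that("summaries obey the loss-estimator conventions", {
  st <- matrix(rep(c(1.1, 0.5, -0.2), each = 20), 20, 3,
               dimnames = list(NULL, c("mu", "tau", "gamma")))
  s <- summarize_chain(fake_chain(st))
  expect_equal(s$mean, c(1.1, 0.5, -0.2))
  expect_equal(s$median, c(1.1, 0.5, -0.2))
  expect_equal(s$mode, c(1.1, 0.5, -0.2))
  expect_equal(s$sd, c(0, 0, 0))
  # type-7 quantiles on a known sample
  st2 <- cbind(mu = rep(0, 12), tau = rep(1, 12), gamma = c(1:4, 1:4, 1:4))
  s2 <- summarize_chain(fake_chain(st2))
  expect_equal(s2$mean[3], 2.5)
  expect_equal(s2$median[3], 2.5)
  expect_equal(s2$q1[3], unname(quantile(c(1, 2, 3, 4), 0.25)))
  expect_true(all(s2$q1 <= s2$median & s2$median <= s2$q3))
})

test_that("location summaries recentre across the wrap point", {
  set.seed(101)
  ang <- wrap_pi(pi + rnorm(500, 0, 0.1))   # straddles +/- pi
  st <- cbind(mu = ang, tau = rep(1, 500), gamma = rep(0, 500))
  s <- summarize_chain(fake_chain(st))
  expect_lt(abs(abs(s$mean[1]) - pi), 0.02)
  expect_lt(s$sd[1], 0.12)                  # no wrap inflation
  rm <- running_mean(fake_chain(st), "mu")
  expect_equal(rm[length(rm)], s$mean[1], tolerance = 1e-14)
})

test_that("the KDE mode estimator finds the density peak", {
  # the argmax of a Silverman-bandwidth KDE over a flat-topped normal peak
  # has a sampling sd near 0.06 even at n = 1e5, so single draws are
  # checked loosely and unbiasedness is checked on the average
  set.seed(103)
  modes <- vapply(1:10, function(i) {
    x <- rnorm(100000)
    st <- cbind(mu = rep(0, 2), tau = rep(1, 2))
    skewsphere:::kde_mode(x)
  }, 0)
  expect_true(all(abs(modes) < 0.2))
  expect_lt(abs(mean(modes)), 0.05)
})

test_that("running means are cumulative and consistent", {
  st <- cbind(mu = rep(0, 3), tau = rep(1, 3), gamma = c(1, 2, 3))
  expect_equal(running_mean(fake_chain(st), "gamma"), c(1, 1.5, 2))
  expect_equal(running_mean(fake_chain(st), "tau"), c(1, 1, 1))
})

test_that("whole-versus-tail densities detect drift and nothing else", {
  set.seed(107)
  iid <- cbind(mu = rep(0, 2000), tau = rep(1, 2000), gamma = rnorm(2000))
  cp <- compare_partial(fake_chain(iid), "gamma")
  expect_lt(cp$l1, 0.35)
  expect_equal(compare_partial(fake_chain(iid), "gamma", 1)$l1, 0)
  drift <- iid
  drift[, "gamma"] <- drift[, "gamma"] + seq(0, 6, length.out = 2000)
  cpd <- compare_partial(fake_chain(drift), "gamma")
  expect_gt(cpd$l1, 3 * cp$l1)
})

test_that("the symmetry statistic vanishes for reflected samples and is rotation invariant", {
  set.seed(109)
  th <- runif(30, -1, 1.5)
  refl <- c(th, 2 * circular_mean(th) - th)
  expect_lt(abs(pewsey_symmetry_test(refl)$b2bar), 1e-12)
  base <- pewsey_symmetry_test(th)
  rot <- pewsey_symmetry_test(th + 1.234)
  expect_equal(base$z, rot$z, tolerance = 1e-10)
  expect_equal(base$p_value, rot$p_value, tolerance = 1e-10)
  expect_error(pewsey_symmetry_test(c(0, pi/2, pi, -pi/2, 0, pi/2, pi, -pi/2,
                                      0, pi/2, pi, -pi/2)), "resultant")
})

test_that("power against skew alternatives matches asymptotic theory", {
  # population second sine moment and asymptotic variances by quadrature
  # give the theoretical power of the two-sided level-0.05 test; the
  # simulated rejection rate must agree within Monte-Carlo error and the
  # test must have substantial power at n = 60 (strong power, > 0.9, needs
  # n of about 100 at this concentration)
  f <- function(t) exp(svm_logpdf(t, 0, 0.6, 5))
  mdir <- atan2(integrate(function(t) sin(t) * f(t), -pi, pi)$value,
                integrate(function(t) cos(t) * f(t), -pi, pi)$value)
  mom <- function(g) integrate(function(t) g(t - mdir) * f(t), -pi, pi,
                               subdivisions = 500)$value
  b2 <- mom(function(d) sin(2 * d)); b1 <- mom(function(d) sin(d))
  a1 <- mom(function(d) cos(d)); a2 <- mom(function(d) cos(2 * d))
  a3 <- mom(function(d) cos(3 * d)); a4 <- mom(function(d) cos(4 * d))
  c21 <- 2 * a2 / a1
  v_alt <- (mom(function(d) sin(2 * d)^2) - b2^2) +
    c21^2 * (mom(function(d) sin(d)^2) - b1^2) -
    2 * c21 * (mom(function(d) sin(2 * d) * sin(d)) - b2 * b1)
  v_plug <- (1 - a4) / 2 + 2 * a2^2 * (1 - a2) / a1^2 -
    2 * a2 * (a1 - a3) / a1
  n <- 60
  crit <- qnorm(0.975)
  pow_theory <- pnorm((-crit * sqrt(v_plug) - sqrt(n) * b2) / sqrt(v_alt)) +
    pnorm((crit * sqrt(v_plug) - sqrt(n) * b2) / sqrt(v_alt),
          lower.tail = FALSE)
  rej <- vapply(1:400, function(r) {
    th <- as.numeric(unclass(sample_sfvml(n, sfvml_params(3, 0.6, 5),
                                          seed = derive_seed(r, "power"))))
    pewsey_symmetry_test(th)$p_value < 0.05
  }, NA)
  expect_lt(abs(mean(rej) - pow_theory), 0.07)
  expect_gt(mean(rej), 0.5)
})

test_that("maximum likelihood reduces to the closed-form von Mises fit", {
  d <- sample_sfvml(300, sfvml_params(3, 0.6, 1), seed = 113)
  ml0 <- mle_fit(d, fix_gamma = 0)
  m <- colMeans(as_cartesian(d))
  rbar <- sqrt(sum(m^2))
  expect_lt(abs(wrap_pi(ml0$params$mu - atan2(m[2], m[1]))), 1e-4)
  tau_hat <- uniroot(function(t) besselI(t, 1, TRUE) / besselI(t, 0, TRUE) - rbar,
                     c(1e-6, 100), tol = 1e-12)$root
  expect_lt(abs(ml0$params$tau - tau_hat), 1e-4)
})

test_that("maximum likelihood is consistent and dominates the truth", {
  pp <- sfvml_params(3, 0.6, 1)
  d <- sample_sfvml(2000, pp, seed = 127)
  ml <- mle_fit(d)
  expect_gte(ml$loglik, log_likelihood(d, pp))
  est <- c(ml$params$mu, ml$params$tau, ml$params$gamma)
  err <- est - c(3, 0.6, 1)
  err[1] <- wrap_pi(err[1])
  ok <- is.finite(ml$se)
  expect_true(all(abs(err[ok]) < 3 * ml$se[ok] + 0.05))
})

test_that("relative efficiency output is internally consistent", {
  re <- relative_efficiency(sfvml_params(3, 0.6, 1), ref_spec3(),
                            n_list = 15, reps = 4, B = 60, N = 60, k = 40,
                            seed = 131)
  expect_equal(re$re1, re$mse_mean / re$mse_mle, tolerance = 1e-12)
  expect_equal(re$re2, re$mse_median / re$mse_mle, tolerance = 1e-12)
  expect_true(all(re$mse_mle >= 0))
  expect_identical(re$parameter, c("mu", "tau", "gamma"))
})
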