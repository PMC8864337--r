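test_that("chains are deterministic in (seed, data, spec, B, N, k)", {
  pp <- sfvml_params(3, 0.6, 1)
  d <- sample_sfvml(60, pp, seed = 71)
  sp <- ref_spec3()
  a <- run_chain(d, sp, B = 30, N = 20, k = 50, seed = 5)
  b <- run_chain(d, sp, B = 30, N = 20, k = 50, seed = 5)
  expect_identical(a$states, b$states)
  s1 <- gibbs_step(list(mu = 3, tau = 0.6, gamma = 1), d, sp, 50, seed = 9)
  s2 <- gibbs_step(list(mu = 3, tau = 0.6, gamma = 1), d, sp, 50, seed = 9)
  expect_identical(s1[c("mu", "tau", "gamma")], s2[c("mu", "tau", "gamma")])
})

test_that("tied weights break to the lowest index and empty pools error", {
  sp <- ref_spec3()
  expect_identical(skewsphere:::select_candidate(rep(2.5, 7), "argmax",
                                                 "gamma", sp), 1L)
  expect_error(skewsphere:::select_candidate(rep(-Inf, 5), "argmax",
                                             "gamma", sp), "zero weight")
  # observations at the location make every gamma weight equal up to
  # rounding; the selected candidate must come from the replayed prior pool
  d <- direction_sample(rep(0.5, 5))
  ch <- run_chain(d, sp, B = 0, N = 1, k = 40,
                  fixed = list(mu = 0.5, tau = 0.5), seed = 11)
  set.seed(11)
  G <- skewsphere:::sample_gamma_prior(sp, 40)
  expect_true(any(abs(G - ch$states[1L, "gamma"]) < 1e-15))
})

test_that("the selection weight cancels the prior analytically", {
  # for the independent-prior scenarios the mu-block weight must equal
  # (full conditional - log prior) up to a constant across candidates
  pp <- sfvml_params(3, 0.6, 1)
  d <- sample_sfvml(25, pp, seed = 73)
  sp <- ref_spec3()
  state <- list(mu = 2.9, tau = 0.8, gamma = 1.1)
  Xc <- as_cartesian(d)
  Sx <- colSums(Xc)
  grid <- seq(-pi + 0.1, pi, length.out = 40)
  direct <- vapply(grid, function(m) {
    state$tau * sum(to_cartesian(m) * Sx) +
      sum(pnorm(drop(Xc %*% (tangent_frame(to_cartesian(m))$upsilon %*%
                               state$gamma)), log.p = TRUE))
  }, 0)
  via_cond <- vapply(grid, function(m) {
    log_full_conditional("mu", m, state, d, sp) -
      sp$tau0 * sum(to_cartesian(m) * sp$mu0_cart)
  }, 0)
  expect_lt(max(abs(direct - via_cond)), 1e-8)
})

test_that("posterior chains recover generating parameters", {
  pp <- sfvml_params(2, 1, -1)
  d <- sample_sfvml(200, pp, seed = 79)
  ch <- run_chain(d, ref_spec3(), B = 400, N = 300, k = 200, seed = 83,
                  init = "mle")
  s <- summarize_chain(ch)
  truth <- c(2, 1, -1)
  expect_true(all(abs(s$mean - truth) < pmax(3 * s$sd, 0.35)))
  expect_true(all(s$q1 <= s$median & s$median <= s$q3))
})

test_that("larger candidate pools reduce estimation bias", {
  pp <- sfvml_params(3, 0.6, 1)
  reps <- 12
  bias <- sapply(c(5, 150), function(k) {
    est <- sapply(seq_len(reps), function(r) {
      d <- sample_sfvml(60, pp, seed = derive_seed(r, "kbias-data"))
      ch <- run_chain(d, ref_spec3(), B = 150, N = 150, k = k,
                      seed = derive_seed(r, paste0("kbias-", k)),
                      init = "mle")
      colMeans(kept_states(ch))
    })
    rowMeans(est - c(3, 0.6, 1))
  })
  # average absolute bias over the parameters shrinks as k grows
  expect_lt(mean(abs(bias[, 2])), mean(abs(bias[, 1])))
})

test_that("independent chains mix and the diagnostic is order-invariant", {
  pp <- sfvml_params(2, 1, -1)
  d <- sample_sfvml(200, pp, seed = 89)
  ps <- run_parallel_chains(d, ref_spec3(), n_chains = 4, B = 200,
                            N = 200, k = 150, seed = 91, init = "mle")
  expect_true(all(ps$rhat < 1.1))
  draws <- lapply(ps$chains, kept_states)
  expect_equal(split_rhat(draws), split_rhat(rev(draws)))
  # identical seeds give identical chains
  c1 <- run_chain(d, ref_spec3(), B = 20, N = 10, k = 40, seed = 93)
  c2 <- run_chain(d, ref_spec3(), B = 20, N = 10, k = 40, seed = 93)
  expect_identical(c1$states, c2$states)
})

test_that("the joint location-concentration block drives scenario-2 chains", {
  pp <- sfvml_params(3, 0.6, 1)
  d <- sample_sfvml(120, pp, seed = 95)
  ch <- run_chain(d, ref_spec2(), B = 300, N = 200, k = 200, seed = 97,
                  init = "mle")
  s <- summarize_chain(ch)
  expect_lt(abs(wrap_pi(s$mean[1] - 3)), 0.6)
  expect_lt(abs(s$mean[3] - 1), 0.8)
  # selected weights are recorded for every step
  expect_false(anyNA(ch$logrho))
  expect_equal(ch$logrho[, "mu"], ch$logrho[, "tau"])
})
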