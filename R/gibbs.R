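# --- candidate scoring -------------------------------------------------------
# The selection weight of Algorithm-style sampling-resampling is
# rho_i = full conditional(candidate_i | rest) / prior(candidate_i);
# the prior factor cancels analytically in every block below, so only the
# likelihood part of the conditional is evaluated. All work is in log space;
# the probit products are computed by a compiled kernel.

# Ups(mu) %*% gamma for k candidate locations at once, as a p x k matrix of
# weight vectors; the probit argument of observation x is then x . w.
gamma_weights <- function(mu_cands, gamma, p) {
  if (p == 2L) {
    m <- mu_cands[, 1L]
    rbind(-gamma * sin(m), gamma * cos(m))
  } else {
    Mc <- to_cartesian(mu_cands)
    g1 <- gamma[1L]; g2 <- gamma[2L]
    denom <- 1 - Mc[, 1L]
    cc <- ifelse(denom < 1e-14, 0, (Mc[, 2L] * g1 + Mc[, 3L] * g2) / denom)
    rbind(cc * denom,
          g1 - cc * Mc[, 2L],
          g2 - cc * Mc[, 3L])
  }
}

draw_mu_cands <- function(spec, k) {
  switch(spec$mu_prior_type,
    fvml_gamma = {
      if (spec$p == 2L) {
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
    },
    angles = cbind(rvonmises_angle(k, spec$mu0[1L], spec$tau0[1L]),
                   rvonmises_angle(k, spec$mu0[2L], spec$tau0[2L])),
    flat = matrix(stats::runif(k * (spec$p - 1L), -pi, pi), k, spec$p - 1L),
    stop("no independent mu prior for this scenario"))
}

draw_tau_cands <- function(spec, k) {
  switch(spec$mu_prior_type,
    fvml_gamma = ,
    angles = stats::rgamma(k, shape = spec$alpha, rate = spec$beta),
    flat = stats::runif(k, 0, spec$tau_max),
    stop("no independent tau prior for this scenario"))
}

select_candidate <- function(logrho, select, block, spec) {
  if (!any(is.finite(logrho))) {
    stop(sprintf("all %d candidates of the %s block have zero weight (scenario %d)",
                 length(logrho), block, spec$scenario))
  }
  if (select == "argmax") {
    which.max(logrho)          # ties broken by lowest index
  } else {
    w <- exp(logrho - max(logrho))
    sample.int(length(logrho), 1L, prob = w)
  }
}

make_gibbs_env <- function(data, spec, k, fixed = NULL,
                           select = "argmax", pool_sweeps = 4) {
  env <- new.env(parent = emptyenv())
  env$Xc <- as_cartesian(data)
  env$n <- nrow(env$Xc)
  env$Sx <- colSums(env$Xc)
  env$spec <- spec
  env$k <- k
  env$p <- spec$p
  env$nu <- spec$p / 2 - 1
  env$fixed <- names(fixed %||% list())
  env$select <- select
  env$pool_sweeps <- pool_sweeps
  env$pool <- NULL
  if (spec$mu_prior_type == "nag" &&
      !all(c("mu", "tau") %in% env$fixed)) {
    env$pool <- nag_tau_pool(spec, k)
  }
  env
}

log_bessel_i <- function(x, nu) log(besselI(x, nu, expon.scaled = TRUE)) + x

# One sweep of the sampling-resampling update over the (mu, tau, gamma)
# blocks, using already-updated values downstream. For the joint "nag"
# prior the mu and tau steps are combined into one candidate block (the
# prior is not independent); the selection weight then reduces to the
# likelihood kernel.
gibbs_step_impl <- function(state, env) {
  spec <- env$spec
  k <- env$k
  n <- env$n
  logrho_sel <- c(mu = NA_real_, tau = NA_real_, gamma = NA_real_)

  if (spec$mu_prior_type == "nag" && !any(c("mu", "tau") %in% env$fixed)) {
    tau_c <- nag_tau_pool_advance(env$pool, env$pool_sweeps)
    mu_c <- nag_mu_given_tau(tau_c, spec)
    Mc <- to_cartesian(mu_c)
    W <- gamma_weights(mu_c, state$gamma, env$p)
    logrho <- n * (env$nu * log(tau_c) - log_bessel_i(tau_c, env$nu)) +
      tau_c * drop(Mc %*% env$Sx) +
      .colsum_logphi_crossprod(env$Xc, W)
    i <- select_candidate(logrho, env$select, "mu-tau", spec)
    state$mu <- mu_c[i, ]
    state$mu_cart <- Mc[i, ]
    state$tau <- tau_c[i]
    logrho_sel["mu"] <- logrho_sel["tau"] <- logrho[i]
  } else {
    if (!("mu" %in% env$fixed)) {
      mu_c <- draw_mu_cands(spec, k)
      Mc <- to_cartesian(mu_c)
      W <- gamma_weights(mu_c, state$gamma, env$p)
      logrho <- state$tau * drop(Mc %*% env$Sx) +
        .colsum_logphi_crossprod(env$Xc, W)
      i <- select_candidate(logrho, env$select, "mu", spec)
      state$mu <- mu_c[i, ]
      state$mu_cart <- Mc[i, ]
      logrho_sel["mu"] <- logrho[i]
    }
    if (!("tau" %in% env$fixed)) {
      tau_c <- draw_tau_cands(spec, k)
      logrho <- n * (env$nu * log(tau_c) - log_bessel_i(tau_c, env$nu)) +
        tau_c * sum(state$mu_cart * env$Sx)
      i <- select_candidate(logrho, env$select, "tau", spec)
      state$tau <- tau_c[i]
      logrho_sel["tau"] <- logrho[i]
    }
  }
  if (!("gamma" %in% env$fixed)) {
    G <- sample_gamma_prior(spec, k)
    V <- env$Xc %*% tangent_frame(state$mu_cart)$upsilon
    logrho <- .colsum_logphi_crossprod(V, t(G))
    i <- select_candidate(logrho, env$select, "gamma", spec)
    state$gamma <- G[i, ]
    logrho_sel["gamma"] <- logrho[i]
  }
  state$logrho <- logrho_sel
  state
}

#' One sampling-resampling Gibbs update
#'
#' For each block in order (`mu`, `tau`, `gamma`; jointly `(mu, tau)` for
#' the non-independent "nag" prior of scenarios 1-2), draws `k` fresh
#' candidates from the block's prior, weighs each by the ratio of its full
#' conditional to its prior (computed in log space with the prior factor
#' cancelled analytically), and selects the candidate with maximal weight,
#' ties broken by lowest index. Blocks update sequentially using
#' already-updated values.
#'
#' @param state list with current `mu` (angles), `tau`, `gamma`.
#' @param data a [direction_sample()].
#' @param spec a [scenario_spec()].
#' @param k candidate pool size.
#' @param seed optional integer seed.
#' @param select `"argmax"` (the algorithm's rule) or `"multinomial"`
#'   (standard sampling-importance-resampling, for comparison).
#' @return the updated state; element `logrho` carries the selected
#'   log-weight per block.
#' @export
gibbs_step <- function(state, data, spec, k, seed = NULL,
                       select = c("argmax", "multinomial")) {
  select <- match.arg(select)
  with_seed(seed, {
    env <- make_gibbs_env(data, spec, k, select = select)
    state$mu_cart <- to_cartesian(state$mu)
    gibbs_step_impl(state, env)
  })
}

auto_init <- function(data, spec) {
  Xc <- as_cartesian(data)
  m <- colMeans(Xc)
  rbar <- sqrt(sum(m^2))
  mu <- drop(to_angles(m / max(rbar, 1e-12)))
  tau <- fvml_concentration_from_rbar(rbar, ncol(Xc))
  list(mu = mu, tau = max(tau, 1e-3), gamma = rep(0, ncol(Xc) - 1L))
}

mle_init <- function(data) {
  ml <- mle_fit(data)
  list(mu = if (unit_p(data) == 2L) wrap_pi(ml$params$mu) else ml$params$mu,
       tau = max(ml$params$tau, 1e-3), gamma = ml$params$gamma)
}

param_names <- function(p) {
  if (p == 2L) c("mu", "tau", "gamma")
  else c("mu1", "mu2", "tau", "gamma1", "gamma2")
}

state_to_row <- function(state, p) {
  if (p == 2L) c(state$mu, state$tau, state$gamma)
  else c(state$mu, state$tau, state$gamma)
}

#' Run the sampling-resampling Gibbs sampler
#'
#' Iterates [gibbs_step()] `B + N` times from the initial state; the first
#' `B` states are burn-in. The chain is a deterministic function of
#' `(seed, data, spec, B, N, k)`.
#'
#' @param data a [direction_sample()].
#' @param spec a [scenario_spec()].
#' @param B burn-in length.
#' @param N number of kept states.
#' @param k candidate pool size per block.
#' @param init `"auto"` (location: mean direction of the data;
#'   concentration: moment estimate; skewness: 0), `"mle"` (start at the
#'   maximum likelihood fit), or a list with `mu`, `tau`, `gamma`. The
#'   probit-skewed posterior has a mirrored near-mode at
#'   `(mu', -gamma)`; because the argmax selection rule cannot jump
#'   between well-separated modes, the moment start can leave the basin
#'   choice to the first few candidate pools, whereas `"mle"` starts the
#'   chain in the basin the data favour.
#' @param fixed optional named list of blocks to hold fixed at a known
#'   value (e.g. `list(mu = 3, tau = 1)`); used by the prior-impact study
#'   when only `gamma` is unknown.
#' @param seed optional integer seed.
#' @param select candidate selection rule, see [gibbs_step()].
#' @return object of class `sfvml_chain` with the `(B + N) x d` state
#'   matrix, the burn-in marker, `k`, the scenario and the selected
#'   log-weights per step.
#' @export
run_chain <- function(data, spec, B = 5000, N = 500, k = 500, init = "auto",
                      fixed = NULL, seed = NULL,
                      select = c("argmax", "multinomial")) {
  select <- match.arg(select)
  stopifnot(inherits(data, "direction_sample"), inherits(spec, "scenario_spec"),
            B >= 0, N >= 1, k >= 1, unit_p(data) == spec$p)
  with_seed(seed, {
    if (identical(init, "auto")) init <- auto_init(data, spec)
    else if (identical(init, "mle")) init <- mle_init(data)
    if (!is.null(fixed)) init[names(fixed)] <- fixed
    state <- list(mu = init$mu, tau = init$tau, gamma = init$gamma)
    state$mu_cart <- to_cartesian(state$mu)
    env <- make_gibbs_env(data, spec, k, fixed = fixed, select = select)
    p <- spec$p
    d <- 2L * (p - 1L) + 1L
    states <- matrix(NA_real_, B + N, d,
                     dimnames = list(NULL, param_names(p)))
    logrho <- matrix(NA_real_, B + N, 3L,
                     dimnames = list(NULL, c("mu", "tau", "gamma")))
    for (it in seq_len(B + N)) {
      state <- tryCatch(gibbs_step_impl(state, env), error = function(e) {
        stop(sprintf("iteration %d: %s", it, conditionMessage(e)))
      })
      states[it, ] <- state_to_row(state, p)
      logrho[it, ] <- state$logrho
    }
    structure(list(states = states, burnin = B, N = N, k = k,
                   scenario = spec, seed = seed, fixed = fixed,
                   select = select, logrho = logrho, p = p),
              class = "sfvml_chain")
  })
}

#' Post-burn-in states of a chain
#'
#' @param chain an `sfvml_chain`.
#' @return the `N x d` matrix of kept states.
#' @export
kept_states <- function(chain) {
  stopifnot(inherits(chain, "sfvml_chain"))
  chain$states[(chain$burnin + 1L):nrow(chain$states), , drop = FALSE]
}

#' @export
print.sfvml_chain <- function(x, ...) {
  cat(sprintf("sfvml_chain: scenario %d (p = %d), B = %d, N = %d, k = %d\n",
              x$scenario$scenario, x$p, x$burnin, x$N, x$k))
  cat("posterior means (kept states):\n")
  print(signif(colMeans(kept_states(x)), 5))
  invisible(x)
}

#' Run independent chains and assess mixing
#'
#' Runs `n_chains` chains from independent substream seeds and reports the
#' rank-normalized split-R-hat per parameter.
#'
#' @inheritParams run_chain
#' @param n_chains number of chains (at least 2 for the diagnostic).
#' @param seed base seed; per-chain seeds are derived substreams.
#' @return object of class `sfvml_chain_set`: list of chains plus `rhat`.
#' @export
run_parallel_chains <- function(data, spec, n_chains = 4, B = 5000, N = 500,
                                k = 500, init = "auto", fixed = NULL,
                                seed = NULL, select = "argmax") {
  stopifnot(n_chains >= 2)
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1L)
  chains <- lapply(seq_len(n_chains), function(i) {
    run_chain(data, spec, B = B, N = N, k = k, init = init, fixed = fixed,
              seed = derive_seed(seed, paste0("chain", i)), select = select)
  })
  draws <- lapply(chains, kept_states)
  structure(list(chains = chains, rhat = split_rhat(draws), seed = seed),
            class = "sfvml_chain_set")
}

#' Rank-normalized split R-hat
#'
#' Standard between/within mixing diagnostic: each chain is split in half,
#' pooled draws are rank-normalized to normal scores, and the
#' between-to-within variance ratio is folded into
#' `sqrt((n - 1)/n + B/(n W))`. Values near 1 indicate good mixing.
#'
#' @param draws list of equally sized draw matrices (one per chain,
#'   parameters in columns).
#' @return named vector of R-hat values.
#' @export
split_rhat <- function(draws) {
  stopifnot(length(draws) >= 2)
  d <- ncol(draws[[1L]])
  n0 <- nrow(draws[[1L]])
  half <- n0 %/% 2L
  out <- numeric(d)
  for (j in seq_len(d)) {
    cols <- lapply(draws, function(m) m[, j])
    splits <- unlist(lapply(cols, function(v) {
      list(v[seq_len(half)], v[(half + 1L):(2L * half)])
    }), recursive = FALSE)
    x <- matrix(unlist(splits), nrow = half)
    r <- matrix(rank(x, ties.method = "average"), nrow = half)
    z <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
    m <- ncol(z); n <- nrow(z)
    mns <- colMeans(z)
    B <- n * stats::var(mns)
    W <- mean(apply(z, 2, stats::var))
    out[j] <- sqrt((n - 1) / n + B / (n * W))
  }
  names(out) <- colnames(draws[[1L]])
  out
}
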