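# Exact von Mises variates by the Best-Fisher wrapped-Cauchy rejection
# method, vectorized over the rejection loop. kappa = 0 falls back to the
# uniform law on the circle.
rvonmises_angle <- function(n, mu, kappa) {
  if (n == 0L) return(numeric(0))
  if (length(kappa) == 1L) kappa <- rep(kappa, n)
  stopifnot(length(kappa) == n, all(kappa >= 0))
  if (length(mu) == 1L) mu <- rep(mu, n)
  out <- numeric(n)
  # below ~1e-5 the wrapped-Cauchy constants cancel catastrophically and
  # the law is indistinguishable from uniform (total variation ~ kappa)
  unif <- kappa < 1e-5
  out[unif] <- stats::runif(sum(unif), -pi, pi)
  todo <- which(!unif)
  if (length(todo)) {
    kap <- kappa[todo]
    a <- 1 + sqrt(1 + 4 * kap^2)
    b <- (a - sqrt(2 * a)) / (2 * kap)
    r <- (1 + b^2) / (2 * b)
    theta <- numeric(length(todo))
    active <- seq_along(todo)
    while (length(active)) {
      m <- length(active)
      u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
      z <- cos(pi * u1)
      f <- (1 + r[active] * z) / (r[active] + z)
      cc <- kap[active] * (r[active] - f)
      acc <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
      if (any(acc)) {
        idx <- active[acc]
        theta[idx] <- sign(u3[acc] - 0.5) * acos(pmin(1, pmax(-1, f[acc])))
      }
      active <- active[!acc]
    }
    out[todo] <- theta
  }
  wrap_pi(out + mu)
}

# Inverse-CDF draw of the axial coordinate t = x . mu for the FvML law on
# S^2: t = 1 + log(u + (1 - u) * exp(-2 tau)) / tau; exact and stable for
# large tau. tau = 0 gives t ~ Uniform(-1, 1). Vectorized over tau.
rfvml_t_s2 <- function(n, tau) {
  if (length(tau) == 1L) tau <- rep(tau, n)
  u <- stats::runif(n)
  out <- numeric(n)
  unif <- tau < 1e-8
  out[unif] <- 2 * u[unif] - 1
  i <- !unif
  # log(u + (1-u) e^{-2 tau}) computed as log(u) + log1p((1-u)/u e^{-2 tau})
  out[i] <- 1 + (log(u[i]) + log1p((1 - u[i]) / u[i] * exp(-2 * tau[i]))) /
    tau[i]
  pmin(1, pmax(-1, out))
}

#' Sample from the FvML distribution
#'
#' Exact draws from the rotationally symmetric Fisher-von Mises-Langevin
#' law. On the circle the Best-Fisher rejection sampler for the von Mises
#' distribution is used; on the sphere the axial coordinate is drawn by its
#' closed-form inverse CDF, the longitude uniformly, and the result rotated
#' to the location `mu`.
#'
#' @param n sample size.
#' @param mu location angles (scalar for `p = 2`, length 2 for `p = 3`).
#' @param tau concentration, non-negative.
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return a [direction_sample()].
#' @export
sample_fvml <- function(n, mu, tau, seed = NULL) {
  stopifnot(n >= 1, tau >= 0)
  p <- length(mu) + 1L
  with_seed(seed, {
    if (p == 2L) {
      direction_sample(rvonmises_angle(n, mu, tau))
    } else if (p == 3L) {
      mu_cart <- to_cartesian(mu)
      tt <- rfvml_t_s2(n, tau)
      psi <- stats::runif(n, 0, 2 * pi)
      fr <- tangent_frame(mu_cart)
      s <- sqrt(pmax(0, 1 - tt^2))
      X <- tt %o% mu_cart +
        (s * cos(psi)) %o% fr$upsilon[, 1L] +
        (s * sin(psi)) %o% fr$upsilon[, 2L]
      direction_sample(to_angles(X), p = 3L)
    } else {
      stop("only p = 2 and p = 3 are supported")
    }
  })
}

#' Sample from the skew-FvML distribution
#'
#' Exact draws by the sign-flip construction: generate `Y` from the
#' symmetric FvML core, draw a fresh uniform sign vector `u` on `S^{p-2}`
#' (`+/-1` on the circle), keep it with probability
#' `Pi(sqrt(1 - t^2) * gamma . u)` and flip it otherwise, then reassemble
#' `X = t * mu + sqrt(1 - t^2) * Ups_mu u`. Exactly one output per input;
#' there is no rejection.
#'
#' @param n sample size.
#' @param params an [sfvml_params()].
#' @param seed optional integer seed.
#' @return a [direction_sample()].
#' @export
sample_sfvml <- function(n, params, seed = NULL) {
  stopifnot(inherits(params, "sfvml_params"), n >= 1)
  p <- params$p
  with_seed(seed, {
    Y <- sample_fvml(n, params$mu, params$tau)
    Yc <- as_cartesian(Y)
    tt <- pmin(1, pmax(-1, drop(Yc %*% params$mu_cart)))
    s <- sqrt(pmax(0, 1 - tt^2))
    fr <- tangent_frame(params$mu_cart)
    sk <- skewing_function(params$skewing)
    if (p == 2L) {
      u <- matrix(sample(c(-1, 1), n, replace = TRUE), ncol = 1L)
    } else {
      phi <- stats::runif(n, 0, 2 * pi)
      u <- cbind(cos(phi), sin(phi))
    }
    keep <- stats::runif(n) <= sk$Pi(s * drop(u %*% params$gamma))
    u <- u * ifelse(keep, 1, -1)
    X <- tt %o% params$mu_cart + (s * u) %*% t(fr$upsilon)
    direction_sample(to_angles(X), p = p)
  })
}

#' Univariate-update slice sampler
#'
#' Coordinate-wise slice sampling with stepping-out and shrinkage (Neal,
#' 2003) for an unnormalized log-density on `R^d`, optionally restricted to
#' a box. Used for the non-conjugate location-concentration prior and as a
#' general-purpose posterior sampler.
#'
#' @param log_target function mapping a length-`d` numeric vector to a
#'   finite log-density value (or `-Inf` outside the support).
#' @param x0 starting point; `log_target(x0)` must be finite.
#' @param n number of states to return (after burn-in and thinning).
#' @param width initial bracket width for stepping out.
#' @param burnin number of initial sweeps to discard.
#' @param thin keep every `thin`-th sweep.
#' @param max_step maximum number of stepping-out extensions per side.
#' @param lower,upper optional box constraints (length `d` or scalars).
#' @param seed optional integer seed.
#' @return an `n x d` matrix of states.
#' @export
slice_sample <- function(log_target, x0, n, width = 1, burnin = 0, thin = 1,
                         max_step = 50, lower = -Inf, upper = Inf,
                         seed = NULL) {
  d <- length(x0)
  lower <- rep_len(lower, d); upper <- rep_len(upper, d)
  f0 <- log_target(x0)
  if (!is.finite(f0)) stop("log_target must be finite at x0")
  eval_pt <- function(x) {
    v <- log_target(x)
    if (is.nan(v)) {
      stop(sprintf("log_target returned NaN at (%s)",
                   paste(signif(x, 6), collapse = ", ")))
    }
    v
  }
  with_seed(seed, {
    out <- matrix(NA_real_, n, d)
    x <- x0
    fx <- f0
    total <- burnin + n * thin
    kept <- 0L
    for (it in seq_len(total)) {
      for (j in seq_len(d)) {
        y <- fx - stats::rexp(1)
        L <- x; R <- x
        L[j] <- max(lower[j], x[j] - stats::runif(1) * width)
        R[j] <- min(upper[j], L[j] + width)
        steps <- max_step
        while (steps > 0 && L[j] > lower[j] && eval_pt(L) > y) {
          L[j] <- max(lower[j], L[j] - width); steps <- steps - 1L
        }
        steps <- max_step
        while (steps > 0 && R[j] < upper[j] && eval_pt(R) > y) {
          R[j] <- min(upper[j], R[j] + width); steps <- steps - 1L
        }
        repeat {
          xp <- x
          xp[j] <- stats::runif(1, L[j], R[j])
          fxp <- eval_pt(xp)
          if (fxp >= y) {
            x <- xp; fx <- fxp
            break
          }
          if (xp[j] < x[j]) L[j] <- xp[j] else R[j] <- xp[j]
        }
      }
      if (it > burnin && (it - burnin) %% thin == 0L) {
        kept <- kept + 1L
        out[kept, ] <- x
      }
    }
    out
  })
}

# One vectorized slice sweep applied to m independent 1-d chains sharing the
# same target family. `logf` maps a vector of m points to m log-density
# values. Bounds are scalars. Used to refresh the candidate pool of the
# non-conjugate prior: the m chains are mutually independent, so after
# warm-up each sweep yields m independent draws.
slice_sweep_vec <- function(x, logf, width = 1, lower = -Inf, upper = Inf,
                            max_step = 50) {
  m <- length(x)
  y <- logf(x) - stats::rexp(m)
  L <- pmax(lower, x - stats::runif(m) * width)
  R <- pmin(upper, L + width)
  for (side in 1:2) {
    steps <- 0L
    repeat {
      b <- if (side == 1L) L else R
      open <- if (side == 1L) b > lower else b < upper
      act <- which(open & logf(b) > y)
      if (!length(act) || steps >= max_step) break
      if (side == 1L) L[act] <- pmax(lower, L[act] - width)
      else R[act] <- pmin(upper, R[act] + width)
      steps <- steps + 1L
    }
  }
  xnew <- x
  active <- seq_len(m)
  while (length(active)) {
    prop <- L[active] + stats::runif(length(active)) * (R[active] - L[active])
    ok <- logf(prop) >= y[active]
    xnew[active[ok]] <- prop[ok]
    shrink <- !ok
    if (any(shrink)) {
      i <- active[shrink]
      lo <- prop[shrink] < xnew[i]
      L[i[lo]] <- prop[shrink][lo]
      R[i[!lo]] <- prop[shrink][!lo]
    }
    active <- active[shrink]
  }
  xnew
}
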