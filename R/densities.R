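#' Log normalizing constant of the FvML distribution
#'
#' `C(tau) = (2*pi)^(-p/2) * tau^(p/2-1) / I_{p/2-1}(tau)` with `I` the
#' modified Bessel function of the first kind. Evaluated with exponentially
#' scaled Bessel functions so concentrations up to 1e4 do not overflow.
#' The `tau -> 0` limit is the uniform density on the sphere,
#' `C(0) = Gamma(p/2) / (2 * pi^(p/2))`.
#'
#' @param tau concentration, `tau >= 0` (vectorized).
#' @param p ambient dimension, `p >= 2`.
#' @return `log C(tau)`.
#' @export
log_norm_const <- function(tau, p) {
  if (any(tau < 0)) stop("tau must be non-negative")
  stopifnot(p >= 2)
  nu <- p / 2 - 1
  out <- numeric(length(tau))
  tiny <- tau < 1e-10
  # log I_nu(tau) = log(besselI scaled) + tau
  out[!tiny] <- -p / 2 * log(2 * pi) + nu * log(tau[!tiny]) -
    (log(besselI(tau[!tiny], nu, expon.scaled = TRUE)) + tau[!tiny])
  out[tiny] <- lgamma(p / 2) - log(2) - (p / 2) * log(pi)
  out
}

#' Skewing functions
#'
#' A skewing function is a monotone map `Pi : R -> [0, 1]` with
#' `Pi(t) + Pi(-t) = 1`. Two choices are provided: `"probit"` (the standard
#' normal CDF, used by all Bayesian machinery in the package) and `"sine"`
#' (`Pi(x) = (1 + x) / 2` on `[-1, 1]`, the linear skew used by the
#' sine-skewed von Mises family; only valid on the circle with
#' `|gamma| <= 1`).
#'
#' @param id `"probit"` or `"sine"`.
#' @return list with elements `id`, `Pi` (function) and `log_Pi`
#'   (numerically stable log).
#' @export
skewing_function <- function(id = c("probit", "sine")) {
  id <- match.arg(id)
  if (id == "probit") {
    list(id = id,
         Pi = function(t) stats::pnorm(t),
         log_Pi = function(t) stats::pnorm(t, log.p = TRUE))
  } else {
    list(id = id,
         Pi = function(t) {
           if (any(abs(t) > 1 + 1e-12)) stop("sine skewing needs |t| <= 1")
           pmin(1, pmax(0, (1 + t) / 2))
         },
         log_Pi = function(t) {
           if (any(abs(t) > 1 + 1e-12)) stop("sine skewing needs |t| <= 1")
           log1p(pmax(t, -1)) - log(2)
         })
  }
}

#' Skew-FvML parameter set
#'
#' Bundles the location `mu` (given as `p - 1` angles, radians), the
#' concentration `tau >= 0`, the skewness vector `gamma` (length `p - 1`)
#' and the skewing-function choice.
#'
#' @param mu location angles: a scalar angle for `p = 2`, `(theta1, theta2)`
#'   for `p = 3`.
#' @param tau concentration, non-negative.
#' @param gamma skewness vector of length `p - 1`.
#' @param skewing `"probit"` (default) or `"sine"` (`p = 2`,
#'   `gamma` in `[-1, 1]` only).
#' @return object of class `sfvml_params`.
#' @export
sfvml_params <- function(mu, tau, gamma, skewing = c("probit", "sine")) {
  skewing <- match.arg(skewing)
  p <- length(mu) + 1L
  stopifnot(p %in% c(2L, 3L), length(gamma) == p - 1L,
            is.finite(tau), tau >= 0, all(is.finite(gamma)))
  if (skewing == "sine") {
    if (p != 2L) stop("sine skewing is only defined for p = 2")
    if (abs(gamma) > 1) stop("sine skewing needs gamma in [-1, 1]")
  }
  if (p == 2L) mu <- wrap_pi(mu)
  structure(list(mu = mu, mu_cart = to_cartesian(mu), tau = tau,
                 gamma = gamma, skewing = skewing, p = p),
            class = "sfvml_params")
}

#' @export
print.sfvml_params <- function(x, ...) {
  cat(sprintf("sfvml_params (p = %d, %s skewing): mu = (%s), tau = %g, gamma = (%s)\n",
              x$p, x$skewing, paste(signif(x$mu, 5), collapse = ", "),
              x$tau, paste(signif(x$gamma, 5), collapse = ", ")))
  invisible(x)
}

#' FvML log-density
#'
#' `log f(x) = log C(tau) + tau * x . mu`, the rotationally symmetric
#' Fisher-von Mises-Langevin density on `S^{p-1}`.
#'
#' @param x unit vector, or matrix of unit rows.
#' @param mu unit vector (Cartesian).
#' @param tau concentration, non-negative.
#' @return log-density value(s).
#' @export
fvml_logpdf <- function(x, mu, tau) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(mu)) stop("dimension mismatch between x and mu")
  drop(log_norm_const(tau, length(mu)) + tau * (x %*% mu))
}

#' Skew-FvML log-density
#'
#' `log 2 + log C(tau) + tau * x . mu + log Pi(gamma . Ups_mu' x)`, where
#' `Ups_mu' x = sqrt(1 - (x . mu)^2) * U_mu(x)` is the tangent component of
#' `x` in the deterministic Householder frame of [tangent_frame()].
#'
#' @param x unit vector or matrix of unit rows (Cartesian).
#' @param params an [sfvml_params()].
#' @return log-density value(s).
#' @export
sfvml_logpdf <- function(x, params) {
  stopifnot(inherits(params, "sfvml_params"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  p <- params$p
  if (ncol(x) != p) stop("dimension mismatch between x and params")
  fr <- tangent_frame(params$mu_cart)
  sk <- skewing_function(params$skewing)
  w <- drop(fr$upsilon %*% params$gamma)      # gamma' Ups' x = (Ups gamma) . x
  arg <- drop(x %*% w)
  log(2) + fvml_logpdf(x, params$mu_cart, params$tau) + sk$log_Pi(arg)
}

#' Skew-von Mises log-density on the circle
#'
#' `log f(theta) = -log(pi * I_0(tau)) + tau * cos(theta - mu) +
#' log Pi(gamma * sin(theta - mu))`. With `skewing = "sine"` this is the
#' sine-skewed von Mises density (requires `gamma` in `[-1, 1]`); with the
#' probit skew it is the circular member of the skew-FvML family.
#'
#' @param theta angle(s), radians.
#' @param mu_angle location angle in `(-pi, pi]`.
#' @param tau concentration, non-negative.
#' @param gamma scalar skewness.
#' @param skewing `"probit"` or `"sine"`.
#' @return log-density value(s).
#' @export
svm_logpdf <- function(theta, mu_angle, tau, gamma,
                       skewing = c("probit", "sine")) {
  skewing <- match.arg(skewing)
  stopifnot(tau >= 0)
  if (skewing == "sine" && abs(gamma) > 1) {
    stop("sine skewing needs gamma in [-1, 1]")
  }
  sk <- skewing_function(skewing)
  d <- theta - mu_angle
  logI0 <- log(besselI(tau, 0, expon.scaled = TRUE)) + tau
  -log(pi) - logI0 + tau * cos(d) + sk$log_Pi(gamma * sin(d))
}
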