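# Independent numerical oracles used across the suite.

# integral of f over (-pi, pi] by Gauss-Legendre quadrature (trapezoid
# fallback if pracma is unavailable).
circle_integral <- function(f, n = 400) {
  if (requireNamespace("pracma", quietly = TRUE)) {
    gl <- pracma::gaussLegendre(n, -pi, pi)
    sum(gl$w * f(gl$x))
  } else {
    x <- seq(-pi, pi, length.out = 20001)
    y <- f(x)
    sum((y[-1] + y[-length(y)]) / 2) * diff(x[1:2])
  }
}

# integral of g(theta1, theta2) * sin(theta1) over the sphere in spherical
# coordinates, by a product Gauss grid.
sphere_integral <- function(g, n = 200) {
  if (requireNamespace("pracma", quietly = TRUE)) {
    g1 <- pracma::gaussLegendre(n, 0, pi)
    g2 <- pracma::gaussLegendre(n, -pi, pi)
    gr <- expand.grid(t1 = g1$x, t2 = g2$x)
    w <- as.vector(outer(g1$w, g2$w))
    sum(w * g(gr$t1, gr$t2) * sin(gr$t1))
  } else {
    t1 <- seq(1e-6, pi - 1e-6, length.out = 801)
    t2 <- seq(-pi, pi, length.out = 801)
    gr <- expand.grid(t1 = t1, t2 = t2)
    mean(g(gr$t1, gr$t2) * sin(gr$t1)) * pi * 2 * pi
  }
}

# brute-force optimal-transport cost between equal-size empirical
# distributions: minimum over all assignments of the mean |x - y| cost.
# Exact for n <= 7 (enumerates all permutations).
w1_permutation_oracle <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) <= 7)
  n <- length(a)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    best <- min(best, mean(abs(a - b[p])))
  }
  best
}

# minimal chain object for summary-level unit tests
fake_chain <- function(states, p = 2L, burnin = 0L) {
  structure(list(states = states, burnin = burnin,
                 N = nrow(states) - burnin, p = p),
            class = "sfvml_chain")
}

ref_spec2 <- function() {
  scenario_spec(2, mu0 = 1, zeta = 10, eta = 0.5,
                xi = 0.5, sigma = 0.5, lambda = -1)
}

ref_spec4 <- function() {
  scenario_spec(4, mu0 = 0.5, tau0 = 0.01, alpha = 0.5, beta = 9,
                xi = 0.5, sigma = 0.5, lambda = -2)
}

ref_spec3 <- function() {
  scenario_spec(3, mu0 = 1, tau0 = 9, alpha = 0.5, beta = 5,
                xi = -4, sigma = 1)
}
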