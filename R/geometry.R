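#' Wrap angles to the half-open interval (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles congruent to `x` modulo `2*pi`, lying in `(-pi, pi]`.
#' @export
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

#' Spherical-coordinate to Cartesian transformation
#'
#' Maps `p - 1` angles to a unit vector via the standard cosine
#' transformation `x = (cos t1, sin t1 cos t2, sin t1 sin t2)`; on the circle
#' (`p = 2`) this is `(cos t, sin t)`.
#'
#' @param angles numeric vector of length `p - 1` (a single point) or a
#'   matrix with `p - 1` columns (one point per row). `p = 2` and `p = 3`
#'   are supported.
#' @return a unit vector of length `p`, or an `n x p` matrix of unit rows.
#' @export
to_cartesian <- function(angles) {
  if (is.matrix(angles)) {
    stopifnot(all(is.finite(angles)))
    if (ncol(angles) == 1L) {
      return(cbind(cos(angles[, 1L]), sin(angles[, 1L])))
    } else if (ncol(angles) == 2L) {
      return(cbind(cos(angles[, 1L]),
                   sin(angles[, 1L]) * cos(angles[, 2L]),
                   sin(angles[, 1L]) * sin(angles[, 2L])))
    }
    stop("only p = 2 and p = 3 are supported")
  }
  if (!all(is.finite(angles))) stop("angles must be finite")
  if (length(angles) == 1L) {
    c(cos(angles), sin(angles))
  } else if (length(angles) == 2L) {
    c(cos(angles[1L]),
      sin(angles[1L]) * cos(angles[2L]),
      sin(angles[1L]) * sin(angles[2L]))
  } else {
    stop("only p = 2 and p = 3 are supported")
  }
}

#' Cartesian to spherical-coordinate transformation
#'
#' Inverse of [to_cartesian()]. On the circle the angle lies in `(-pi, pi]`;
#' on the sphere the colatitude `t1` lies in `[0, pi]` and the longitude `t2`
#' in `(-pi, pi]`. At a pole (`|x1| = 1`, `p = 3`) the longitude is not
#' identified; it is set to 0 and the result carries attribute
#' `degenerate = TRUE`.
#'
#' @param x unit vector of length 2 or 3, or a matrix of unit rows.
#' @return angle vector of length `p - 1` (or matrix), radians.
#' @export
to_angles <- function(x) {
  if (!is.matrix(x)) {
    out <- to_angles(matrix(x, nrow = 1L))
    deg <- attr(out, "degenerate")
    out <- drop(out)
    if (any(deg)) attr(out, "degenerate") <- TRUE
    return(out)
  }
  p <- ncol(x)
  if (p == 2L) {
    ang <- matrix(atan2(x[, 2L], x[, 1L]), ncol = 1L)
    ang[ang <= -pi] <- pi
    attr(ang, "degenerate") <- rep(FALSE, nrow(x))
    return(ang)
  }
  if (p != 3L) stop("only p = 2 and p = 3 are supported")
  t1 <- acos(pmin(1, pmax(-1, x[, 1L])))
  s <- sqrt(pmax(0, x[, 2L]^2 + x[, 3L]^2))
  deg <- s < 1e-14
  t2 <- ifelse(deg, 0, atan2(x[, 3L], x[, 2L]))
  t2[t2 <= -pi] <- pi
  ang <- cbind(t1, t2)
  dimnames(ang) <- NULL
  attr(ang, "degenerate") <- deg
  ang
}

#' Tangent frame at a point of the sphere
#'
#' Builds the `p x (p - 1)` semi-orthogonal matrix `upsilon` whose columns
#' span the tangent space at `mu`, satisfying
#' `t(upsilon) %*% upsilon = I_{p-1}` and
#' `upsilon %*% t(upsilon) = I_p - mu mu'`.
#'
#' For `p = 2` the single column is the +90 degree rotation of `mu`, so the
#' scalar tangent coordinate of a point at angle `theta` equals
#' `sin(theta - mu_angle)`. For `p >= 3` the frame is the Householder
#' reflection mapping `e1` to `mu`, applied to the remaining standard basis
#' vectors; the construction is deterministic in `mu`.
#'
#' @param mu unit vector of length `p`.
#' @return object of class `tangent_frame`: a list with `mu` and `upsilon`.
#' @export
tangent_frame <- function(mu) {
  p <- length(mu)
  stopifnot(p >= 2L, abs(sum(mu^2) - 1) < 1e-8)
  if (p == 2L) {
    ups <- matrix(c(-mu[2L], mu[1L]), 2L, 1L)
  } else {
    v <- -mu
    v[1L] <- v[1L] + 1            # v = e1 - mu
    nv2 <- sum(v^2)
    if (nv2 < 1e-28) {
      ups <- diag(p)[, -1L, drop = FALSE]
    } else {
      H <- diag(p) - (2 / nv2) * tcrossprod(v)
      ups <- H[, -1L, drop = FALSE]
    }
  }
  structure(list(mu = mu, upsilon = ups), class = "tangent_frame")
}

#' Tangent-normal decomposition
#'
#' Splits a unit vector as `x = t * mu + sqrt(1 - t^2) * upsilon %*% u`, with
#' `t = x . mu` and `u` the unit sign vector of the tangent component
#' (a scalar in `{-1, +1}` when `p = 2`). When `x = +/- mu` the sign vector
#' is not identified; the first tangent basis vector is returned and the
#' `degenerate` flag is set.
#'
#' @param x unit vector.
#' @param frame a [tangent_frame()].
#' @return list with `t`, `u`, and logical `degenerate`.
#' @export
tangent_decompose <- function(x, frame) {
  stopifnot(inherits(frame, "tangent_frame"))
  tt <- pmin(1, pmax(-1, sum(x * frame$mu)))
  v <- drop(crossprod(frame$upsilon, x))
  nv <- sqrt(sum(v^2))
  if (nv < 1e-14) {
    u <- c(1, rep(0, length(v) - 1L))
    degenerate <- TRUE
  } else {
    u <- v / nv
    degenerate <- FALSE
  }
  list(t = tt, u = u, degenerate = degenerate)
}

#' Construct a sample of directions
#'
#' A `direction_sample` stores `n` points of the unit sphere `S^{p-1}` as
#' angles (radians): one column for `p = 2` (`theta` in `(-pi, pi]`), two
#' columns (`theta1`, `theta2`) for `p = 3`. The Cartesian view is available
#' through [as_cartesian()].
#'
#' @param angles numeric vector or `n x (p-1)` matrix of angles, radians.
#' @param p dimension of the ambient space (2 or 3); inferred from the
#'   number of columns when omitted.
#' @return object of class `direction_sample`.
#' @export
direction_sample <- function(angles, p = NULL) {
  if (!is.matrix(angles)) angles <- matrix(angles, ncol = 1L)
  if (is.null(p)) p <- ncol(angles) + 1L
  stopifnot(p %in% c(2L, 3L), ncol(angles) == p - 1L, all(is.finite(angles)))
  if (p == 2L) angles[, 1L] <- wrap_pi(angles[, 1L])
  dimnames(angles) <- NULL
  attr(angles, "degenerate") <- NULL
  structure(angles, class = "direction_sample", p = p)
}

#' Cartesian view of a direction sample
#'
#' @param x a [direction_sample()].
#' @return `n x p` matrix of unit rows.
#' @export
as_cartesian <- function(x) {
  stopifnot(inherits(x, "direction_sample"))
  to_cartesian(unclass_angles(x))
}

# strip class/attrs, keep the angle matrix
unit_p <- function(x) attr(x, "p")
unclass_angles <- function(x) {
  y <- unclass(x)
  attr(y, "p") <- NULL
  y
}

#' @export
print.direction_sample <- function(x, ...) {
  cat(sprintf("direction_sample: n = %d points on S^%d (angles, radians)\n",
              nrow(x), unit_p(x) - 1L))
  utils::str(unclass_angles(x))
  invisible(x)
}
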