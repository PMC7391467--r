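# Horizontal integral curves: constant-coefficient association-field models.
#
# A horizontal curve follows a fixed combination c1 X1 + c2 X2 + c3 X3 +
# c4 X4 of the horizontal frame. With constant coefficients the system has a
# closed-form solution (circular arcs in space when the orientation turns);
# a classical 4th-order integrator serves as an independent oracle.

#' Coefficients of a horizontal vector field
#'
#' @param c1,c2,c3,c4 Finite real weights on `X1..X4`.
#' @return An object of class `curve_coefficients`.
#' @export
curve_coefficients <- function(c1 = 0, c2 = 0, c3 = 0, c4 = 0) {
  v <- c(c1 = c1, c2 = c2, c3 = c3, c4 = c4)
  if (!all(is.finite(v))) stop("curve coefficients must be finite")
  structure(as.list(v), class = "curve_coefficients")
}

#' Velocity of a horizontal curve
#'
#' The coordinate components of
#' \eqn{\gamma' = c_1 X_1 + c_2 X_2 + c_3 X_3 + c_4 X_4} at a feature point:
#' \deqn{(c_1\cos\theta - c_3\sin\theta,\; c_1\sin\theta + c_3\cos\theta,\;
#'        c_2,\; c_4,\; c_3\,\omega).}
#' The fifth component is the phase rate \eqn{\phi' = c_3\,\omega}.
#'
#' @param point A [feature_point()], or a bare numeric 5-vector
#'   `(q1, q2, theta, omega, phi)` (used internally by the integrator, where
#'   angles are not wrapped).
#' @param coeffs A [curve_coefficients()].
#' @return Numeric length-5 vector `(q1', q2', theta', omega', phi')`.
#' @export
curve_velocity <- function(point, coeffs) {
  stopifnot(inherits(coeffs, "curve_coefficients"))
  if (inherits(point, "feature_point")) {
    theta <- point$theta; omega <- point$omega
  } else {
    stopifnot(length(point) == 5)
    theta <- point[3]; omega <- point[4]
  }
  c(coeffs$c1 * cos(theta) - coeffs$c3 * sin(theta),
    coeffs$c1 * sin(theta) + coeffs$c3 * cos(theta),
    coeffs$c2,
    coeffs$c4,
    coeffs$c3 * omega)
}

curve_samples <- function(times, q1, q2, theta, omega, phi, init, coeffs) {
  keep <- omega > 0
  if (!all(keep)) {
    first_bad <- which(!keep)[1]
    keep <- seq_along(times) < first_bad
    warning("curve truncated where omega reached the manifold boundary (omega <= 0)")
  }
  df <- data.frame(t = times, q1 = q1, q2 = q2, theta = theta,
                   omega = omega, phi = phi)[keep, , drop = FALSE]
  rownames(df) <- NULL
  structure(list(samples = df, init = init, coeffs = coeffs),
            class = "horizontal_curve")
}

#' @export
print.horizontal_curve <- function(x, ...) {
  cat(sprintf("<horizontal_curve %d samples, t in [%g, %g], c=(%g, %g, %g, %g)>\n",
              nrow(x$samples), min(x$samples$t), max(x$samples$t),
              x$coeffs$c1, x$coeffs$c2, x$coeffs$c3, x$coeffs$c4))
  invisible(x)
}

#' @export
as.data.frame.horizontal_curve <- function(x, ...) x$samples

#' Closed-form constant-coefficient horizontal curve
#'
#' Exact solution of the horizontal ODE system. When the orientation turns
#' (`|c2| > eps_switch`) the spatial trace is a circular arc of radius
#' `|c1/c2|` (for `c3 = 0`); in the straight branch (`c2 = 0`) the
#' orientation is constant. In both branches
#' `theta(t) = c2 t + theta0`, `omega(t) = c4 t + omega0` and
#' `phi(t) = (c3 c4 t^2 + 2 t c3 omega0 + 2 phi0) / 2`.
#' Samples with `omega <= 0` are truncated: positive frequency is a manifold
#' constraint.
#'
#' @param init Initial [feature_point()].
#' @param coeffs A [curve_coefficients()].
#' @param times Nondecreasing sample times starting at 0.
#' @param eps_switch Branch threshold on `|c2|`; below it the straight
#'   branch is used (the two branches agree to ~1e-5 at `|c2| = 1e-8`).
#' @return An object of class `horizontal_curve`.
#' @export
closed_form_curve <- function(init, coeffs, times = seq(0, 1, length.out = 101),
                              eps_switch = 1e-10) {
  stopifnot(inherits(init, "feature_point"),
            inherits(coeffs, "curve_coefficients"))
  t <- as.numeric(times)
  if (length(t) == 0 || abs(t[1]) > 0) stop("`times` must start at 0")
  c1 <- coeffs$c1; c2 <- coeffs$c2; c3 <- coeffs$c3; c4 <- coeffs$c4
  th0 <- init$theta; om0 <- init$omega
  if (abs(c2) > eps_switch) {
    tht <- c2 * t + th0
    q1 <- init$q1 + (-c3 * cos(th0) + c3 * cos(tht) -
                       c1 * sin(th0) + c1 * sin(tht)) / c2
    q2 <- init$q2 + (c1 * cos(th0) - c1 * cos(tht) -
                       c3 * sin(th0) + c3 * sin(tht)) / c2
    theta <- tht
  } else {
    q1 <- init$q1 + t * (c1 * cos(th0) - c3 * sin(th0))
    q2 <- init$q2 + t * (c3 * cos(th0) + c1 * sin(th0))
    theta <- rep(th0, length(t))
  }
  omega <- c4 * t + om0
  phi <- (c3 * c4 * t^2 + 2 * t * c3 * om0 + 2 * init$phi) / 2
  curve_samples(t, q1, q2, theta, omega, phi, init, coeffs)
}

#' Numerically integrated horizontal curve
#'
#' Classical 4th-order Runge--Kutta integration of [curve_velocity()];
#' the independent oracle for [closed_form_curve()], with 4th-order
#' convergence under step refinement.
#'
#' @inheritParams closed_form_curve
#' @param step Maximum internal integration step.
#' @return An object of class `horizontal_curve`.
#' @export
numeric_curve <- function(init, coeffs, times = seq(0, 1, length.out = 101),
                          step = 1e-3) {
  stopifnot(inherits(init, "feature_point"),
            inherits(coeffs, "curve_coefficients"), step > 0)
  t <- as.numeric(times)
  if (length(t) == 0 || abs(t[1]) > 0) stop("`times` must start at 0")
  state <- c(init$q1, init$q2, init$theta, init$omega, init$phi)
  out <- matrix(0, length(t), 5)
  out[1, ] <- state
  f <- function(y) curve_velocity(y, coeffs)
  for (n in seq_along(t)[-1]) {
    span <- t[n] - t[n - 1]
    nsub <- max(1L, ceiling(span / step))
    hh <- span / nsub
    for (m in seq_len(nsub)) {
      k1 <- f(state)
      k2 <- f(state + hh / 2 * k1)
      k3 <- f(state + hh / 2 * k2)
      k4 <- f(state + hh * k3)
      state <- state + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[n, ] <- state
  }
  curve_samples(t, out[, 1], out[, 2], out[, 3], out[, 4], out[, 5],
                init, coeffs)
}

#' Fan of horizontal curves
#'
#' One curve per value of a varied coefficient, all from the same initial
#' point -- the association-field fans: varying `c2` on top of `X1` sweeps
#' circular arcs mirrored across the initial axis; varying `c4` on top of
#' `X3` keeps the orientation constant while drifting in frequency.
#'
#' @param init Initial [feature_point()].
#' @param base_coeffs A [curve_coefficients()] giving the fixed weights.
#' @param vary Which coefficient to vary: `"c1".."c4"`.
#' @param values Numeric values the varied coefficient takes.
#' @param times Sample times passed to [closed_form_curve()].
#' @return A list of `horizontal_curve`s, named by the varied value.
#' @export
curve_fan <- function(init, base_coeffs, vary = c("c2", "c4", "c1", "c3"),
                      values, times = seq(0, 1, length.out = 101)) {
  vary <- match.arg(vary)
  stopifnot(inherits(base_coeffs, "curve_coefficients"))
  out <- lapply(values, function(v) {
    cf <- base_coeffs
    cf[[vary]] <- v
    closed_form_curve(init, cf, times)
  })
  names(out) <- format(values)
  out
}

#' Export sampled curves as CSV
#'
#' Columns `t, q1, q2, theta, omega, phi`; a list of curves gains a leading
#' `curve` column.
#'
#' @param curves A `horizontal_curve` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(curves, path) {
  if (inherits(curves, "horizontal_curve")) {
    df <- curves$samples
  } else {
    stopifnot(length(curves) > 0,
              all(vapply(curves, inherits, TRUE, "horizontal_curve")))
    nm <- names(curves)
    if (is.null(nm)) nm <- as.character(seq_along(curves))
    df <- do.call(rbind, lapply(seq_along(curves), function(i) {
      cbind(curve = nm[i], curves[[i]]$samples)
    }))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
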