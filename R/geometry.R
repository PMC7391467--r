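# The sub-Riemannian engine: contact form, horizontal frame, commutators,
# induced metric with closed-form inverse/determinant, and the per-frequency
# group structure.
#
# Coordinates are ordered (x, y, theta, omega, s) throughout. The contact
# form Theta = -omega sin(theta) dx + omega cos(theta) dy - ds annihilates
# the horizontal frame X1..X4; its kernel is the space of admissible
# directions of neural-activity propagation.

coord_names <- c("x", "y", "theta", "omega", "s")

#' Horizontal frame at a feature point
#'
#' The four horizontal vector fields in the coordinate basis
#' `(dx, dy, dtheta, domega, ds)`:
#' \deqn{X_1 = \cos\theta\,\partial_x + \sin\theta\,\partial_y,\quad
#'       X_2 = \partial_\theta,}
#' \deqn{X_3 = -\sin\theta\,\partial_x + \cos\theta\,\partial_y +
#'       \omega\,\partial_s,\quad X_4 = \partial_\omega.}
#' They span the kernel of the contact form; the spatial parts of
#' `(X1, X3)` form a rotation matrix.
#'
#' @param point A [feature_point()].
#' @return A 4 x 5 matrix, rows `X1..X4`, columns the coordinate basis.
#' @export
horizontal_frame <- function(point) {
  stopifnot(inherits(point, "feature_point"))
  ct <- cos(point$theta); st <- sin(point$theta)
  A <- rbind(
    X1 = c(ct, st, 0, 0, 0),
    X2 = c(0, 0, 1, 0, 0),
    X3 = c(-st, ct, 0, 0, point$omega),
    X4 = c(0, 0, 0, 1, 0))
  colnames(A) <- coord_names
  A
}

# theta- and omega-derivatives of the frame coefficient rows; exact, used by
# the analytic commutator machinery.
frame_theta_derivative <- function(point) {
  ct <- cos(point$theta); st <- sin(point$theta)
  A <- rbind(X1 = c(-st, ct, 0, 0, 0),
             X2 = c(0, 0, 0, 0, 0),
             X3 = c(-ct, -st, 0, 0, 0),
             X4 = c(0, 0, 0, 0, 0))
  colnames(A) <- coord_names
  A
}

frame_omega_derivative <- function(point) {
  A <- rbind(X1 = c(0, 0, 0, 0, 0),
             X2 = c(0, 0, 0, 0, 0),
             X3 = c(0, 0, 0, 0, 1),
             X4 = c(0, 0, 0, 0, 0))
  colnames(A) <- coord_names
  A
}

#' Contact form and its value on a tangent vector
#'
#' `contact_form()` returns the covector of
#' \eqn{\Theta = -\omega\sin\theta\,dx + \omega\cos\theta\,dy - ds};
#' `contact_form_value()` pairs it with a coordinate tangent 5-vector.
#'
#' @param point A [feature_point()].
#' @param tangent Numeric length-5 coordinate vector.
#' @return A length-5 covector, resp. a scalar.
#' @export
contact_form <- function(point) {
  stopifnot(inherits(point, "feature_point"))
  th <- c(-point$omega * sin(point$theta), point$omega * cos(point$theta),
          0, 0, -1)
  names(th) <- coord_names
  th
}

#' @rdname contact_form
#' @export
contact_form_value <- function(point, tangent) {
  stopifnot(length(tangent) == 5)
  sum(contact_form(point) * tangent)
}

#' Commutators of the horizontal frame
#'
#' `commutator_field()` returns the coordinate coefficients of
#' \eqn{[X_i, X_j]} at a point, computed exactly from the frame and its
#' analytic coefficient derivatives. The only nonzero brackets are
#' \eqn{[X_1,X_2] = \sin\theta\,\partial_x - \cos\theta\,\partial_y},
#' \eqn{[X_2,X_3] = -\cos\theta\,\partial_x - \sin\theta\,\partial_y} and
#' \eqn{[X_3,X_4] = -\partial_s}.
#'
#' `commutator_apply()` applies \eqn{[X_i, X_j]} to a twice-differentiable
#' test field (see [test_field()]) via
#' \eqn{X_i(X_j f) - X_j(X_i f)} using the field's analytic gradient and
#' Hessian -- an independent route whose Hessian contributions must cancel.
#'
#' @param i,j Frame indices in `1..4`.
#' @param point A [feature_point()].
#' @return `commutator_field()`: a length-5 coordinate vector.
#' @export
commutator_field <- function(i, j, point) {
  A <- horizontal_frame(point)
  dAt <- frame_theta_derivative(point)
  dAo <- frame_omega_derivative(point)
  out <- (A[i, 3] * dAt[j, ] + A[i, 4] * dAo[j, ]) -
         (A[j, 3] * dAt[i, ] + A[j, 4] * dAo[i, ])
  names(out) <- coord_names
  out
}

#' @rdname commutator_field
#' @param field A [test_field()].
#' @return `commutator_apply()`: the scalar \eqn{[X_i,X_j]f} at the point.
#' @export
commutator_apply <- function(i, j, point, field) {
  stopifnot(inherits(field, "test_field"))
  p <- c(point$q1, point$q2, point$theta, point$omega, point$phi)
  g <- field$grad(p)
  H <- field$hess(p)
  A <- horizontal_frame(point)
  dAt <- frame_theta_derivative(point)
  dAo <- frame_omega_derivative(point)
  second <- function(i, j) {
    # X_i (X_j f) = A_i . [ (d A_j) g ] + A_i^T H A_j
    dAj <- A[i, 3] * dAt[j, ] + A[i, 4] * dAo[j, ]
    sum(dAj * g) + drop(A[i, ] %*% H %*% A[j, ])
  }
  second(i, j) - second(j, i)
}

#' Analytic test fields for differential-geometric checks
#'
#' A `test_field` bundles a smooth scalar function on the 5-manifold with its
#' exact gradient and Hessian, so frame and commutator identities can be
#' verified to floating-point accuracy rather than by finite differences.
#' `test_field_poly()` and `test_field_trig()` supply ready-made fields.
#'
#' @param f,grad,hess Functions of a length-5 coordinate vector
#'   `(x, y, theta, omega, s)` returning a scalar, a length-5 vector and a
#'   5 x 5 matrix respectively.
#' @return An object of class `test_field`.
#' @export
test_field <- function(f, grad, hess) {
  structure(list(f = f, grad = grad, hess = hess), class = "test_field")
}

#' @rdname test_field
#' @export
test_field_poly <- function() {
  test_field(
    f = function(p) p[1]^2 * p[2] + p[2] * p[5] + p[3]^2 * p[5] + p[1] * p[4]^2,
    grad = function(p) c(2 * p[1] * p[2] + p[4]^2,
                         p[1]^2 + p[5],
                         2 * p[3] * p[5],
                         2 * p[1] * p[4],
                         p[2] + p[3]^2),
    hess = function(p) {
      H <- matrix(0, 5, 5)
      H[1, 1] <- 2 * p[2]
      H[1, 2] <- H[2, 1] <- 2 * p[1]
      H[1, 4] <- H[4, 1] <- 2 * p[4]
      H[2, 5] <- H[5, 2] <- 1
      H[3, 3] <- 2 * p[5]
      H[3, 5] <- H[5, 3] <- 2 * p[3]
      H[4, 4] <- 2 * p[1]
      H
    })
}

#' @rdname test_field
#' @export
test_field_trig <- function() {
  test_field(
    f = function(p) sin(p[1] + 2 * p[3]) * cos(p[4]) + p[5]^2 * p[2],
    grad = function(p) c(cos(p[1] + 2 * p[3]) * cos(p[4]),
                         p[5]^2,
                         2 * cos(p[1] + 2 * p[3]) * cos(p[4]),
                         -sin(p[1] + 2 * p[3]) * sin(p[4]),
                         2 * p[5] * p[2]),
    hess = function(p) {
      H <- matrix(0, 5, 5)
      s <- sin(p[1] + 2 * p[3]); cc <- cos(p[1] + 2 * p[3])
      H[1, 1] <- -s * cos(p[4])
      H[1, 3] <- H[3, 1] <- -2 * s * cos(p[4])
      H[1, 4] <- H[4, 1] <- -cc * sin(p[4])
      H[3, 3] <- -4 * s * cos(p[4])
      H[3, 4] <- H[4, 3] <- -2 * cc * sin(p[4])
      H[4, 4] <- -s * cos(p[4])
      H[2, 5] <- H[5, 2] <- 2 * p[5]
      H[5, 5] <- 2 * p[2]
      H
    })
}

#' Bracket-generating (Hoermander) rank at a point
#'
#' Numeric rank of `span(X1, X2, X3, X4, [X1, X2])`; equals 5 everywhere,
#' which guarantees horizontal connectivity of any two feature points
#' (Chow--Rashevskii).
#'
#' @param point A [feature_point()].
#' @return Integer matrix rank.
#' @export
horizontal_rank <- function(point) {
  M <- rbind(horizontal_frame(point), commutator_field(1, 2, point))
  qr(M)$rank
}

# ---- volume form ------------------------------------------------------------

permutations5 <- function() {
  out <- matrix(0L, 120L, 5L)
  r <- 0L
  rec <- function(prefix, rest) {
    if (length(rest) == 0L) {
      r <<- r + 1L
      out[r, ] <<- prefix
      return(invisible())
    }
    for (i in seq_along(rest)) rec(c(prefix, rest[i]), rest[-i])
  }
  rec(integer(0), 1:5)
  out
}

perm_sign <- function(p) {
  s <- 1L
  p <- as.integer(p)
  n <- length(p)
  for (a in 1:(n - 1)) for (b in (a + 1):n) if (p[a] > p[b]) s <- -s
  s
}

#' Volume-form coefficient of the contact structure
#'
#' Numerically evaluates the 5-form \eqn{\Theta \wedge d\Theta \wedge d\Theta}
#' on the coordinate basis `(dx, dy, dtheta, domega, ds)`. The result equals
#' the frequency \eqn{\omega} at every point, so the contact form is
#' maximally nondegenerate.
#'
#' @param point A [feature_point()].
#' @return A scalar (the coefficient of the coordinate volume element).
#' @export
volume_form_coefficient <- function(point) {
  th <- contact_form(point)
  # dTheta = (-sin(theta) domega - omega cos(theta) dtheta) ^ dx
  #        + ( cos(theta) domega - omega sin(theta) dtheta) ^ dy
  ct <- cos(point$theta); st <- sin(point$theta); om <- point$omega
  B <- matrix(0, 5, 5)
  add <- function(a, b, v) {
    B[a, b] <<- B[a, b] + v
    B[b, a] <<- B[b, a] - v
  }
  add(4, 1, -st); add(3, 1, -om * ct)
  add(4, 2, ct); add(3, 2, -om * st)
  perms <- permutations5()
  total <- 0
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    total <- total + perm_sign(p) * th[p[1]] * B[p[2], p[3]] * B[p[4], p[5]]
  }
  # normalization 1/(1! 2! 2!) for the wedge of a 1-form with two 2-forms
  unname(total / 4)
}

# ---- induced metric ---------------------------------------------------------

#' Metric induced by the output responses
#'
#' Given the horizontal gradients \eqn{(X_1 u, \ldots)} and nonnegative
#' weights \eqn{c_i}, builds the per-point metric
#' \eqn{g = I + w w^T} with \eqn{w_i = \sqrt{c_i}\, X_i u}: diagonal entries
#' \eqn{1 + c_i (X_i u)^2}, off-diagonals \eqn{\sqrt{c_i c_j} X_i u X_j u}.
#' The inverse uses the rank-one identity
#' \eqn{(I + w w^T)^{-1} = I - w w^T / (1 + |w|^2)} and the determinant is
#' \eqn{1 + \sum_i c_i (X_i u)^2}; the eigenvalues are exactly
#' `{1, ..., 1, 1 + |w|^2}`.
#'
#' @param gradients Numeric matrix, one row per grid point, columns the
#'   horizontal derivatives `X_i u` (2 for the reduced metric, 4 for the full
#'   one). A bare vector is treated as a single point.
#' @param weights Nonnegative weights `c_i`, one per column.
#' @return An object of class `metric_field`: arrays `g` and `ginv` of shape
#'   `(n, m, m)` and the length-`n` vector `det`.
#' @export
induced_metric <- function(gradients, weights) {
  if (is.null(dim(gradients))) gradients <- matrix(gradients, nrow = 1)
  m <- ncol(gradients)
  if (length(weights) != m) stop("one weight per gradient column required")
  if (any(weights < 0)) stop("metric weights must be nonnegative")
  w <- sweep(gradients, 2, sqrt(weights), `*`)
  n <- nrow(w)
  det <- 1 + rowSums(w^2)
  g <- array(0, dim = c(n, m, m))
  ginv <- array(0, dim = c(n, m, m))
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      ww <- w[, a] * w[, b]
      g[, a, b] <- (a == b) + ww
      ginv[, a, b] <- (a == b) - ww / det
    }
  }
  structure(list(g = g, ginv = ginv, det = det, weights = weights),
            class = "metric_field")
}

#' @export
print.metric_field <- function(x, ...) {
  cat(sprintf("<metric_field %d points, %dx%d, det in [%.4g, %.4g]>\n",
              length(x$det), dim(x$g)[2], dim(x$g)[3],
              min(x$det), max(x$det)))
  invisible(x)
}

# ---- group structure of a frequency layer -----------------------------------

#' Group element of a fixed-frequency layer
#'
#' Each frequency layer of the feature manifold carries a Lie group of rigid
#' motions extended by phase: elements `(q1, q2, theta, phi)` with the layer
#' frequency as context.
#'
#' @param q1,q2 Spatial part.
#' @param theta,phi Angles, reduced mod `2*pi`.
#' @param omega Layer frequency (context only).
#' @return An object of class `group_element`.
#' @export
group_element <- function(q1 = 0, q2 = 0, theta = 0, phi = 0, omega = 1) {
  structure(list(q1 = q1, q2 = q2, theta = wrap_angle(theta),
                 phi = wrap_angle(phi), omega = omega),
            class = "group_element")
}

#' @export
print.group_element <- function(x, ...) {
  cat(sprintf("<group_element q=(%.3g, %.3g) theta=%.4g phi=%.4g | omega=%g>\n",
              x$q1, x$q2, x$theta, x$phi, x$omega))
  invisible(x)
}

rot2 <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)

#' Group multiplication and inverse on a frequency layer
#'
#' The standard rigid-motion law: spatial parts compose through the rotation
#' of the *left* factor, angles add mod `2*pi`. With `as_printed = TRUE` the
#' rotation uses the sum of both angles instead; that variant fails the
#' identity axiom and is retained only for comparison.
#'
#' @param g,h `group_element`s on the same frequency layer.
#' @param as_printed Use the axiom-violating rotation-by-sum variant.
#' @return A `group_element`.
#' @export
group_multiply <- function(g, h, as_printed = FALSE) {
  stopifnot(inherits(g, "group_element"), inherits(h, "group_element"))
  if (!isTRUE(all.equal(g$omega, h$omega)))
    stop("group elements live on different frequency layers")
  ang <- if (as_printed) g$theta + h$theta else g$theta
  q <- c(g$q1, g$q2) + rot2(ang) %*% c(h$q1, h$q2)
  group_element(q[1], q[2], g$theta + h$theta, g$phi + h$phi, g$omega)
}

#' @rdname group_multiply
#' @export
group_inverse <- function(g) {
  stopifnot(inherits(g, "group_element"))
  q <- -rot2(-g$theta) %*% c(g$q1, g$q2)
  group_element(q[1], q[2], -g$theta, -g$phi, g$omega)
}

#' Differential of the left translation
#'
#' The 4 x 4 matrix of the left-translation differential on a frequency
#' layer, evaluated at `(theta, omega)` and returned as printed in the model
#' derivation (zero last column); provided for inspection only.
#'
#' @param g A `group_element`, or a bare orientation angle.
#' @param omega Layer frequency (used when `g` is an angle).
#' @return A 4 x 4 numeric matrix.
#' @export
left_translation_differential <- function(g, omega = NULL) {
  if (inherits(g, "group_element")) {
    theta <- g$theta
    omega <- g$omega
  } else {
    theta <- g
    if (is.null(omega)) stop("`omega` required when `g` is an angle")
  }
  matrix(c(cos(theta), 0, -sin(theta), 0,
           sin(theta), 0, cos(theta), 0,
           0, 1, 0, 0,
           0, 0, omega, 0),
         4, 4, byrow = TRUE)
}
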