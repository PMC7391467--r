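# Gabor receptive profiles and the discrete filter bank.
#
# The receptive profile of a V1 simple cell is modeled as a complex Gabor
# function parameterized by retinal position q = (q1, q2), preferred
# orientation theta, spatial frequency omega (radians/pixel) and phase phi.
# Every profile is a rototranslated, frequency-modulated, phase-shifted copy
# of a single mother profile, which is what ties the filter bank to the
# contact geometry implemented in geometry.R.

wrap_angle <- function(x) x %% (2 * pi)

#' Feature point on the five-dimensional feature manifold
#'
#' A point of the lifted space \eqn{R^2 \times S^1 \times R^+ \times S^1}:
#' spatial position, orientation, spatial frequency and phase. The wave vector
#' \eqn{r = (-\omega\sin\theta, \omega\cos\theta)} is derived on demand and the
#' temporal rate is globally fixed to 1 (the model is static).
#'
#' @param q1,q2 Spatial position in pixels.
#' @param theta Orientation in radians; reduced to `[0, 2*pi)`.
#' @param omega Spatial frequency in radians/pixel; must be positive.
#' @param phi Phase in radians; reduced to `[0, 2*pi)`.
#' @return An object of class `feature_point`.
#' @examples
#' p <- feature_point(0, 0, pi / 2, omega = 2)
#' wave_vector(p) # waves along -x
#' @export
feature_point <- function(q1 = 0, q2 = 0, theta = 0, omega = 1, phi = 0) {
  stopifnot(is.numeric(q1), is.numeric(q2), is.numeric(theta),
            is.numeric(omega), is.numeric(phi))
  if (!is.finite(omega) || omega <= 0)
    stop("`omega` must be a positive finite frequency (radians/pixel)")
  structure(
    list(q1 = as.numeric(q1), q2 = as.numeric(q2),
         theta = wrap_angle(as.numeric(theta)),
         omega = as.numeric(omega),
         phi = wrap_angle(as.numeric(phi))),
    class = "feature_point")
}

#' @rdname feature_point
#' @param point A `feature_point`.
#' @export
wave_vector <- function(point) {
  c(-point$omega * sin(point$theta), point$omega * cos(point$theta))
}

#' @export
print.feature_point <- function(x, ...) {
  cat(sprintf("<feature_point q=(%.3g, %.3g) theta=%.4g omega=%.4g phi=%.4g>\n",
              x$q1, x$q2, x$theta, x$omega, x$phi))
  invisible(x)
}

#' Specification of a Gabor filter bank
#'
#' @param sigma Gaussian scale of the spatial envelope, in pixels.
#' @param trunc_factor Half-width of the sampled spatial support in units of
#'   `sigma`; the window is `(2*trunc_factor*sigma + 1)` pixels on a side.
#'   The default 6 gives a 24-pixel total support at `sigma = 2`.
#' @param K Number of orientation samples, uniform on `[0, 2*pi)`.
#' @param omegas Strictly increasing vector of positive frequencies
#'   (radians/pixel). May be non-uniform.
#' @param M Number of phase samples. Phase enters all downstream computations
#'   as an analytic unit-modulus factor, so `M` only affects quadrature
#'   constants, never storage.
#' @param theta_offset Offset of the orientation grid, radians.
#' @return An object of class `bank_spec`.
#' @export
bank_spec <- function(sigma = 2, trunc_factor = 6, K = 16,
                      omegas = c(seq(0.25, 1, by = 0.25),
                                 seq(1.125, 2.25, by = 0.125)),
                      M = 8, theta_offset = 0) {
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  if (!is.numeric(trunc_factor) || trunc_factor <= 0)
    stop("`trunc_factor` must be > 0")
  if (K < 1 || K != round(K)) stop("`K` must be a positive integer")
  if (M < 1 || M != round(M)) stop("`M` must be a positive integer")
  omegas <- as.numeric(omegas)
  if (length(omegas) > 0) {
    if (any(omegas <= 0)) stop("all frequencies must be positive")
    if (length(omegas) > 1 && any(diff(omegas) <= 0))
      stop("`omegas` must be strictly increasing")
  }
  structure(
    list(sigma = sigma, trunc_factor = trunc_factor, K = as.integer(K),
         omegas = omegas, M = as.integer(M), theta_offset = theta_offset),
    class = "bank_spec")
}

#' @export
print.bank_spec <- function(x, ...) {
  cat(sprintf(
    "<bank_spec sigma=%g trunc=%g K=%d L=%d M=%d window=%dpx>\n",
    x$sigma, x$trunc_factor, x$K, length(x$omegas), x$M,
    2L * as.integer(round(x$trunc_factor * x$sigma)) + 1L))
  invisible(x)
}

#' Mother Gabor profile
#'
#' The reference receptive profile for the frequency-`omega` layer,
#' \eqn{\Psi_0(x, y, s) = e^{-i(\omega y - s)} e^{-(x^2+y^2)/\sigma^2}}.
#' `sigma = 1` recovers the unit-width profile; the experiments use
#' `sigma = 2` pixels.
#'
#' @param x,y Spatial coordinates (pixels), relative to the profile center.
#' @param s Phase coordinate (radians).
#' @param omega Spatial frequency (radians/pixel), positive.
#' @param sigma Gaussian scale (pixels), positive.
#' @return Complex value(s); modulus is at most 1.
#' @examples
#' mother_profile(0, 0, 0, omega = 2)       # 1 + 0i
#' mother_profile(1, 0, 0, omega = 2)       # exp(-1)
#' @export
mother_profile <- function(x, y, s = 0, omega, sigma = 1) {
  if (!is.numeric(omega) || any(omega <= 0)) stop("`omega` must be > 0")
  if (!is.numeric(sigma) || any(sigma <= 0)) stop("`sigma` must be > 0")
  exp(-1i * (omega * y - s)) * exp(-(x^2 + y^2) / sigma^2)
}

#' Generic Gabor receptive profile
#'
#' The profile attached to an arbitrary feature point, obtained from the
#' mother profile by the rigid motion
#' \eqn{A_{(q,\theta,\phi)}(\tilde x,\tilde y,\tilde s) =
#' (q + R_\theta (\tilde x,\tilde y), \phi + \tilde s)}:
#' `gabor_profile(point, x, y, s)` equals the mother profile evaluated at
#' \eqn{A^{-1}(x, y, s)}.
#'
#' @inheritParams mother_profile
#' @param point A [feature_point()].
#' @return Complex value(s).
#' @export
gabor_profile <- function(point, x, y, s = 0, sigma = 1) {
  stopifnot(inherits(point, "feature_point"))
  dx <- x - point$q1
  dy <- y - point$q2
  ct <- cos(point$theta); st <- sin(point$theta)
  xt <- ct * dx + st * dy
  yt <- -st * dx + ct * dy
  mother_profile(xt, yt, s - point$phi, point$omega, sigma)
}

#' Build the discrete Gabor filter bank
#'
#' Samples one complex filter per (orientation, frequency) pair on an
#' integer-pixel window centered at the origin, at phase coordinate `s = 0`.
#' The phase axis is never materialized: the filter at phase `phi` is exactly
#' `exp(-1i * phi)` times the stored one (see [bank_filter()]).
#'
#' @param spec A [bank_spec()].
#' @return An object of class `filter_stack` with the complex filter array
#'   `filters[wx, wy, k, l]`, the orientation/frequency grids, and the window
#'   offsets.
#' @export
build_bank <- function(spec) {
  stopifnot(inherits(spec, "bank_spec"))
  h <- as.integer(round(spec$trunc_factor * spec$sigma))
  offs <- seq(-h, h)
  W <- length(offs)
  K <- spec$K
  L <- length(spec$omegas)
  thetas <- spec$theta_offset + 2 * pi * (seq_len(K) - 1L) / K
  filters <- array(complex(real = 0), dim = c(W, W, K, max(L, 1L)))
  X <- matrix(offs, W, W)        # first index is x
  Y <- matrix(offs, W, W, byrow = TRUE)
  for (k in seq_len(K)) {
    for (l in seq_len(L)) {
      p <- feature_point(0, 0, thetas[k], spec$omegas[l], 0)
      filters[, , k, l] <- gabor_profile(p, X, Y, 0, spec$sigma)
    }
  }
  if (L == 0L) filters <- array(complex(real = 0), dim = c(W, W, K, 0L))
  structure(
    list(filters = filters, thetas = thetas, omegas = spec$omegas,
         sigma = spec$sigma, half_width = h, offsets = offs, spec = spec),
    class = "filter_stack")
}

#' @export
print.filter_stack <- function(x, ...) {
  cat(sprintf("<filter_stack %d orientations x %d frequencies, window %dx%d>\n",
              length(x$thetas), length(x$omegas),
              length(x$offsets), length(x$offsets)))
  invisible(x)
}

#' Extract one filter, materializing a phase value
#'
#' @param bank A `filter_stack`.
#' @param k Orientation index (1-based).
#' @param l Frequency index (1-based).
#' @param phi Phase (radians); applied as the factor `exp(-1i * phi)`.
#' @return A complex matrix.
#' @export
bank_filter <- function(bank, k, l, phi = 0) {
  stopifnot(inherits(bank, "filter_stack"))
  exp(-1i * phi) * bank$filters[, , k, l]
}

# Embed a centered kernel into an nx-by-ny periodic array (center at [1, 1],
# negative offsets wrapped), so that fft() sees it as supported at the origin.
embed_kernel <- function(kernel, nx, ny, offsets) {
  if (nrow(kernel) > nx || ncol(kernel) > ny)
    stop("filter window larger than the target grid")
  out <- matrix(complex(real = 0), nx, ny)
  ix <- (offsets %% nx) + 1L
  iy <- (offsets %% ny) + 1L
  out[ix, iy] <- kernel
  out
}

#' Spectral coverage of a filter bank
#'
#' The Fourier-domain sum of squared filter moduli,
#' \eqn{\sum_{\theta,\omega} |\hat\Psi|^2}, on the discrete Fourier grid of
#' the given shape. Invertibility of the lift requires this Plancherel-type
#' coverage to be bounded away from zero on the spectral band occupied by the
#' image; the phase factor has unit modulus and contributes only counts.
#'
#' @param bank A `filter_stack`.
#' @param shape Integer vector `c(nx, ny)`; must be at least the filter
#'   window size.
#' @return A nonnegative `nx` by `ny` matrix (DC at `[1, 1]`).
#' @export
spectral_coverage <- function(bank, shape) {
  stopifnot(inherits(bank, "filter_stack"), length(shape) == 2)
  nx <- as.integer(shape[1]); ny <- as.integer(shape[2])
  cov <- matrix(0, nx, ny)
  L <- length(bank$omegas)
  for (k in seq_along(bank$thetas)) {
    for (l in seq_len(L)) {
      kc <- embed_kernel(bank$filters[, , k, l], nx, ny, bank$offsets)
      cov <- cov + Mod(stats::fft(kc))^2
    }
  }
  cov
}

# Quadrature weights for the inverse transform: uniform in orientation
# (2*pi/K), trapezoidal on the (possibly non-uniform) frequency grid, and the
# analytic phase integral contributes the constant 2*pi (M samples of a
# unit-modulus factor times the sample spacing 2*pi/M).
channel_weights <- function(bank) {
  K <- length(bank$thetas)
  om <- bank$omegas
  L <- length(om)
  if (L == 0) return(matrix(0, K, 0))
  if (L == 1) {
    wl <- 1
  } else {
    wl <- numeric(L)
    wl[1] <- (om[2] - om[1]) / 2
    wl[L] <- (om[L] - om[L - 1]) / 2
    if (L > 2) wl[2:(L - 1)] <- (om[3:L] - om[1:(L - 2)]) / 2
  }
  outer(rep(2 * pi / K, K), wl * 2 * pi)
}

# Weighted coverage used for Wiener-style normalization in reconstruct():
# sum_c w_c |F_c|^2 with F_c = fft(Conj(psi_c)), matching exactly the
# transfer function product of the forward and adjoint transforms.
coverage_for_reconstruction <- function(bank, nx, ny) {
  w <- channel_weights(bank)
  cov <- matrix(0, nx, ny)
  for (k in seq_along(bank$thetas)) {
    for (l in seq_along(bank$omegas)) {
      kc <- embed_kernel(bank$filters[, , k, l], nx, ny, bank$offsets)
      cov <- cov + w[k, l] * Mod(stats::fft(Conj(kc)))^2
    }
  }
  cov
}

#' Save / load a filter bank
#'
#' The filter arrays go into an RDS container; a JSON sidecar records the
#' generating [bank_spec()] so a saved bank is self-describing.
#'
#' @param bank A `filter_stack`.
#' @param path Output path (`.rds`); the sidecar is `<path>.json`.
#' @return `write_bank()` returns `path` invisibly; `read_bank()` the bank.
#' @export
write_bank <- function(bank, path) {
  stopifnot(inherits(bank, "filter_stack"))
  saveRDS(bank, path)
  meta <- unclass(bank$spec)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bank
#' @export
read_bank <- function(path) {
  bank <- readRDS(path)
  stopifnot(inherits(bank, "filter_stack"))
  bank
}
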