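# Seeded synthetic fixtures: gratings, composites, Gaussian noise, PSNR.
#
# Every stage of the pipeline is testable without external data. Intensities
# are floats in [0, 1]; noise is applied without clipping (the diffusion
# theory is linear), clipping happens only at image export.

#' Oriented sinusoidal grating
#'
#' \eqn{I(x, y) = 0.5 + 0.5\,\mathrm{contrast}\cdot
#' \cos(\omega_0(-x\sin\theta_0 + y\cos\theta_0) + \mathrm{phase})} on
#' 0-based pixel centers, so the spectral peak sits at the wave vector
#' \eqn{(-\omega_0\sin\theta_0, \omega_0\cos\theta_0)}.
#'
#' @param shape Integer `c(nx, ny)`, at least 16 x 16.
#' @param theta0 Grating orientation (radians).
#' @param omega0 Spatial frequency (radians/pixel), below Nyquist (`pi`).
#' @param phase Phase offset (radians).
#' @param contrast Contrast in `(0, 1]`.
#' @return A real image matrix with values in `[0, 1]`.
#' @export
grating <- function(shape, theta0 = 0, omega0 = 0.75, phase = 0,
                    contrast = 1) {
  check_fixture_shape(shape)
  if (omega0 < 0 || omega0 >= pi)
    stop("`omega0` must lie in [0, pi) (below Nyquist)")
  if (contrast <= 0 || contrast > 1) stop("`contrast` must be in (0, 1]")
  x <- matrix(seq_len(shape[1]) - 1L, shape[1], shape[2])
  y <- matrix(seq_len(shape[2]) - 1L, shape[1], shape[2], byrow = TRUE)
  0.5 + 0.5 * contrast *
    cos(omega0 * (-x * sin(theta0) + y * cos(theta0)) + phase)
}

check_fixture_shape <- function(shape) {
  if (length(shape) != 2 || any(shape < 16))
    stop("fixture shape must be two dimensions, each at least 16")
  invisible(shape)
}

#' Composite multi-grating image
#'
#' Superposition of oriented gratings around mid-gray:
#' `0.5 + 0.5 * sum(contrast_i * cos(...))`. The total contrast must not
#' exceed 1, keeping values inside `[0, 1]`.
#'
#' @param shape Integer `c(nx, ny)`.
#' @param components Data frame (or list of vectors) with columns
#'   `theta0, omega0, phase, contrast`.
#' @return A real image matrix in `[0, 1]`.
#' @export
composite_grating <- function(shape, components) {
  check_fixture_shape(shape)
  components <- as.data.frame(components)
  stopifnot(all(c("theta0", "omega0", "contrast") %in% names(components)))
  if (is.null(components$phase)) components$phase <- 0
  if (sum(components$contrast) > 1 + 1e-12)
    stop("total contrast exceeds 1; image would leave [0, 1]")
  x <- matrix(seq_len(shape[1]) - 1L, shape[1], shape[2])
  y <- matrix(seq_len(shape[2]) - 1L, shape[1], shape[2], byrow = TRUE)
  acc <- matrix(0, shape[1], shape[2])
  for (r in seq_len(nrow(components))) {
    cmp <- components[r, ]
    if (cmp$omega0 < 0 || cmp$omega0 >= pi)
      stop("component frequency must lie in [0, pi)")
    acc <- acc + cmp$contrast *
      cos(cmp$omega0 * (-x * sin(cmp$theta0) + y * cos(cmp$theta0)) +
            cmp$phase)
  }
  0.5 + 0.5 * acc
}

#' Additive white Gaussian noise
#'
#' Zero-mean Gaussian noise with standard deviation `sigma_n`, reproducible
#' by `seed`; the output is not clipped.
#'
#' @param image Real image matrix.
#' @param sigma_n Noise standard deviation (intensity units), nonnegative.
#' @param seed Integer seed.
#' @return The noisy image.
#' @export
add_noise <- function(image, sigma_n, seed = 42L) {
  stopifnot(is.matrix(image))
  if (sigma_n < 0) stop("`sigma_n` must be nonnegative")
  if (sigma_n == 0) return(image)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  image + matrix(stats::rnorm(length(image), sd = sigma_n),
                 nrow(image), ncol(image))
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in decibels; identical images give `Inf`.
#'
#' @param a,b Image matrices of identical shape.
#' @param peak Peak intensity (1 for `[0, 1]` images).
#' @return PSNR in dB (symmetric in its two image arguments).
#' @export
psnr <- function(a, b, peak = 1) {
  if (!all(dim(a) == dim(b))) stop("images must have identical shapes")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Fixture presets
#'
#' Deterministic named test scenes:
#' \describe{
#'   \item{`"noisy-gratings-64"`}{The default enhancement fixture: 64 x 64,
#'     two gratings (`theta = 0, omega = 0.75`) and
#'     (`theta = pi/3, omega = 1.5`), contrast 0.5 each, white Gaussian
#'     noise `sigma_n = 0.1`, seed 42.}
#'   \item{`"bandlimited-64"`}{A noise-free 64 x 64 composite of five
#'     on-grid gratings (integer wave vectors, so the scene is exactly
#'     periodic) spanning low to high frequencies and orientations off the
#'     coarse orientation grids; the transform round-trip fixture.}
#' }
#'
#' @param name Fixture name.
#' @return A list with elements `clean`, `noisy` (equal to `clean` when the
#'   fixture is noise-free), and `spec` describing the components.
#' @export
fixture_preset <- function(name = c("noisy-gratings-64", "bandlimited-64")) {
  name <- match.arg(name)
  if (name == "noisy-gratings-64") {
    comp <- data.frame(theta0 = c(0, pi / 3), omega0 = c(0.75, 1.5),
                       phase = 0, contrast = c(0.5, 0.5))
    clean <- composite_grating(c(64, 64), comp)
    noisy <- add_noise(clean, 0.1, seed = 42L)
    spec <- list(shape = c(64, 64), components = comp, sigma_n = 0.1,
                 seed = 42L)
  } else {
    # integer wave vectors (kx, ky) on the 64-periodic grid:
    # r = 2*pi/64 * (kx, ky), theta = atan2(-kx, ky), omega = |r|
    wv <- rbind(c(0, 8), c(-12, 0), c(-6, 6), c(-5, 12), c(-20, 8))
    omega0 <- 2 * pi / 64 * sqrt(rowSums(wv^2))
    theta0 <- atan2(-wv[, 1], wv[, 2])
    comp <- data.frame(theta0 = theta0, omega0 = omega0, phase = 0,
                       contrast = rep(0.18, nrow(wv)))
    clean <- composite_grating(c(64, 64), comp)
    noisy <- clean
    spec <- list(shape = c(64, 64), components = comp, sigma_n = 0,
                 seed = NA_integer_)
  }
  list(clean = clean, noisy = noisy, spec = spec)
}
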