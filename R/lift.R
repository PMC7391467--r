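# Forward Gabor lifting and the exact inverse transform.
#
# The lift correlates the image against every (orientation, frequency) filter
# at phase 0, producing a complex coefficient field on the (x, y, theta,
# omega) grid -- the discrete point of the 5D feature manifold, with the phase
# axis carried analytically as the factor exp(-1i * phi). The inverse
# transform is the adjoint sum with conjugate filters and quadrature weights,
# followed by a Wiener-style Fourier-domain normalization by the bank's
# coverage function, which subsumes the continuum reproducing constant and
# equalizes non-uniform frequency sampling.

pad_reflect <- function(m, h) {
  # mirror about edge pixels, edge not duplicated (period 2n - 2)
  n <- nrow(m); p <- ncol(m)
  ix <- reflect_index(seq(1 - h, n + h), n)
  iy <- reflect_index(seq(1 - h, p + h), p)
  m[ix, iy, drop = FALSE]
}

reflect_index <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n - 2L)
  j <- ifelse(j >= n, 2L * n - 2L - j, j)
  as.integer(j + 1L)
}

periodic_index <- function(i, n) as.integer(((i - 1L) %% n) + 1L)

#' Lift an image to the feature manifold
#'
#' Computes the simple-cell output responses
#' \eqn{O^I[i,j,k,l] = \sum_{\tilde i,\tilde j}
#' \Psi_{[i,j,k,l,0]}[\tilde i,\tilde j, 0]\, I[\tilde i,\tilde j]}
#' for every grid point, one correlation per (orientation, frequency)
#' channel. The forward inner product carries no conjugate; the conjugate
#' belongs to the inverse transform.
#'
#' @param image Real numeric matrix; first index is x (rightward), second y
#'   (downward).
#' @param bank A [build_bank()] filter stack.
#' @param boundary Spatial boundary handling for the correlation:
#'   `"reflect"` (default; avoids wrap-around artifacts) or `"periodic"`
#'   (exact spectral algebra, used by the transform tests).
#' @return An object of class `lifted_image` with complex array
#'   `coef[x, y, k, l]` at phase 0 and the generating grids.
#' @export
lift <- function(image, bank, boundary = c("reflect", "periodic")) {
  boundary <- match.arg(boundary)
  stopifnot(is.matrix(image), is.numeric(image), inherits(bank, "filter_stack"))
  nx <- nrow(image); ny <- ncol(image)
  h <- bank$half_width
  W <- 2L * h + 1L
  if (W > nx || W > ny)
    warning(sprintf("filter window (%d px) larger than image (%d x %d)",
                    W, nx, ny))
  if (boundary == "reflect") {
    Ip <- pad_reflect(image, h)
  } else {
    Ip <- image
  }
  npx <- nrow(Ip); npy <- ncol(Ip)
  Ih <- stats::fft(Ip)
  K <- length(bank$thetas); L <- length(bank$omegas)
  coef <- array(complex(real = 0), dim = c(nx, ny, K, L))
  sel_x <- if (boundary == "reflect") (h + 1L):(h + nx) else seq_len(nx)
  sel_y <- if (boundary == "reflect") (h + 1L):(h + ny) else seq_len(ny)
  np <- npx * npy
  for (k in seq_len(K)) {
    for (l in seq_len(L)) {
      kc <- embed_kernel(bank$filters[, , k, l], npx, npy, bank$offsets)
      G <- Conj(stats::fft(Conj(kc)))
      Oc <- stats::fft(Ih * G, inverse = TRUE) / np
      coef[, , k, l] <- Oc[sel_x, sel_y]
    }
  }
  structure(
    list(coef = coef, thetas = bank$thetas, omegas = bank$omegas,
         spec = bank$spec, boundary = boundary, shape = c(nx, ny)),
    class = "lifted_image")
}

#' @export
print.lifted_image <- function(x, ...) {
  d <- dim(x$coef)
  cat(sprintf("<lifted_image %dx%d spatial, %d orientations, %d frequencies (%s)>\n",
              d[1], d[2], d[3], d[4], x$boundary))
  invisible(x)
}

#' Materialize the analytic phase axis
#'
#' In the phase-0 lifting, the coefficient at phase `phi` is exactly
#' `exp(-1i * phi)` times the stored coefficient; the modulus is
#' phase-invariant.
#'
#' @param lifted A `lifted_image`.
#' @param phi Phase (radians).
#' @return The complex 4D coefficient array at that phase.
#' @export
materialize_phase <- function(lifted, phi) {
  stopifnot(inherits(lifted, "lifted_image"))
  exp(-1i * phi) * lifted$coef
}

#' Inverse Gabor transform
#'
#' Discrete realization of the exact inverse transform: the adjoint sum over
#' all channels with conjugate filters, quadrature weights over orientation
#' (uniform), frequency (trapezoidal on the non-uniform grid) and phase
#' (analytic), then division in the Fourier domain by the bank's weighted
#' coverage, floored at `coverage_floor * max(coverage)`.
#'
#' @param lifted A `lifted_image`.
#' @param bank The `filter_stack` that produced it.
#' @param coverage_floor Relative Wiener floor; spectral bins whose coverage
#'   falls below it cannot be recovered and trigger a warning reporting the
#'   uncovered fraction of the Fourier grid.
#' @return A real image matrix with the lifted spatial shape.
#' @export
reconstruct <- function(lifted, bank, coverage_floor = 1e-3) {
  stopifnot(inherits(lifted, "lifted_image"), inherits(bank, "filter_stack"))
  nx <- lifted$shape[1]; ny <- lifted$shape[2]
  h <- bank$half_width
  pad <- lifted$boundary == "reflect"
  npx <- if (pad) nx + 2L * h else nx
  npy <- if (pad) ny + 2L * h else ny
  w <- channel_weights(bank)
  K <- length(bank$thetas); L <- length(bank$omegas)
  num <- matrix(complex(real = 0), npx, npy)
  cov <- matrix(0, npx, npy)
  for (k in seq_len(K)) {
    for (l in seq_len(L)) {
      kc <- embed_kernel(bank$filters[, , k, l], npx, npy, bank$offsets)
      Fc <- stats::fft(Conj(kc))
      Oc <- lifted$coef[, , k, l]
      if (pad) {
        Ocp <- pad_reflect(Re(Oc), h) + 1i * pad_reflect(Im(Oc), h)
      } else {
        Ocp <- Oc
      }
      num <- num + w[k, l] * stats::fft(Ocp) * Fc
      cov <- cov + w[k, l] * Mod(Fc)^2
    }
  }
  eps <- coverage_floor * max(cov)
  uncovered <- mean(cov < eps)
  if (uncovered > 0)
    warning(sprintf("spectral coverage below floor on %.1f%% of the Fourier grid",
                    100 * uncovered))
  Ih <- num / pmax(cov, eps)
  Ip <- Re(stats::fft(Ih, inverse = TRUE)) / (npx * npy)
  if (pad) Ip[(h + 1L):(h + nx), (h + 1L):(h + ny)] else Ip
}

#' Round-trip reconstruction error
#'
#' Relative L2 distance between an image and `reconstruct(lift(image))`.
#' A diagnostic for sampling quality: the error grows as the spectral
#' coverage of the bank develops holes (e.g. too few orientation samples).
#'
#' @inheritParams lift
#' @param coverage_floor Passed to [reconstruct()].
#' @return A nonnegative scalar; 0 only for perfect recovery.
#' @export
roundtrip_error <- function(image, bank, boundary = c("reflect", "periodic"),
                            coverage_floor = 1e-3) {
  boundary <- match.arg(boundary)
  rec <- reconstruct(lift(image, bank, boundary), bank,
                     coverage_floor = coverage_floor)
  nimg <- sqrt(sum(image^2))
  nerr <- sqrt(sum((rec - image)^2))
  if (nimg == 0) nerr else nerr / nimg
}

#' Save / load lifted coefficients
#'
#' RDS container for the complex coefficient array plus a JSON sidecar with
#' the grids and generating spec.
#'
#' @param lifted A `lifted_image`.
#' @param path Output path (`.rds`).
#' @return `write_lifted()` returns `path` invisibly; `read_lifted()` the
#'   object.
#' @export
write_lifted <- function(lifted, path) {
  stopifnot(inherits(lifted, "lifted_image"))
  saveRDS(lifted, path)
  meta <- list(shape = lifted$shape, thetas = lifted$thetas,
               omegas = lifted$omegas, boundary = lifted$boundary,
               spec = unclass(lifted$spec))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lifted
#' @export
read_lifted <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "lifted_image"))
  x
}
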