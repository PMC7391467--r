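# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force (loops, direct sums, dense linear algebra) so
# they share no code path with the production implementations they check.

rel_l2 <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))

# Direct-sum lift oracle: O(q) = sum_Delta psi(Delta) I(q + Delta) with
# explicit boundary index folding.
oracle_lift_value <- function(image, bank, i, j, k, l, boundary) {
  h <- bank$half_width
  nx <- nrow(image); ny <- ncol(image)
  fold <- function(idx, n) {
    if (boundary == "periodic") ((idx - 1) %% n) + 1
    else {
      jj <- (idx - 1) %% (2 * n - 2)
      ifelse(jj >= n, 2 * n - 2 - jj, jj) + 1
    }
  }
  acc <- 0 + 0i
  for (u in -h:h) {
    for (v in -h:h) {
      acc <- acc + bank$filters[u + h + 1, v + h + 1, k, l] *
        image[fold(i + u, nx), fold(j + v, ny)]
    }
  }
  acc
}

# Bilinear periodic sampler for the dense Laplace-Beltrami oracle.
oracle_sample <- function(arr, k, x, y) {
  nx <- dim(arr)[1]; ny <- dim(arr)[2]
  pidx <- function(i, n) ((i - 1) %% n) + 1
  x0 <- floor(x); y0 <- floor(y); fx <- x - x0; fy <- y - y0
  (1 - fx) * (1 - fy) * arr[pidx(x0, nx), pidx(y0, ny), k] +
    fx * (1 - fy) * arr[pidx(x0 + 1, nx), pidx(y0, ny), k] +
    (1 - fx) * fy * arr[pidx(x0, nx), pidx(y0 + 1, ny), k] +
    fx * fy * arr[pidx(x0 + 1, nx), pidx(y0 + 1, ny), k]
}

# Naive dense assembly of the divergence-form operator on a periodic grid
# with bilinear interpolation: per-point 2x2 matrix inversion via solve(),
# explicit loops everywhere.
oracle_laplace_beltrami <- function(u, thetas, c1, c2) {
  nx <- dim(u)[1]; ny <- dim(u)[2]; K <- dim(u)[3]
  dth <- 2 * pi / K
  pidx <- function(i, n) ((i - 1) %% n) + 1
  X1 <- array(0, dim(u)); X2 <- array(0, dim(u))
  for (k in 1:K) for (i in 1:nx) for (j in 1:ny) {
    dx <- cos(thetas[k]); dy <- sin(thetas[k])
    X1[i, j, k] <- (oracle_sample(u, k, i + dx, j + dy) -
                      oracle_sample(u, k, i - dx, j - dy)) / 2
    X2[i, j, k] <- (u[i, j, pidx(k + 1, K)] - u[i, j, pidx(k - 1, K)]) /
      (2 * dth)
  }
  Y1 <- sqrt(c1) * X1; Y2 <- sqrt(c2) * X2
  F1 <- array(0, dim(u)); F2 <- array(0, dim(u)); Lu <- array(0, dim(u))
  for (k in 1:K) for (i in 1:nx) for (j in 1:ny) {
    w <- c(Y1[i, j, k], Y2[i, j, k])
    g <- diag(2) + w %*% t(w)
    Fv <- sqrt(det(g)) * solve(g) %*% w
    F1[i, j, k] <- Fv[1]; F2[i, j, k] <- Fv[2]
  }
  for (k in 1:K) for (i in 1:nx) for (j in 1:ny) {
    dx <- cos(thetas[k]); dy <- sin(thetas[k])
    dF1 <- (oracle_sample(F1, k, i + dx, j + dy) -
              oracle_sample(F1, k, i - dx, j - dy)) / 2
    dF2 <- (F2[i, j, pidx(k + 1, K)] - F2[i, j, pidx(k - 1, K)]) / (2 * dth)
    w <- c(Y1[i, j, k], Y2[i, j, k])
    Lu[i, j, k] <- (sqrt(c1) * dF1 + sqrt(c2) * dF2) / sqrt(1 + sum(w^2))
  }
  Lu
}

# Circumradius of three planar points.
circumradius <- function(p1, p2, p3) {
  a <- sqrt(sum((p1 - p2)^2)); b <- sqrt(sum((p2 - p3)^2))
  cc <- sqrt(sum((p1 - p3)^2))
  a * b * cc / sqrt((a + b + cc) * (-a + b + cc) * (a - b + cc) * (a + b - cc))
}

random_feature_point <- function() {
  feature_point(stats::runif(1, -5, 5), stats::runif(1, -5, 5),
                stats::runif(1, 0, 2 * pi), stats::runif(1, 0.1, 4),
                stats::runif(1, 0, 2 * pi))
}

small_bank <- function() {
  build_bank(bank_spec(sigma = 1, trunc_factor = 2, K = 4,
                       omegas = c(0.5, 1.2), M = 4))
}
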