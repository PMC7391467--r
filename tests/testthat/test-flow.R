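test_that("the stability bound evaluates the printed expression", {
  expect_equal(round(max_timestep(16, 1, 0.0625), 2), 0.87)
  # decreasing in K at fixed ratio
  expect_lt(max_timestep(32, 1, 1 / 16), max_timestep(16, 1, 1 / 16))
  # algebraic simplification 2 s sqrt(r) / (sqrt(2) + 2 s sqrt(r)) for s^2 r < 1
  K <- 64; r <- 2
  s <- 2 * pi / K
  expect_equal(max_timestep(K, r, 1),
               2 * s * sqrt(r) / (sqrt(2) + 2 * s * sqrt(r)),
               tolerance = 1e-12)
  # the operational step 0.1 is admissible for the experiment protocols
  expect_lt(0.1, max_timestep(16, 1, (16 / 64)^2))
  expect_lt(0.1, max_timestep(16, 1, (16 / 256)^2))
  expect_error(max_timestep(16, 0, 1), "c1")
})

test_that("horizontal derivatives vanish on constants and are exact on affine fields", {
  K <- 8
  thetas <- 2 * pi * (0:(K - 1)) / K
  u0 <- array(2.7, c(12, 12, K))
  for (ord in 1:2) {
    d <- horizontal_derivatives(u0, thetas, order = ord, interp_order = 1,
                                boundary = "periodic")
    expect_equal(max(abs(d[[1]])), 0)
    expect_equal(max(abs(d[[2]])), 0)
  }
  # u = x: X1 u = cos(theta_k) exactly (linear interpolation exact on affine)
  nx <- 16
  u <- array(rep(matrix(0:(nx - 1), nx, nx), K), c(nx, nx, K))
  d1 <- horizontal_derivatives(u, thetas, order = 1, interp_order = 1,
                               boundary = "periodic")
  for (k in 1:K) {
    expect_equal(d1$X1[4:13, 4:13, k],
                 matrix(cos(thetas[k]), 10, 10), tolerance = 1e-12)
  }
  expect_error(horizontal_derivatives(u, thetas, interp_order = 2), "order")
})

test_that("the angular second difference converges at second order", {
  errs <- sapply(c(8, 16, 32), function(K) {
    thetas <- 2 * pi * (0:(K - 1)) / K
    u <- array(0, c(4, 4, K))
    for (k in 1:K) u[, , k] <- sin(thetas[k])
    d2 <- horizontal_derivatives(u, thetas, order = 2, interp_order = 1,
                                 boundary = "periodic")
    max(abs(d2$X22[1, 1, ] + sin(thetas)))
  })
  # halving the angular step divides the error by ~4
  expect_gt(errs[1] / errs[2], 3.5)
  expect_gt(errs[2] / errs[3], 3.5)
})

test_that("the horizontal Laplacian matches analytic second derivatives", {
  K <- 8
  thetas <- 2 * pi * (0:(K - 1)) / K
  nx <- 20
  u <- array(rep(matrix((0:(nx - 1))^2, nx, nx), K), c(nx, nx, K))
  d2 <- horizontal_derivatives(u, thetas, order = 2, interp_order = 3,
                               boundary = "reflect")
  for (k in 1:K) {
    expect_equal(d2$X11[8:13, 8:13, k],
                 matrix(2 * cos(thetas[k])^2, 6, 6), tolerance = 1e-2)
  }
  L <- sub_riemannian_laplacian(u, thetas, c(1, 0.25), interp_order = 3,
                                boundary = "reflect")
  expect_equal(L[8:13, 8:13, 1], d2$X11[8:13, 8:13, 1], tolerance = 1e-12)
  expect_equal(max(abs(sub_riemannian_laplacian(
    array(1, c(8, 8, 4)), 2 * pi * (0:3) / 4, c(1, 1)))), 0)
})

test_that("laplace_beltrami matches the naive dense assembly", {
  set.seed(51)
  u <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  thetas <- 2 * pi * (0:3) / 4
  cfg <- flow_config(c1 = 1, c2 = 0.25, interp_order = 1,
                     boundary = "periodic")
  cfg$c2 <- 0.25
  expect_equal(laplace_beltrami(u, thetas, cfg),
               oracle_laplace_beltrami(u, thetas, 1, 0.25),
               tolerance = 1e-10)
  # constant fields are exact fixed points
  expect_equal(max(abs(laplace_beltrami(array(3.3, c(8, 8, 4)), thetas, cfg))),
               0)
})

test_that("the small-amplitude limit reduces to the horizontal Laplacian", {
  # quadratic spatial field, orientation-constant: both stencil realizations
  # are exact in the deep interior, so the limit is sharp there
  nx <- 48; K <- 8
  thetas <- 2 * pi * (0:(K - 1)) / K
  X <- matrix(0:(nx - 1), nx, nx); Y <- matrix(0:(nx - 1), nx, nx, byrow = TRUE)
  u <- array(rep(0.5 * X^2 - 0.3 * X * Y + 0.2 * Y^2, K), c(nx, nx, K))
  cfg <- flow_config(c1 = 1, c2 = 0.0625, interp_order = 3)
  cfg$c2 <- 0.0625
  eps <- 1e-6
  Leps <- laplace_beltrami(eps * u, thetas, cfg) / eps
  D0 <- sub_riemannian_laplacian(u, thetas, c(1, 0.0625), 3, "reflect")
  int <- 17:32
  expect_lt(max(abs((Leps - D0)[int, int, ])) / max(abs(D0[int, int, ])),
            1e-4)
})

test_that("the Euler step updates by dt and reports divergence", {
  K <- 4
  thetas <- 2 * pi * (0:(K - 1)) / K
  cfg <- flow_config(c1 = 1, c2 = 0.25, dt = 0.1, iterations = 1,
                     interp_order = 1, boundary = "periodic",
                     metric_source = "identity")
  # a field with L u == 0 is unchanged
  st <- flow_state(array(1.5, c(8, 8, K)), thetas, cfg)
  st1 <- flow_step(st)
  expect_equal(st1$u, st$u)
  expect_equal(st1$iteration, 1L)
  expect_equal(st1$time, 0.1)
  # divergence raises an error naming the iteration
  bad <- flow_state(array(0, c(8, 8, K)), thetas, cfg)
  bad$u[1, 1, 1] <- Inf
  expect_error(flow_step(bad), "iteration 1")
  # a time step beyond the bound is rejected up front
  # K = 4, c1/c2 = 0.01 gives a bound of ~0.18, so dt = 0.5 must be rejected
  expect_error(flow_state(array(0, c(8, 8, K)), thetas,
                          flow_config(c1 = 1, c2 = 100, dt = 0.5)),
               "stability")
})

test_that("the frozen-coefficient scheme obeys the discrete maximum principle", {
  K <- 16
  thetas <- 2 * pi * (0:(K - 1)) / K
  set.seed(52)
  u <- array(rnorm(16 * 16 * K), c(16, 16, K))
  dt <- 0.3 * max_timestep(K, 1, 0.0625)
  st <- flow_state(u, thetas,
                   flow_config(c1 = 1, c2 = 0.0625, dt = dt, iterations = 50,
                               interp_order = 1, metric_source = "identity"))
  m0 <- max(abs(st$u))
  for (i in 1:50) st <- flow_step(st)
  expect_lte(max(abs(st$u)), m0 + 1e-9)
})

test_that("energy decays along the Laplace-Beltrami flow", {
  K <- 16
  thetas <- 2 * pi * (0:(K - 1)) / K
  set.seed(53)
  u <- array(rnorm(16 * 16 * K), c(16, 16, K))
  st <- flow_state(u, thetas,
                   flow_config(c1 = 1, c2 = 0.0625, dt = 0.1,
                               iterations = 15))
  e <- sum(st$u^2)
  for (i in 1:15) {
    st <- flow_step(st)
    e_next <- sum(st$u^2)
    expect_lte(e_next, e * (1 + 1e-6))
    e <- e_next
  }
})

test_that("flow configuration validates its fields", {
  expect_error(flow_config(c1 = -1), "nonnegative")
  expect_error(flow_config(dt = 0), "dt")
  expect_error(flow_config(iterations = -2), "iterations")
  expect_error(flow_config(interp_order = 2), "order")
  expect_error(flow_config(metric_period = 0), "metric_period")
})
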