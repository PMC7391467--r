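test_that("curve velocity has the printed components", {
  p0 <- feature_point(0, 0, 0, 1, 0)
  expect_equal(curve_velocity(p0, curve_coefficients(c1 = 1)),
               c(1, 0, 0, 0, 0))
  # phase rate is c3 * omega
  p <- feature_point(0, 0, 0.4, 2.3, 0)
  v <- curve_velocity(p, curve_coefficients(c3 = 1))
  expect_equal(v[5], 2.3)
  expect_equal(curve_velocity(p, curve_coefficients()), rep(0, 5))
  expect_error(curve_coefficients(c1 = Inf), "finite")
})

test_that("closed form solves the system: endpoints and the RK4 oracle agree", {
  set.seed(41)
  tt <- seq(0, 1, length.out = 11)
  for (r in 1:100) {
    init <- feature_point(rnorm(1), rnorm(1), runif(1, 0, 2 * pi),
                          runif(1, 0.5, 3), runif(1, 0, 2 * pi))
    cf <- curve_coefficients(rnorm(1), rnorm(1), rnorm(1), 0.3 * rnorm(1))
    a <- suppressWarnings(closed_form_curve(init, cf, tt))
    expect_equal(as.numeric(a$samples[1, -1]),
                 c(init$q1, init$q2, init$theta, init$omega, init$phi))
    if (nrow(a$samples) == length(tt)) {
      expect_equal(a$samples$theta[11], cf$c2 + init$theta, tolerance = 1e-12)
      expect_equal(a$samples$omega[11], cf$c4 + init$omega, tolerance = 1e-12)
    }
    b <- suppressWarnings(numeric_curve(init, cf, tt, step = 1e-3))
    n <- min(nrow(a$samples), nrow(b$samples))
    expect_lt(max(abs(as.matrix(a$samples[1:n, -1]) -
                        as.matrix(b$samples[1:n, -1]))), 1e-6)
  }
})

test_that("the two solution branches agree across the switch", {
  init <- feature_point(0, 0, 0.5, 1, 0)
  a <- closed_form_curve(init, curve_coefficients(1, 1e-8, 0.7, 0.2),
                         seq(0, 1, 0.1))
  b <- closed_form_curve(init, curve_coefficients(1, 0, 0.7, 0.2),
                         seq(0, 1, 0.1))
  expect_lt(max(abs(as.matrix(a$samples) - as.matrix(b$samples))), 1e-5)
  # straight branch keeps the orientation constant
  expect_equal(unique(b$samples$theta), 0.5)
})

test_that("the numeric integrator converges at fourth order", {
  init <- feature_point(0, 0, 0.3, 1, 0)
  cf <- curve_coefficients(1, 2, 0.5, 0.1)
  ref <- as.numeric(closed_form_curve(init, cf, c(0, 1))$samples[2, -1])
  e <- sapply(c(0.1, 0.05), function(h) {
    max(abs(as.numeric(numeric_curve(init, cf, c(0, 1),
                                     step = h)$samples[2, -1]) - ref))
  })
  expect_gt(e[1] / e[2], 12)
  expect_lt(e[1] / e[2], 20)
  # zero coefficients give a constant curve
  cv <- numeric_curve(init, curve_coefficients(), c(0, 0.5, 1))
  expect_equal(cv$samples$q1, rep(0, 3))
  expect_equal(cv$samples$omega, rep(1, 3))
})

test_that("turning curves trace circular arcs of radius |c1/c2|", {
  for (pars in list(c(2, 0.5), c(1, -0.25), c(0.7, 1.3))) {
    cv <- closed_form_curve(feature_point(0, 0, 0.3, 1, 0),
                            curve_coefficients(c1 = pars[1], c2 = pars[2]),
                            seq(0, 2, 0.01))
    s <- cv$samples
    idx <- c(1, 80, 180)
    r <- circumradius(c(s$q1[idx[1]], s$q2[idx[1]]),
                      c(s$q1[idx[2]], s$q2[idx[2]]),
                      c(s$q1[idx[3]], s$q2[idx[3]]))
    expect_equal(r, abs(pars[1] / pars[2]), tolerance = 1e-8)
  }
})

test_that("curves are horizontal: the contact form annihilates their velocity", {
  set.seed(42)
  for (r in 1:25) {
    init <- feature_point(rnorm(1), rnorm(1), runif(1, 0, 2 * pi),
                          runif(1, 0.5, 3), 0)
    cf <- curve_coefficients(rnorm(1), rnorm(1), rnorm(1), 0.1)
    cv <- suppressWarnings(closed_form_curve(init, cf, seq(0, 1, 0.05)))
    s <- cv$samples
    for (n in seq_len(nrow(s))) {
      p <- feature_point(s$q1[n], s$q2[n], s$theta[n], s$omega[n], 0)
      v <- curve_velocity(p, cf)
      # -omega sin(theta) q1' + omega cos(theta) q2' - phi' = 0
      res <- -s$omega[n] * sin(s$theta[n]) * v[1] +
        s$omega[n] * cos(s$theta[n]) * v[2] - v[5]
      expect_lt(abs(res), 1e-8)
    }
  }
})

test_that("curves truncate at the positive-frequency boundary", {
  init <- feature_point(0, 0, 0, 0.5, 0)
  cf <- curve_coefficients(c1 = 1, c4 = -1)
  expect_warning(cv <- closed_form_curve(init, cf, seq(0, 1, 0.1)), "omega")
  expect_true(all(cv$samples$omega > 0))
  expect_lt(max(cv$samples$t), 0.5)
})

test_that("curve fans reproduce the association-field geometries", {
  fan1 <- curve_fan(feature_point(0, 0, 0, 1, 0), curve_coefficients(c1 = 1),
                    "c2", c(-0.5, 0.5))
  expect_length(fan1, 2)
  s1 <- fan1[[1]]$samples; s2 <- fan1[[2]]$samples
  # mirror images across the x-axis: q1 even, q2 odd in c2
  expect_equal(s1$q1, s2$q1, tolerance = 1e-12)
  expect_equal(s1$q2, -s2$q2, tolerance = 1e-12)
  # frequency fan keeps theta constant on every curve
  fan2 <- suppressWarnings(curve_fan(feature_point(0, 0, 0.7, 2, 0),
                                     curve_coefficients(c3 = 1), "c4",
                                     c(-0.5, 0, 0.5, 1)))
  for (cv in fan2) expect_equal(unique(cv$samples$theta), 0.7)
  fan3 <- curve_fan(feature_point(0, 0, 0, 1, 0), curve_coefficients(c1 = 1),
                    "c2", 0.3)
  expect_length(fan3, 1)
})

test_that("curves export as CSV with the canonical columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  cv <- closed_form_curve(feature_point(0, 0, 0, 1, 0),
                          curve_coefficients(c1 = 1, c2 = 0.5),
                          seq(0, 1, 0.25))
  write_curves_csv(cv, path)
  df <- utils::read.csv(path)
  expect_named(df, c("t", "q1", "q2", "theta", "omega", "phi"))
  expect_equal(nrow(df), 5)
  fan <- curve_fan(feature_point(0, 0, 0, 1, 0), curve_coefficients(c1 = 1),
                   "c2", c(-1, 1))
  write_curves_csv(fan, path)
  df2 <- utils::read.csv(path)
  expect_named(df2, c("curve", "t", "q1", "q2", "theta", "omega", "phi"))
})
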