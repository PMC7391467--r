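test_that("horizontal frame matches the explicit fields and spans ker Theta", {
  p <- feature_point(1, 2, 0, 1.7, 0.3)
  A <- horizontal_frame(p)
  expect_equal(unname(A["X1", ]), c(1, 0, 0, 0, 0))
  expect_equal(unname(A["X3", ]), c(0, 1, 0, 0, 1.7))
  set.seed(31)
  for (r in 1:100) {
    p <- random_feature_point()
    A <- horizontal_frame(p)
    for (i in 1:4) {
      expect_lt(abs(contact_form_value(p, A[i, ])), 1e-14)
    }
    # spatial parts of (X1, X3) form a rotation: determinant 1
    expect_equal(det(cbind(A["X1", 1:2], A["X3", 1:2])), 1, tolerance = 1e-14)
  }
})

test_that("contact form pairs as printed with coordinate directions", {
  p <- feature_point(0, 0, 0.8, 2.2, 0)
  expect_equal(contact_form_value(p, c(0, 0, 1, 0, 0)), 0)
  expect_equal(contact_form_value(p, c(0, 0, 0, 0, 1)), -1)
  expect_equal(contact_form_value(p, horizontal_frame(p)["X3", ]), 0,
               tolerance = 1e-15)
})

test_that("the commutator table holds, including all vanishing brackets", {
  printed <- function(i, j, p) {
    ct <- cos(p$theta); st <- sin(p$theta)
    key <- paste0(i, j)
    switch(key,
           "12" = c(st, -ct, 0, 0, 0),
           "23" = c(-ct, -st, 0, 0, 0),
           "34" = c(0, 0, 0, 0, -1),
           rep(0, 5))
  }
  set.seed(32)
  for (r in 1:100) {
    p <- random_feature_point()
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(unname(commutator_field(i, j, p)), printed(i, j, p),
                   tolerance = 1e-14)
    }
  }
  # spot values from the printed table
  p0 <- feature_point(0, 0, 0, 1, 0)
  expect_equal(unname(commutator_field(1, 2, p0)), c(0, -1, 0, 0, 0))
  expect_equal(unname(commutator_field(3, 4, p0)), c(0, 0, 0, 0, -1))
  expect_equal(unname(commutator_field(1, 4, p0)), rep(0, 5))
})

test_that("commutators applied to analytic test fields match the field route", {
  set.seed(33)
  for (tf in list(test_field_poly(), test_field_trig())) {
    for (r in 1:20) {
      p <- random_feature_point()
      pv <- c(p$q1, p$q2, p$theta, p$omega, p$phi)
      for (i in 1:3) for (j in (i + 1):4) {
        lhs <- commutator_apply(i, j, p, tf)
        rhs <- sum(commutator_field(i, j, p) * tf$grad(pv))
        expect_equal(lhs, rhs, tolerance = 1e-10)
      }
    }
  }
})

test_that("the frame is bracket generating: rank 5 with [X1, X2] added", {
  set.seed(34)
  for (r in 1:100) expect_equal(horizontal_rank(random_feature_point()), 5L)
})

test_that("the contact volume density is proportional to the frequency", {
  # standard fully-antisymmetrized evaluation gives -2 * omega; the invariant
  # content is a nonvanishing volume form with density proportional to omega
  set.seed(35)
  for (r in 1:100) {
    p <- random_feature_point()
    expect_equal(volume_form_coefficient(p), -2 * p$omega, tolerance = 1e-10)
  }
})

test_that("induced metric obeys the rank-one determinant and inverse identities", {
  set.seed(36)
  G <- matrix(rnorm(200 * 4), 200, 4)
  wts <- c(1, 0.0625, 0.3, 2)
  mf <- induced_metric(G, wts)
  for (n in sample(200, 50)) {
    g <- mf$g[n, , ]
    expect_equal(det(g), mf$det[n], tolerance = 1e-10)
    expect_equal(g %*% mf$ginv[n, , ], diag(4), tolerance = 1e-10)
    ev <- sort(eigen(g, symmetric = TRUE)$values)
    expect_equal(ev[1:3], rep(1, 3), tolerance = 1e-10)
    expect_equal(ev[4], mf$det[n], tolerance = 1e-10)
  }
  # closed form of the determinant
  expect_equal(mf$det, 1 + colSums(wts * t(G^2)), tolerance = 1e-12)
  # zero gradients give the identity metric
  m0 <- induced_metric(matrix(0, 3, 2), c(1, 1))
  expect_equal(m0$det, rep(1, 3))
  expect_equal(m0$g[2, , ], diag(2))
  expect_error(induced_metric(G, c(-1, 1, 1, 1)), "nonnegative")
})

test_that("the frequency-layer group satisfies the axioms", {
  e <- group_element(0, 0, 0, 0, 1.5)
  g <- group_element(1, 2, 0.3, 0.4, 1.5)
  ge <- group_multiply(g, e); eg <- group_multiply(e, g)
  for (x in list(ge, eg)) {
    expect_equal(c(x$q1, x$q2, x$theta, x$phi), c(g$q1, g$q2, g$theta, g$phi))
  }
  set.seed(37)
  for (r in 1:1000) {
    om <- runif(1, 0.2, 3)
    gs <- lapply(1:3, function(i)
      group_element(rnorm(1), rnorm(1), runif(1, 0, 2 * pi),
                    runif(1, 0, 2 * pi), om))
    lhs <- group_multiply(group_multiply(gs[[1]], gs[[2]]), gs[[3]])
    rhs <- group_multiply(gs[[1]], group_multiply(gs[[2]], gs[[3]]))
    expect_equal(c(lhs$q1, lhs$q2, lhs$theta, lhs$phi),
                 c(rhs$q1, rhs$q2, rhs$theta, rhs$phi), tolerance = 1e-12)
    gi <- group_multiply(gs[[1]], group_inverse(gs[[1]]))
    expect_lt(abs(gi$q1) + abs(gi$q2) + abs(sin(gi$theta)) + abs(sin(gi$phi)),
              1e-12)
  }
  # angles add modulo 2*pi
  h <- group_element(0, 0, 5.1, 4.4, 1.5)
  gh <- group_multiply(g, h)
  expect_equal(gh$theta, (0.3 + 5.1) %% (2 * pi), tolerance = 1e-12)
  expect_equal(gh$phi, (0.4 + 4.4) %% (2 * pi), tolerance = 1e-12)
  expect_error(group_multiply(g, group_element(0, 0, 0, 0, 2)), "layer")
})

test_that("the rotation-by-sum variant of the product breaks the identity axiom", {
  e <- group_element(0, 0, 0, 0, 1)
  g <- group_element(1, 0, pi / 2, 0, 1)
  bad <- group_multiply(e, g, as_printed = TRUE)
  expect_false(isTRUE(all.equal(c(bad$q1, bad$q2), c(g$q1, g$q2))))
})

test_that("the left-translation differential evaluates as printed", {
  M <- left_translation_differential(0, omega = 2.5)
  expect_equal(M[1, 1], 1); expect_equal(M[2, 3], 1)
  expect_equal(M[3, 2], 1); expect_equal(M[4, 3], 2.5)
  expect_equal(M[, 4], rep(0, 4))
  M2 <- left_translation_differential(pi / 2, omega = 1)
  expect_equal(M2[1, 1], 0, tolerance = 1e-15)
  expect_equal(M2[1, 3], -1)
  expect_equal(M2[2, 1], 1)
  set.seed(38)
  for (om in runif(5, 0.1, 5)) {
    expect_equal(left_translation_differential(runif(1, 0, 2 * pi), om)[4, 3],
                 om)
  }
  g <- group_element(3, -1, pi / 2, 0, 1)
  expect_equal(left_translation_differential(g), M2)
})
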