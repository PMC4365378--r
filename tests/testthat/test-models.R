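test_that("mr_extension evaluates the nonlinear spring extension", {
  # vanishes at the reference configuration for any constants
  expect_equal(mr_extension(1, C1 = 3.2, C2 = -7), 0)
  expect_equal(mr_extension(2, C1 = 1, C2 = 0), 3.5)
  expect_equal(mr_extension(0.8, C1 = -5.61, C2 = 4.4), 0.0671,
               tolerance = 1e-12)
  # Neo-Hookean reduction: C2 = 0 gives C1 * (lam^2 - 1/lam)
  lam <- seq(0.5, 1.5, 0.1)
  expect_equal(mr_extension(lam, 2.5, 0), 2.5 * (lam^2 - 1 / lam))
  expect_error(mr_extension(-1, 1, 1), "positive")
})

test_that("polynomial_input is a cubic with no constant term", {
  expect_identical(polynomial_input(0, 5, 4, 3), 0)
  expect_equal(polynomial_input(0.3, 0, 0, 1), 0.3)
  expect_equal(polynomial_input(0.2, 10.8, -1.1, 0), 0.0424,
               tolerance = 1e-12)
})

test_that("maxwell_to_tf and tf_to_maxwell are exact inverses", {
  tf <- maxwell_to_tf(1, 1, 1, 2)
  expect_equal(unlist(tf[c("a1", "a2", "b0", "b1")]),
               c(a1 = 1.5, a2 = 0.5, b0 = 2, b1 = 1.5))
  # single-Maxwell reduction: second body inert
  tf1 <- maxwell_to_tf(3, 0, 2, 7)
  expect_equal(tf1$b0, 3)
  expect_equal(tf1$b1, 3 / 7)
  # algebraic round trip on the reference Hammerstein linear block
  rt <- tf_to_maxwell(maxwell_to_tf(0.81, 0.13, 4, 70))
  expect_equal(rt, list(g1 = 0.81, g2 = 0.13, tau1 = 4, tau2 = 70),
               tolerance = 1e-10)
  expect_error(maxwell_to_tf(1, 1, 3, 3), "degenerate")
  # property: round trip over random stable draws
  set.seed(42)
  for (i in 1:25) {
    th <- draw_maxwell()
    rt <- tf_to_maxwell(do.call(maxwell_to_tf, th))
    expect_equal(rt[c("g1", "g2", "tau1", "tau2")],
                 th[c("g1", "g2", "tau1", "tau2")], tolerance = 1e-8)
  }
})

test_that("poles map to sorted time constants and reject degeneracies", {
  expect_equal(poles_to_time_constants(linear_tf(1.05, 0.05, 1, 1)), c(1, 20),
               tolerance = 1e-12)
  expect_error(poles_to_time_constants(linear_tf(2, 1, 1, 1)), "repeated")
  expect_error(poles_to_time_constants(linear_tf(0.2, 1, 1, 1)), "complex")
})

test_that("parameter records enforce their physical invariants", {
  expect_error(model1_params(1, 1, -1, 1, 1, 2), "g1")
  expect_error(model1_params(1, 1, 1, 1, -1, 2))
  expect_error(model2_params(1, 1, 1, 1, 1, 5, 5), "distinct")
  p <- model1_params(-5.61, 4.4, 0.63, 5.21, 1, 20)
  expect_equal(p$g1 * p$tau1 / p$g1, p$tau1)   # eta_i / g_i == tau_i
})

test_that("relaxation closed form has the right limits", {
  t <- c(0, 1, 10, 1e4)
  y <- relaxation_closed_form(2, 1, 1, 10, eps0 = 0.5, t)
  expect_equal(y[1], 0.5 * 3)            # instantaneous modulus
  expect_lt(abs(y[4]), 1e-12)            # full relaxation
  expect_equal(y, 0.5 * (2 * exp(-t) + exp(-t / 10)))
})
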