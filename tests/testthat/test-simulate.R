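test_that("state-space simulation matches the closed-form relaxation", {
  # 100 random stable draws, step input, sup-norm <= 1e-6 (oracle equivalence)
  set.seed(7)
  t <- seq(0, 200, by = 0.5)
  worst <- 0
  for (i in 1:100) {
    th <- draw_maxwell()
    eps0 <- stats::runif(1, -0.5, 0.5)
    y <- simulate_lti(do.call(maxwell_to_tf, th), rep(eps0, length(t)), t)$y
    yc <- relaxation_closed_form(th$g1, th$g2, th$tau1, th$tau2, eps0, t)
    worst <- max(worst, max(abs(y - yc)) / max(abs(yc)))
  }
  expect_lt(worst, 1e-6)
})

test_that("simulate_lti handles trivial and textbook cases", {
  t <- seq(0, 20, 0.1)
  # zero input, zero states
  expect_equal(simulate_lti(maxwell_to_tf(2, 1, 1, 10), numeric(length(t)), t)$y,
               numeric(length(t)))
  # single Maxwell body: unit step -> exp(-t)
  y <- simulate_lti(maxwell_to_tf(1, 0, 1, 50), rep(1, length(t)), t)$y
  expect_equal(y, exp(-t) + 0 * exp(-t / 50), tolerance = 1e-9)
  expect_equal(y[1], 1)
  # step of amplitude 0.5 through (2, 1, 1, 10)
  y2 <- simulate_lti(maxwell_to_tf(2, 1, 1, 10), rep(0.5, length(t)), t)$y
  expect_equal(y2, 0.5 * (2 * exp(-t) + exp(-t / 10)), tolerance = 1e-9)
  expect_warning(simulate_lti(suppressWarnings(linear_tf(-1, 0.5, 1, 1)),
                              rep(1, 5), 0:4), "unstable")
})

test_that("complex-pole fallback agrees with the real-pole fast path", {
  # a tf with real poles forced through the generic state-space route by a
  # nonzero initial state must agree with itself from zero states
  t <- seq(0, 30, 0.05)
  u <- sin(0.7 * t) + 0.3 * cos(2 * t)
  tf <- maxwell_to_tf(1.3, 0.4, 2, 9)
  y_fast <- simulate_lti(tf, u, t)$y                 # modal path
  y_gen <- simulate_lti(tf, u, t, x0 = c(0, 0 + 0))  # same zero states
  expect_equal(y_gen$y, y_fast, tolerance = 1e-10)
  y_forced <- simulate_lti(tf, u, t, x0 = c(1e-300, 0))  # generic path
  expect_equal(y_forced$y, y_fast, tolerance = 1e-8)
})

test_that("model 1 is at equilibrium under constant reference extension", {
  p <- ref_model1()
  k <- kinematic_signal(seq(0, 50, 0.1), rep(5, 501), 5)
  out <- simulate_model1(p, k)
  expect_equal(out$y, numeric(501))
  expect_equal(out$x1, numeric(501))
})

test_that("model 1 with one body reduces to a single exponential", {
  # constant compressed extension: e' is a step, so with g2 = 0 the load
  # relaxes as a single exponential with time constant tau1
  p <- model1_params(C1 = 1, C2 = 0.5, g1 = 2, g2 = 0, tau1 = 3, tau2 = 30)
  t <- seq(0, 30, 0.01)
  k <- kinematic_signal(t, rep(4, length(t)), 5)
  ep <- mr_extension(0.8, 1, 0.5)
  y <- simulate_model1(p, k)$y
  y_oracle <- p$g1 * ep * exp(-t / p$tau1) * (5 / 4)
  expect_equal(y, y_oracle, tolerance = 1e-9)
})

test_that("model 1 integration matches an independent stiff ODE solver", {
  skip_if_not_installed("deSolve")
  p <- ref_model1()
  kin <- make_cycles(cyc_spec())
  mine <- simulate_model1(p, kin)
  # the continuous-time input is the piecewise-linear crosshead motion e(t);
  # the oracle integrates the exact nonlinear-input ODE with lsoda
  e_fun <- stats::approxfun(kin$t, kin$e, rule = 2)
  rhs <- function(t, x, parms) {
    ep <- mr_extension(e_fun(t) / p$e0, p$C1, p$C2)
    list(c((ep - x[1]) / p$tau1, (ep - x[2]) / p$tau2))
  }
  sol <- deSolve::lsoda(c(0, 0), kin$t, rhs, NULL, rtol = 1e-10, atol = 1e-12)
  ep <- mr_extension(kin$lam, p$C1, p$C2)
  y_ref <- (p$g1 * (ep - sol[, 2]) + p$g2 * (ep - sol[, 3])) * (p$e0 / kin$e)
  expect_lt(max(abs(mine$y - y_ref)) / max(abs(y_ref)), 5e-7)
})

test_that("halving the sampling step changes the response below 1e-6", {
  p <- ref_model1()
  k1 <- make_cycles(cyc_spec(rate = 10))
  k2 <- make_cycles(cyc_spec(rate = 20))
  y1 <- simulate_model1(p, k1)$y
  y2 <- simulate_model1(p, k2)$y[seq(1, length(k2$t), by = 2)]
  expect_lt(max(abs(y1 - y2)) / max(abs(y1)), 1e-6)
})

test_that("model 1 output is invariant along the (kC, g/k) scale ridge", {
  kin <- make_cycles(cyc_spec())
  p <- ref_model1()
  y0 <- simulate_model1(p, kin)$y
  for (k in c(0.5, 2, 10)) {
    pk <- model1_params(k * p$C1, k * p$C2, p$g1 / k, p$g2 / k,
                        p$tau1, p$tau2, p$e0, p$A0)
    expect_equal(simulate_model1(pk, kin)$y, y0, tolerance = 1e-10)
  }
})

test_that("hammerstein simulation is the cubic block into the linear block", {
  kin <- make_cycles(cyc_spec())
  p <- ref_hamm()
  out <- simulate_hammerstein(p, kin)
  two_stage <- simulate_lti(maxwell_to_tf(p$g1, p$g2, p$tau1, p$tau2),
                            polynomial_input(kin$eps, p$p0, p$p1, p$p2),
                            kin$t)$y
  expect_identical(out$y, two_stage)
  # identity static block reduces to the linear model on the strain
  pid <- model2_params(0, 0, 1, p$g1, p$g2, p$tau1, p$tau2)
  expect_equal(simulate_hammerstein(pid, kin)$y,
               simulate_lti(maxwell_to_tf(p$g1, p$g2, p$tau1, p$tau2),
                            kin$eps, kin$t)$y)
  # zero static block kills the output
  p0 <- model2_params(0, 0, 0, p$g1, p$g2, p$tau1, p$tau2)
  expect_equal(simulate_hammerstein(p0, kin)$y, numeric(length(kin$t)))
})

test_that("steady-state hysteresis loops of passive models dissipate work", {
  set.seed(11)
  spec <- cyc_spec()
  kin <- make_cycles(spec)
  # last full cycle indices (cycle period 60 s at 10 Hz after 60 s approach)
  for (i in 1:5) {
    th <- draw_maxwell()
    y <- simulate_lti(do.call(maxwell_to_tf, th), kin$eps, kin$t)$y
    n <- length(kin$t)
    idx <- seq(n - 600, n)
    expect_gt(hysteresis_area(kin$eps[idx], y[idx]), 0)
  }
  ph <- ref_hamm()
  yh <- simulate_hammerstein(ph, kin)$y
  idx <- seq(length(kin$t) - 600, length(kin$t))
  expect_gt(hysteresis_area(kin$eps[idx], yh[idx]), 0)
})
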