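test_that("FIT hits its closed-form anchor points", {
  y <- c(0.3, -1.2, 4.5, 2)
  expect_equal(fit_percent(y, y), 100)
  expect_equal(fit_percent(rep(mean(y), 4), y), 0)
  expect_equal(fit_percent(c(0, 1, 3), c(0, 1, 2)), 100 * (1 - 1 / sqrt(2)))
  expect_error(fit_percent(c(1, 2), c(3, 3)), "constant")
  expect_error(fit_percent(1:3, 1:4), "length")
})

test_that("FIT is invariant to common shifts and scalings", {
  set.seed(3)
  ym <- rnorm(50); yd <- ym + rnorm(50, sd = 0.2)
  f0 <- fit_percent(ym, yd)
  expect_equal(fit_percent(ym + 7, yd + 7), f0)
  expect_equal(fit_percent(-3 * ym, -3 * yd), f0)
})

test_that("FPE applies the Akaike small-sample penalty", {
  expect_equal(fpe(1, 4, 100), 0.01 * 104 / 96)
  expect_equal(fpe(2, 0, 50), 2 / 50)           # no-parameter limit
  # monotone in d at fixed loss and N
  vals <- vapply(0:6, function(d) fpe(1, d, 100), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(fpe(1, 10, 10), "more samples")
})

test_that("mr_linearize exactly inverts the stress-stretch law", {
  lam <- seq(0.7, 0.95, by = 0.001)
  C1 <- -5.61; C2 <- 4.4
  sigma <- (C1 + C2 / lam) * (lam^2 - 1 / lam)
  d <- mr_linearize(lam, sigma)
  expect_lt(abs(d$intercept - C1), 1e-9)
  expect_lt(abs(d$slope - C2), 1e-9)
  # Neo-Hookean signature: flat line at C1
  sigma_nh <- 0.22 * (lam^2 - 1 / lam)
  d2 <- mr_linearize(lam, sigma_nh)
  expect_lt(abs(d2$slope), 1e-9)
  expect_lt(abs(d2$intercept - 0.22), 1e-9)
})

test_that("mr_linearize guards the lambda = 1 singularity", {
  lam <- c(0.995, 1, 1.005, 0.8, 0.9, 0.85)
  sigma <- 2 * (lam^2 - 1 / lam)
  d <- mr_linearize(lam, sigma, guard = 0.01)
  expect_identical(d$n_excluded, 3L)
  expect_length(d$x, 3L)
  expect_error(mr_linearize(c(1, 1.001), c(0, 0)), "fewer than 2")
})

test_that("hysteresis area is zero for elastic loops, exact on polygons", {
  eps <- c(seq(-0.1, -0.3, length.out = 30), seq(-0.3, -0.1, length.out = 30))
  expect_equal(hysteresis_area(eps, 5 * eps), 0, tolerance = 1e-12)
  # closed parallelogram (-0.1,0.1) (-0.3,0) (-0.3,0.1) (-0.1,0.2): area 0.02
  e4 <- c(-0.1, -0.3, -0.3, -0.1, -0.1)
  y4 <- c(0.1, 0.0, 0.1, 0.2, 0.1)
  expect_equal(abs(hysteresis_area(e4, y4)), 0.02, tolerance = 1e-12)
  expect_error(hysteresis_area(c(-0.1, -0.2, -0.3), c(0, 1, 2)), "open")
})

test_that("cyclic records split at the first touch of the lower bound", {
  ds <- generate_dataset("hammerstein", ref_hamm(), cyc_spec(), seed = 2,
                         label = "s")
  parts <- split_first_compression(ds, lower_bound = 0.15)
  eng_first <- -(ds$e0 / (1 - parts$first$strain) - ds$e0) / ds$e0
  expect_lt(max(eng_first[-length(eng_first)]), 0.15)
  expect_gte(max(eng_first), 0.15 - 1e-9)
  expect_equal(length(parts$first$t) + length(parts$cycling$t),
               length(ds$t) + 1L)   # split sample belongs to both parts
  expect_match(parts$cycling$label, "_cycling$")
})
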