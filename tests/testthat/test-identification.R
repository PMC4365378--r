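test_that("srivc recovers a noise-free transfer function to 0.1%", {
  tf0 <- maxwell_to_tf(1, 1, 1, 20)
  ds <- generate_dataset("linear", tf0, cyc_spec(), noise_sd = 0, label = "id")
  fit <- srivc(ds)
  th0 <- unlist(tf0[c("a1", "a2", "b0", "b1")])
  th <- unlist(fit$tf[c("a1", "a2", "b0", "b1")])
  expect_lt(max(abs(th - th0) / abs(th0)), 1e-3)
  expect_true(fit$converged)
  # physical and transfer-function parameterizations are equivalent
  expect_equal(poles_to_time_constants(fit$tf), c(1, 20), tolerance = 1e-3)
})

test_that("srivc refuses an unexciting input", {
  ds <- ts_dataset(0:99, rep(0, 100), rnorm(100), label = "flat")
  expect_error(srivc(ds), "rank deficient|excite")
})

test_that("srivc degrades gracefully at 1% output noise", {
  tf0 <- maxwell_to_tf(1, 1, 1, 20)
  th0 <- unlist(tf0[c("a1", "a2", "b0", "b1")])
  errs <- vapply(1:20, function(s) {
    ds <- generate_dataset("linear", tf0, cyc_spec(), seed = 100 + s,
                           label = "id")
    th <- unlist(srivc(ds)$tf[c("a1", "a2", "b0", "b1")])
    max(abs(th - th0) / abs(th0))
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("grey-box fit recovers noise-free model-1 parameters to 0.5%", {
  p <- ref_model1()
  ds <- generate_dataset("model1", p, cyc_spec(), noise_sd = 0, label = "id")
  fit <- fit_greybox(ds, "model1",
    init = list(C1 = 2 * p$C1, C2 = p$C2, g1 = 2 * p$g1, g2 = 2 * p$g2,
                tau1 = p$tau1, tau2 = p$tau2),
    fixed = c("C2", "tau1", "tau2"))
  expect_true(fit$converged)
  expect_lt(rel_err(fit$params$C1, p$C1), 0.005)
  expect_lt(rel_err(fit$params$g1, p$g1), 0.005)
  expect_lt(rel_err(fit$params$g2, p$g2), 0.005)
})

test_that("all-fixed fit returns the initial model's residuals unchanged", {
  p <- ref_hamm()
  ds <- generate_dataset("hammerstein", p, cyc_spec(), seed = 4, label = "id")
  init <- list(p0 = p$p0, p1 = p$p1, p2 = p$p2, g1 = p$g1, g2 = p$g2,
               tau1 = p$tau1, tau2 = p$tau2)
  fit <- fit_greybox(ds, "hammerstein", init = init,
                     fixed = names(init))
  kin <- make_cycles(cyc_spec())
  expect_equal(fit$residuals, ds$load - simulate_hammerstein(p, kin)$y)
  expect_identical(fit$n_iter, 0L)
})

test_that("the model-1 scale ridge makes unnormalized fits non-unique", {
  p <- ref_model1()
  ds <- generate_dataset("model1", p, cyc_spec(), seed = 21, label = "id")
  base <- list(C1 = p$C1, C2 = p$C2, g1 = p$g1, g2 = p$g2,
               tau1 = p$tau1, tau2 = p$tau2)
  k <- 3
  ridge <- list(C1 = k * p$C1, C2 = k * p$C2, g1 = p$g1 / k, g2 = p$g2 / k,
                tau1 = p$tau1, tau2 = p$tau2)
  f1 <- fit_greybox(ds, "model1", init = base, fixed = c("tau1", "tau2"))
  f2 <- fit_greybox(ds, "model1", init = ridge, fixed = c("tau1", "tau2"))
  expect_lt(abs(f1$loss - f2$loss) / f1$loss, 1e-8)
  # ... while the parameter vectors stay far apart
  expect_gt(abs(f1$params$C1 - f2$params$C1) / abs(f1$params$C1), 0.5)
})

test_that("loss is non-increasing across accepted LM iterations", {
  p <- ref_hamm()
  ds <- generate_dataset("hammerstein", p, cyc_spec(), seed = 6, label = "id")
  fit <- fit_greybox(ds, "hammerstein",
    init = list(p0 = 2 * p$p0, p1 = 2 * p$p1, p2 = 0, g1 = p$g1,
                g2 = 2 * p$g2, tau1 = 2 * p$tau1, tau2 = 2 * p$tau2),
    fixed = "g1")
  expect_true(all(diff(fit$rsstrace) <= 1e-12 * fit$rsstrace[1]))
})

test_that("fixing a parameter at a wrong value raises the best loss", {
  p <- ref_hamm()
  ds <- generate_dataset("hammerstein", p, cyc_spec(), seed = 8, label = "id")
  init_true <- list(p0 = p$p0, p1 = p$p1, p2 = p$p2, g1 = p$g1, g2 = p$g2,
                    tau1 = p$tau1, tau2 = p$tau2)
  f_ok <- fit_greybox(ds, "hammerstein", init = init_true,
                      fixed = c("g1", "tau1"))
  init_bad <- init_true
  init_bad$tau1 <- 4 * p$tau1
  f_bad <- fit_greybox(ds, "hammerstein", init = init_bad,
                       fixed = c("g1", "tau1"))
  expect_gt(f_bad$loss, f_ok$loss * 1.01)
})

test_that("validation is a pure forward simulation with label hygiene", {
  p <- ref_hamm()
  ds_id <- generate_dataset("hammerstein", p, cyc_spec(), noise_sd = 0,
                            label = "sample1")
  fit <- fit_greybox(ds_id, "hammerstein",
    init = list(p0 = p$p0, p1 = p$p1, p2 = p$p2, g1 = p$g1, g2 = p$g2,
                tau1 = p$tau1, tau2 = p$tau2),
    fixed = names(ref_hamm())[1:7])
  # validating the generating model on its own noise-free data: FIT = 100
  ds_val <- generate_dataset("hammerstein", p, cyc_spec(0.5), noise_sd = 0,
                             label = "sample2")
  expect_equal(validate(fit, ds_val)$fit_percent, 100, tolerance = 1e-6)
  # identification label refused
  expect_error(validate(fit, ds_id), "label")
  # a linear model validated on strongly nonlinear data stays below 100
  lin <- srivc(generate_dataset("hammerstein", p, cyc_spec(), seed = 1,
                                label = "sample1"))
  expect_lt(validate(lin, ds_val)$fit_percent, 100)
})

test_that("random initialisation is seed-controlled and structure-complete", {
  ds <- generate_dataset("linear", maxwell_to_tf(1, 1, 1, 20), cyc_spec(),
                         seed = 2, label = "id")
  f1 <- suppressWarnings(
    fit_greybox(ds, "hammerstein", seed = 5, fixed = "g1", max_iter = 1))
  f2 <- suppressWarnings(
    fit_greybox(ds, "hammerstein", seed = 5, fixed = "g1", max_iter = 1))
  expect_identical(coef(f1), coef(f2))
})
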