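# Shared fixtures: reference truths and small protocol builders.

ref_model1 <- function() gel_reference_params("model1")
ref_neo <- function() gel_reference_params("model1_neohookean")
ref_hamm <- function() gel_reference_params("hammerstein")

cyc_spec <- function(speed = 1.0, rate = 10, ...)
  protocol_spec("cycles", crosshead_speed = speed, cycle_bounds = c(0.15, 0.25),
                n_cycles = 8, sample_rate = rate, ...)

relax_spec <- function(target = 0.5, hold = 1800, rate = 1)
  protocol_spec("step_relaxation", crosshead_speed = 10,
                target_strain = target, hold_duration = hold,
                sample_rate = rate)

# random stable two-Maxwell parameter draw (log-uniform taus, uniform g)
draw_maxwell <- function() {
  taus <- sort(exp(stats::runif(2, log(0.5), log(100))))
  while (taus[2] / taus[1] < 1.5) taus[2] <- taus[2] * 2
  list(g1 = stats::runif(1, 0.1, 5), g2 = stats::runif(1, 0.1, 5),
       tau1 = taus[1], tau2 = taus[2])
}

rel_err <- function(est, true) abs(est - true) / abs(true)
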