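#' Mechanical test protocol specification
#'
#' Describes one uniaxial unconfined-compression test the way an operator
#' programs the testing machine: crosshead speed in mm/min and compression
#' magnitudes as positive engineering-strain fractions. Conversion to the
#' signed internal strain happens when the kinematic signal is built.
#'
#' @param kind one of `"ramp"`, `"cycles"`, `"step_relaxation"`.
#' @param crosshead_speed crosshead speed, mm/min, positive.
#' @param target_strain final compression magnitude (engineering strain
#'   fraction) for ramp and step-relaxation protocols.
#' @param cycle_bounds length-2 numeric, `(low, high)` compression
#'   magnitudes for cyclic protocols, `0 <= low < high < 1`.
#' @param n_cycles number of triangular cycles, >= 1.
#' @param hold_duration hold time after the ramp for step-relaxation, s.
#' @param sample_rate sampling rate, Hz.
#' @param e0 reference extension (sample thickness), mm.
#' @param A0 reference cross-section, mm^2.
#' @return Object of class `protocol_spec`.
#' @examples
#' protocol_spec("cycles", crosshead_speed = 1.0,
#'               cycle_bounds = c(0.15, 0.25), n_cycles = 8)
#' @export
protocol_spec <- function(kind = c("ramp", "cycles", "step_relaxation"),
                          crosshead_speed = 1.0,
                          target_strain = 0.2,
                          cycle_bounds = c(0.15, 0.25),
                          n_cycles = 8L,
                          hold_duration = 1800,
                          sample_rate = if (kind[1] == "step_relaxation") 1 else 10,
                          e0 = 5, A0 = 700) {
  kind <- match.arg(kind)
  stopifnot(crosshead_speed > 0, sample_rate > 0, e0 > 0, A0 > 0,
            n_cycles >= 1, hold_duration >= 0)
  if (kind %in% c("ramp", "step_relaxation")) {
    if (!(target_strain >= 0 && target_strain < 1))
      stop("'target_strain' must be in [0, 1)")
  }
  if (kind == "cycles") {
    if (length(cycle_bounds) != 2L || cycle_bounds[1] < 0 ||
        cycle_bounds[1] > cycle_bounds[2] || cycle_bounds[2] >= 1)
      stop("'cycle_bounds' must satisfy 0 <= low <= high < 1")
  }
  structure(list(kind = kind, crosshead_speed = crosshead_speed,
                 target_strain = target_strain, cycle_bounds = cycle_bounds,
                 n_cycles = as.integer(n_cycles), hold_duration = hold_duration,
                 sample_rate = sample_rate, e0 = e0, A0 = A0),
            class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("Protocol '%s': %g mm/min, %g Hz, e0 = %g mm, A0 = %g mm^2\n",
              x$kind, x$crosshead_speed, x$sample_rate, x$e0, x$A0))
  if (x$kind == "cycles")
    cat(sprintf("  %d cycles between %g%% and %g%% engineering strain\n",
                x$n_cycles, 100 * x$cycle_bounds[1], 100 * x$cycle_bounds[2]))
  else
    cat(sprintf("  to %g%% engineering strain%s\n", 100 * x$target_strain,
                if (x$kind == "step_relaxation")
                  sprintf(", hold %g s", x$hold_duration) else ""))
  invisible(x)
}

# sample a piecewise-linear extension profile given breakpoint times/values;
# the grid always contains t = 0 and the final breakpoint exactly
sample_piecewise <- function(bp_t, bp_e, rate, e0) {
  t_end <- bp_t[length(bp_t)]
  t <- seq(0, t_end, by = 1 / rate)
  if (t[length(t)] < t_end - 1e-12) t <- c(t, t_end)
  e <- stats::approx(bp_t, bp_e, xout = t, rule = 2)$y
  kinematic_signal(t, e, e0)
}

#' Generate a constant-speed compression ramp
#'
#' Extension decreases linearly from `e0` at the programmed crosshead speed
#' until the compression magnitude reaches `target_strain` (engineering),
#' then the record ends. A speed of 1 mm/min on a 5 mm sample reaches 20%
#' strain in exactly 60 s.
#'
#' @param spec a [protocol_spec] with `kind = "ramp"`.
#' @return A [kinematic_signal].
#' @export
make_ramp <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"), spec$kind == "ramp")
  travel <- spec$e0 * spec$target_strain
  v <- spec$crosshead_speed / 60             # mm/s
  if (travel == 0)
    return(sample_piecewise(c(0, 1 / spec$sample_rate), rep(spec$e0, 2),
                            spec$sample_rate, spec$e0))
  sample_piecewise(c(0, travel / v), c(spec$e0, spec$e0 - travel),
                   spec$sample_rate, spec$e0)
}

#' Generate a triangular cyclic compression protocol
#'
#' An approach ramp from the undeformed state to the mean of the cycle
#' bounds, followed by `n_cycles` triangular excursions about that mean
#' (mean -> high bound -> low bound -> mean), all at the constant crosshead
#' speed. Each cycle produces exactly one local maximum of compression
#' magnitude and travels twice the full excursion, so the cycling phase
#' lasts exactly `n_cycles * 2 * de / speed` with `de` the bound-to-bound
#' travel in mm.
#'
#' @param spec a [protocol_spec] with `kind = "cycles"`.
#' @return A [kinematic_signal].
#' @export
make_cycles <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"), spec$kind == "cycles")
  lo <- spec$cycle_bounds[1]; hi <- spec$cycle_bounds[2]
  mid <- (lo + hi) / 2
  e_mid <- spec$e0 * (1 - mid)
  e_lo  <- spec$e0 * (1 - lo)      # shallow compression = larger extension
  e_hi  <- spec$e0 * (1 - hi)      # deep compression = smaller extension
  v <- spec$crosshead_speed / 60
  bp_e <- c(spec$e0, e_mid)
  if (hi > lo) {
    for (i in seq_len(spec$n_cycles)) bp_e <- c(bp_e, e_hi, e_lo, e_mid)
    bp_t <- c(0, cumsum(abs(diff(bp_e)) / v))
  } else {
    # degenerate bounds: constant plateau (one sample period) after approach
    t_appr <- abs(spec$e0 - e_mid) / v
    bp_e <- c(bp_e, e_mid)
    bp_t <- c(0, t_appr, t_appr + 1 / spec$sample_rate)
  }
  sample_piecewise(bp_t, bp_e, spec$sample_rate, spec$e0)
}

#' Generate a step-relaxation protocol
#'
#' A fast ramp (default 10 mm/min) to the target compression magnitude,
#' then a hold at constant extension for `hold_duration` seconds while the
#' load relaxes. On a 5 mm sample a 50% step takes 15 s of ramping.
#'
#' @param spec a [protocol_spec] with `kind = "step_relaxation"`.
#' @return A [kinematic_signal].
#' @export
make_step_relaxation <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"), spec$kind == "step_relaxation")
  travel <- spec$e0 * spec$target_strain
  v <- spec$crosshead_speed / 60
  t_ramp <- if (travel > 0) travel / v else 0
  e_end <- spec$e0 - travel
  if (spec$hold_duration <= 0) {
    if (t_ramp == 0) stop("degenerate protocol: no ramp and no hold")
    return(sample_piecewise(c(0, t_ramp), c(spec$e0, e_end),
                            spec$sample_rate, spec$e0))
  }
  if (t_ramp == 0)
    return(sample_piecewise(c(0, spec$hold_duration), c(spec$e0, e_end),
                            spec$sample_rate, spec$e0))
  sample_piecewise(c(0, t_ramp, t_ramp + spec$hold_duration),
                   c(spec$e0, e_end, e_end), spec$sample_rate, spec$e0)
}

#' Build the kinematic signal for any protocol
#'
#' Dispatches on `spec$kind` to [make_ramp], [make_cycles] or
#' [make_step_relaxation].
#'
#' @param spec a [protocol_spec].
#' @return A [kinematic_signal].
#' @export
make_protocol_signal <- function(spec) {
  switch(spec$kind,
         ramp = make_ramp(spec),
         cycles = make_cycles(spec),
         step_relaxation = make_step_relaxation(spec))
}
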