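#' Parameters of the Mooney-Rivlin-inspired two-Maxwell model (model 1)
#'
#' Two Maxwell bodies in parallel driven by a nonlinear spring extension
#' derived from the Mooney-Rivlin stress-stretch law. `C1`, `C2` are the
#' Mooney-Rivlin constants (stress-like, MPa under the package's unit
#' convention; unrestricted in sign), `g1`, `g2` the spring constants,
#' `tau1`, `tau2` the relaxation times in seconds (\eqn{\tau_i =
#' \eta_i/g_i}). The viscosities `eta1`, `eta2` are derived, never stored
#' independently. Setting `C2 = 0` gives the Neo-Hookean special case.
#'
#' @param C1,C2 Mooney-Rivlin constants.
#' @param g1,g2 spring constants, non-negative.
#' @param tau1,tau2 relaxation times, s, positive.
#' @param e0 reference extension, mm.
#' @param A0 reference cross-section, mm^2.
#' @return Object of class `model1_params`.
#' @export
model1_params <- function(C1, C2, g1, g2, tau1, tau2, e0 = 5, A0 = 700) {
  stopifnot(tau1 > 0, tau2 > 0, g1 >= 0, g2 >= 0, e0 > 0, A0 > 0)
  structure(list(C1 = C1, C2 = C2, g1 = g1, g2 = g2,
                 tau1 = tau1, tau2 = tau2, e0 = e0, A0 = A0),
            class = "model1_params")
}

#' @export
print.model1_params <- function(x, ...) {
  cat("Mooney-Rivlin-inspired two-Maxwell model parameters:\n")
  cat(sprintf("  C1 = %g, C2 = %g%s\n", x$C1, x$C2,
              if (x$C2 == 0) " (Neo-Hookean)" else ""))
  cat(sprintf("  g1 = %g, g2 = %g; tau1 = %g s, tau2 = %g s\n",
              x$g1, x$g2, x$tau1, x$tau2))
  cat(sprintf("  eta1 = %g, eta2 = %g; e0 = %g mm, A0 = %g mm^2\n",
              x$g1 * x$tau1, x$g2 * x$tau2, x$e0, x$A0))
  invisible(x)
}

#' Parameters of the Hammerstein model (model 2)
#'
#' A memoryless cubic polynomial of the strain,
#' \eqn{f(\epsilon) = p_0\epsilon^3 + p_1\epsilon^2 + p_2\epsilon},
#' feeding the linear two-Maxwell dynamic block with spring constants
#' `g1`, `g2` and relaxation times `tau1`, `tau2` (s). The two time
#' constants must be distinct (two genuinely different Maxwell bodies).
#'
#' @param p0,p1,p2 cubic polynomial coefficients (cubic, quadratic, linear
#'   term; no constant term so that `f(0) = 0`).
#' @param g1,g2 spring constants, non-negative.
#' @param tau1,tau2 relaxation times, s, positive and distinct.
#' @param A0 reference cross-section, mm^2.
#' @return Object of class `model2_params`.
#' @export
model2_params <- function(p0, p1, p2, g1, g2, tau1, tau2, A0 = 700) {
  stopifnot(tau1 > 0, tau2 > 0, g1 >= 0, g2 >= 0, A0 > 0)
  if (tau1 == tau2) stop("degenerate model: tau1 == tau2 (two distinct Maxwell bodies required)")
  structure(list(p0 = p0, p1 = p1, p2 = p2, g1 = g1, g2 = g2,
                 tau1 = tau1, tau2 = tau2, A0 = A0),
            class = "model2_params")
}

#' @export
print.model2_params <- function(x, ...) {
  cat("Hammerstein two-Maxwell model parameters:\n")
  cat(sprintf("  cubic block: f(eps) = %g eps^3 + %g eps^2 + %g eps\n",
              x$p0, x$p1, x$p2))
  cat(sprintf("  linear block: g1 = %g, g2 = %g; tau1 = %g s, tau2 = %g s\n",
              x$g1, x$g2, x$tau1, x$tau2))
  invisible(x)
}

#' Second-order continuous-time transfer function of two Maxwell bodies
#'
#' The linear two-Maxwell system \eqn{\ddot y + a_1\dot y + a_2 y =
#' b_0\ddot u + b_1\dot u}. For physical parameters the denominator roots
#' are real and negative, with \eqn{a_1 = (\tau_1+\tau_2)/\tau_1\tau_2},
#' \eqn{a_2 = 1/\tau_1\tau_2}, \eqn{b_0 = g_1+g_2},
#' \eqn{b_1 = g_1/\tau_2 + g_2/\tau_1}.
#'
#' @param a1,a2 denominator coefficients (1/s, 1/s^2); must be positive for
#'   a stable system (constructor warns otherwise).
#' @param b0,b1 numerator coefficients.
#' @return Object of class `linear_tf`.
#' @export
linear_tf <- function(a1, a2, b0, b1) {
  stopifnot(is.finite(a1), is.finite(a2), is.finite(b0), is.finite(b1))
  if (a1 <= 0 || a2 <= 0)
    warning("unstable transfer function: a1 and a2 should be positive")
  structure(list(a1 = a1, a2 = a2, b0 = b0, b1 = b1), class = "linear_tf")
}

#' @export
print.linear_tf <- function(x, ...) {
  cat(sprintf("Continuous-time transfer function: (%g s^2 + %g s) / (s^2 + %g s + %g)\n",
              x$b0, x$b1, x$a1, x$a2))
  p <- tf_poles(x)
  if (all(Im(p) == 0))
    cat(sprintf("  poles: %g, %g (1/s)\n", Re(p)[1], Re(p)[2]))
  else cat("  poles: complex pair", format(p[1]), "\n")
  invisible(x)
}

#' Map physical two-Maxwell parameters to the transfer function and back
#'
#' `maxwell_to_tf` is the exact algebraic map from `(g1, g2, tau1, tau2)`
#' to `(a1, a2, b0, b1)`; `tf_to_maxwell` inverts it (unique up to the
#' labelling of the two bodies; returned with `tau1 <= tau2`).
#'
#' @param g1,g2 spring constants.
#' @param tau1,tau2 relaxation times, s, positive and distinct.
#' @return `maxwell_to_tf`: a [linear_tf]. `tf_to_maxwell`: a named list
#'   with `g1`, `g2`, `tau1`, `tau2`.
#' @examples
#' tf <- maxwell_to_tf(1, 1, 1, 2)  # a1 = 1.5, a2 = 0.5, b0 = 2, b1 = 1.5
#' tf_to_maxwell(tf)
#' @export
maxwell_to_tf <- function(g1, g2, tau1, tau2) {
  stopifnot(tau1 > 0, tau2 > 0)
  if (tau1 == tau2) stop("degenerate poles: tau1 == tau2")
  linear_tf(a1 = (tau1 + tau2) / (tau1 * tau2),
            a2 = 1 / (tau1 * tau2),
            b0 = g1 + g2,
            b1 = g1 / tau2 + g2 / tau1)
}

#' @rdname maxwell_to_tf
#' @param tf a [linear_tf].
#' @export
tf_to_maxwell <- function(tf) {
  tc <- poles_to_time_constants(tf)      # tau1 <= tau2, errors on complex poles
  tau1 <- tc[1]; tau2 <- tc[2]
  # solve b0 = g1 + g2, b1 = g1/tau2 + g2/tau1 for (g1, g2)
  g1 <- (tf$b1 - tf$b0 / tau1) / (1 / tau2 - 1 / tau1)
  g2 <- tf$b0 - g1
  list(g1 = g1, g2 = g2, tau1 = tau1, tau2 = tau2)
}

tf_poles <- function(tf) {
  disc <- as.complex(tf$a1^2 - 4 * tf$a2)
  (-tf$a1 + c(1, -1) * sqrt(disc)) / 2
}

#' Time constants from the poles of an identified transfer function
#'
#' The poles of the two-Maxwell transfer function are the negative inverse
#' time constants of the Maxwell bodies: \eqn{\tau_i = -1/s_i}. Complex or
#' repeated poles are rejected: they cannot arise from two distinct
#' relaxing bodies.
#'
#' @param tf a [linear_tf].
#' @param tol relative tolerance for deciding whether the two poles are
#'   distinct.
#' @return Numeric vector `c(tau1, tau2)` with `tau1 <= tau2`, seconds.
#' @examples
#' poles_to_time_constants(linear_tf(1.05, 0.05, 1, 1))  # c(1, 20)
#' @export
poles_to_time_constants <- function(tf, tol = 1e-8) {
  p <- tf_poles(tf)
  if (any(abs(Im(p)) > tol * pmax(abs(p), 1)))
    stop("complex poles: not a two-Maxwell system")
  p <- Re(p)
  if (any(p >= 0)) stop("non-negative pole: unstable or non-relaxing system")
  if (abs(p[1] - p[2]) <= tol * max(abs(p)))
    stop("repeated pole: degenerate (tau1 == tau2) system")
  sort(-1 / p)
}

#' Nonlinear spring extension of the Mooney-Rivlin-inspired model
#'
#' The memoryless extension
#' \eqn{e' = (C_1 + C_2/\lambda)(\lambda^2 - 1/\lambda)} driving both
#' Maxwell bodies of model 1. With `C2 = 0` it reduces to the Neo-Hookean
#' form; at \eqn{\lambda = 1} it vanishes for any constants.
#'
#' @param lam stretch, positive.
#' @param C1,C2 Mooney-Rivlin constants.
#' @return Extension `e'` (stress-like units), same shape as `lam`.
#' @examples
#' mr_extension(2, C1 = 1, C2 = 0)          # 3.5
#' mr_extension(0.8, C1 = -5.61, C2 = 4.4)  # 0.0671
#' @export
mr_extension <- function(lam, C1, C2) {
  if (any(lam <= 0)) stop("stretch must be positive")
  (C1 + C2 / lam) * (lam^2 - 1 / lam)
}

#' Cubic input nonlinearity of the Hammerstein model
#'
#' \eqn{f(\epsilon) = p_0\epsilon^3 + p_1\epsilon^2 + p_2\epsilon}. No
#' constant term, so a relaxed sample (`eps = 0`) produces zero input to the
#' linear block.
#'
#' @param eps strain (signed).
#' @param p0,p1,p2 polynomial coefficients.
#' @return Transformed input, same shape as `eps`.
#' @examples
#' polynomial_input(0.2, 10.8, -1.1, 0)  # 0.0424
#' @export
polynomial_input <- function(eps, p0, p1, p2) {
  ((p0 * eps + p1) * eps + p2) * eps
}

#' Closed-form two-exponential relaxation response
#'
#' Analytic load trajectory of the linear two-Maxwell model under an ideal
#' strain step of amplitude `eps0` applied at `t = 0`:
#' \eqn{y(t) = \epsilon_0 (g_1 e^{-t/\tau_1} + g_2 e^{-t/\tau_2})}.
#' Used as the independent oracle for the state-space simulator and as an
#' initialiser for relaxation fits.
#'
#' @param g1,g2 spring constants.
#' @param tau1,tau2 relaxation times, s, positive.
#' @param eps0 step amplitude (strain).
#' @param t time grid, s.
#' @return Numeric load trajectory on `t`.
#' @export
relaxation_closed_form <- function(g1, g2, tau1, tau2, eps0, t) {
  stopifnot(tau1 > 0, tau2 > 0)
  eps0 * (g1 * exp(-t / tau1) + g2 * exp(-t / tau2))
}
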