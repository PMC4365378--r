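#' Sampled kinematic signal of a compression test
#'
#' Bundles the time grid and the mutually consistent deformation measures of
#' one uniaxial test: extension `e` (mm), true strain
#' \eqn{\epsilon = (e - e_0)/e}, engineering strain
#' \eqn{\epsilon_{eng} = (e - e_0)/e_0} and stretch \eqn{\lambda = e/e_0}.
#' In compression `e < e0`, so all strains are negative and \eqn{\lambda < 1};
#' protocol descriptors quote compression magnitudes, the signal carries the
#' signed values.
#'
#' @param t numeric, strictly increasing time grid in seconds.
#' @param e numeric, extension in mm, strictly positive, same length as `t`.
#' @param e0 scalar reference extension at time 0, mm.
#' @return An object of class `kinematic_signal`: a list with fields `t`,
#'   `e`, `e0`, `eps`, `eps_eng`, `lam`.
#' @examples
#' k <- kinematic_signal(t = 0:10, e = seq(5, 4, length.out = 11), e0 = 5)
#' range(k$lam)   # stretch 0.8 .. 1
#' @export
kinematic_signal <- function(t, e, e0) {
  t <- as.numeric(t); e <- as.numeric(e); e0 <- as.numeric(e0)
  if (length(e0) != 1L || !is.finite(e0) || e0 <= 0)
    stop("'e0' must be a single positive number (mm)")
  if (length(t) != length(e)) stop("'t' and 'e' must have equal length")
  if (length(t) < 1L) stop("empty signal")
  if (any(!is.finite(t)) || any(!is.finite(e))) stop("non-finite values in 't' or 'e'")
  if (any(diff(t) <= 0)) stop("'t' must be strictly increasing")
  if (any(e <= 0)) stop("extension 'e' must be strictly positive")
  structure(list(
    t = t, e = e, e0 = e0,
    eps = (e - e0) / e,
    eps_eng = (e - e0) / e0,
    lam = e / e0
  ), class = "kinematic_signal")
}

#' @export
print.kinematic_signal <- function(x, ...) {
  cat("Kinematic signal:", length(x$t), "samples over",
      format(diff(range(x$t))), "s; e0 =", x$e0, "mm\n")
  cat("  engineering strain range: [",
      format(min(x$eps_eng), digits = 4), ",",
      format(max(x$eps_eng), digits = 4), "]\n")
  invisible(x)
}

#' Convert between true strain and stretch
#'
#' The stretch ratio is \eqn{\lambda = (1 - \epsilon)^{-1}} with the true
#' (Eulerian) strain \eqn{\epsilon = (e - e_0)/e}; equivalently
#' \eqn{\lambda = e/e_0}. Compression has \eqn{\epsilon < 0},
#' \eqn{\lambda < 1}.
#'
#' @param eps true strain, must satisfy `eps < 1`.
#' @return Stretch \eqn{\lambda > 0}.
#' @examples
#' stretch_from_strain(0.2)    # 1.25
#' stretch_from_strain(-0.25)  # 0.8 (compression)
#' @export
stretch_from_strain <- function(eps) {
  if (any(eps >= 1)) stop("strain must be < 1: stretch (1 - eps)^-1 undefined")
  1 / (1 - eps)
}

#' @rdname stretch_from_strain
#' @param lam stretch, must be positive.
#' @export
strain_from_stretch <- function(lam) {
  if (any(lam <= 0)) stop("stretch must be positive")
  1 - 1 / lam
}

#' Convert Eulerian stress to the load-compatible stress measure
#'
#' `T = sigma * e0 / e`: the stress measure whose product with the reference
#' cross-section `A0` is the measured load. At \eqn{\lambda = 1} the two
#' coincide.
#'
#' @param sigma Eulerian (Cauchy) stress.
#' @param e current extension, mm, positive.
#' @param e0 reference extension, mm.
#' @return Stress measure `T` (same units as `sigma`).
#' @export
stress_conversion <- function(sigma, e, e0) {
  if (any(e <= 0)) stop("extension 'e' must be positive")
  sigma * e0 / e
}

#' @rdname stress_conversion
#' @param T_stress stress measure `T`.
#' @export
stress_conversion_inverse <- function(T_stress, e, e0) {
  if (any(e <= 0)) stop("extension 'e' must be positive")
  T_stress * e / e0
}
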