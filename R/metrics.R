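#' Normalized goodness-of-fit percentage (FIT)
#'
#' \eqn{FIT = 100\,(1 - \|y_{model} - y_{meas}\| / \|y_{meas} -
#' \overline{y}_{meas}\|)} with the Euclidean norm over the whole record.
#' 100 means a perfect match, 0 is the level of the constant mean
#' predictor, and the value is unbounded below. Invariant to adding a
#' common constant to both signals or scaling both by a common nonzero
#' factor.
#'
#' @param y_model simulated model output.
#' @param y_meas measured output, not constant, same length (>= 2).
#' @return FIT in percent.
#' @examples
#' fit_percent(c(0, 1, 3), c(0, 1, 2))  # 100 * (1 - 1/sqrt(2)) = 29.29
#' @export
fit_percent <- function(y_model, y_meas) {
  if (length(y_model) != length(y_meas)) stop("signals must have equal length")
  if (length(y_meas) < 2) stop("at least two samples required")
  denom <- sqrt(sum((y_meas - mean(y_meas))^2))
  if (denom == 0) stop("'y_meas' is constant: FIT undefined (zero denominator)")
  100 * (1 - sqrt(sum((y_model - y_meas)^2)) / denom)
}

#' Akaike final prediction error
#'
#' \eqn{FPE = (loss/N)\,(1 + d/N)/(1 - d/N)} with `d` free parameters and
#' `N` identification samples — the complexity-penalized loss used to rank
#' model structures on identification data.
#'
#' @param loss sum of squared prediction errors on identification data.
#' @param n_params number of free (estimated) parameters `d`.
#' @param n_samples number of samples `N`, must exceed `n_params`.
#' @return FPE (loss units).
#' @examples
#' fpe(1, 4, 100)  # 0.01 * 104/96
#' @export
fpe <- function(loss, n_params, n_samples) {
  stopifnot(loss >= 0, n_params >= 0)
  if (n_samples <= n_params)
    stop("FPE requires more samples than parameters")
  (loss / n_samples) * (1 + n_params / n_samples) / (1 - n_params / n_samples)
}

#' Mooney-Rivlin linearization diagnostic
#'
#' For data obeying the Mooney-Rivlin stress-stretch law
#' \eqn{\sigma = (C_1 + C_2/\lambda)(\lambda^2 - 1/\lambda)}, plotting
#' \eqn{1/\lambda} against \eqn{\sigma/(\lambda^2 - 1/\lambda)} gives a
#' straight line with intercept \eqn{C_1} and slope \eqn{C_2}; a flat line
#' signals Neo-Hookean behaviour. The transform is singular at
#' \eqn{\lambda = 1}, so points with \eqn{|\lambda - 1| <} `guard` are
#' excluded (their count is reported).
#'
#' @param lam stretch series.
#' @param sigma Eulerian stress series, same length.
#' @param guard half-width of the exclusion band around \eqn{\lambda = 1}.
#' @return List of class `mr_linearization`: `intercept` (\eqn{C_1}),
#'   `slope` (\eqn{C_2}), the transformed cloud `x` (\eqn{1/\lambda}) and
#'   `z`, and `n_excluded`.
#' @export
mr_linearize <- function(lam, sigma, guard = 0.01) {
  stopifnot(length(lam) == length(sigma))
  keep <- abs(lam - 1) >= guard & lam > 0
  n_excluded <- sum(!keep)
  if (sum(keep) < 2)
    stop("fewer than 2 points outside the lambda = 1 guard band")
  x <- 1 / lam[keep]
  z <- sigma[keep] / (lam[keep]^2 - 1 / lam[keep])
  co <- stats::coef(stats::lm(z ~ x))
  out <- list(intercept = unname(co[1]), slope = unname(co[2]),
              x = x, z = z, n_excluded = n_excluded)
  class(out) <- "mr_linearization"
  out
}

#' @export
print.mr_linearization <- function(x, ...) {
  cat(sprintf("Mooney-Rivlin linearization: intercept (C1) = %.4g, slope (C2) = %.4g\n",
              x$intercept, x$slope))
  cat(sprintf("  %d points used, %d excluded near lambda = 1\n",
              length(x$x), x$n_excluded))
  invisible(x)
}

#' @export
plot.mr_linearization <- function(x, ...) {
  graphics::plot(x$x, x$z, xlab = expression(1 / lambda),
                 ylab = expression(sigma / (lambda^2 - 1 / lambda)),
                 main = "Mooney-Rivlin linearization", ...)
  graphics::abline(x$intercept, x$slope, col = "red3")
  invisible(x)
}

#' Dissipated work of a closed strain-load cycle
#'
#' The signed loop integral \eqn{\oint y\, d\epsilon} computed by the
#' shoelace (trapezoid) rule, i.e. the area of the hysteresis loop in the
#' strain-load plane. Positive for a dissipative (viscous) steady-state
#' cycle of a passive model; zero for a purely elastic response. The
#' trajectory must be closed: the first and last points may differ by at
#' most `closure_tol` times the coordinate ranges.
#'
#' @param eps_cycle strain samples of one cycle.
#' @param y_cycle load samples, same length.
#' @param closure_tol relative closure tolerance.
#' @return Signed loop area (N, strain units).
#' @export
hysteresis_area <- function(eps_cycle, y_cycle, closure_tol = 0.02) {
  stopifnot(length(eps_cycle) == length(y_cycle), length(eps_cycle) >= 3)
  gap_e <- abs(eps_cycle[1] - eps_cycle[length(eps_cycle)])
  gap_y <- abs(y_cycle[1] - y_cycle[length(y_cycle)])
  rng_e <- diff(range(eps_cycle)); rng_y <- diff(range(y_cycle))
  if ((rng_e > 0 && gap_e > closure_tol * rng_e) ||
      (rng_y > 0 && gap_y > closure_tol * rng_y))
    stop(sprintf(paste0("open trajectory: endpoint gap is %.3g (strain) / ",
                        "%.3g (load) of the cycle range, closure tolerance %g"),
                 gap_e / max(rng_e, .Machine$double.eps),
                 gap_y / max(rng_y, .Machine$double.eps), closure_tol))
  e <- c(eps_cycle, eps_cycle[1])
  y <- c(y_cycle, y_cycle[1])
  # trapezoid form of the shoelace loop integral, taken in time order:
  # this is the work input per cycle, non-negative for passive parameters
  sum((y[-1] + y[-length(y)]) / 2 * diff(e))
}

#' Split a cyclic record into first compression and cycling parts
#'
#' The analysis of cyclic tests treats (i) the first excursion (first
#' compression) and (ii) the remaining cycling separately. The split point
#' is the first sample at which the compression magnitude (engineering
#' strain) reaches the lower cycle bound.
#'
#' @param ds a [ts_dataset].
#' @param lower_bound lower cycle bound, compression magnitude (fraction).
#' @return List with [ts_dataset] elements `first` and `cycling`.
#' @export
split_first_compression <- function(ds, lower_bound = 0.15) {
  stopifnot(inherits(ds, "ts_dataset"))
  e <- ds$e0 / (1 - ds$strain)
  comp <- -(e - ds$e0) / ds$e0            # engineering compression magnitude
  k <- which(comp >= lower_bound)[1]
  if (is.na(k)) stop("record never reaches the lower cycle bound")
  sub <- function(idx, suffix) ts_dataset(
    ds$t[idx], ds$strain[idx], ds$load[idx], e0 = ds$e0, A0 = ds$A0,
    label = paste0(ds$label, suffix), meta = ds$meta)
  list(first = sub(seq_len(k), "_first"),
       cycling = sub(seq(k, length(ds$t)), "_cycling"))
}
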