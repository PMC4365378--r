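# Continuous-time transfer-function identification in the SRIVC style:
# iterative instrumental-variable estimation with continuous-time
# prefiltering, so that the time derivatives entering the regression are
# obtained by filtering rather than by differencing noisy samples.
#
# Model: ydd + a1 yd + a2 y = b0 udd + b1 ud  (two-Maxwell structure,
# numerator b0 s^2 + b1 s, no static term).

# Filtered signal and its first two "derivatives" through 1/D(s),
# D(s) = s^2 + d1 s + d2: returns f0 = w/D, f1 = s w/D, f2 = s^2 w/D.
svf_filtered <- function(w, t, d1, d2) {
  disc <- d1^2 - 4 * d2
  if (disc > 1e-12 * max(d1^2, 1)) {
    mu <- sort((d1 + c(-1, 1) * sqrt(disc)) / 2)   # D = (s+mu1)(s+mu2)
    if (all(mu > 0) && (mu[2] - mu[1]) > 1e-9 * mu[2]) {
      h1 <- foh_first_order(w, t, mu[1])
      h2 <- foh_first_order(w, t, mu[2])
      f0 <- (h1 - h2) / (mu[2] - mu[1])
      f1 <- (-mu[1] * h1 + mu[2] * h2) / (mu[2] - mu[1])
      return(list(f0 = f0, f1 = f1, f2 = w - d1 * f1 - d2 * f0))
    }
  }
  if (abs(disc) <= 1e-12 * max(d1^2, 1) && d1 > 0) {
    # repeated real pole: cascade of two identical first-order sections
    mu <- d1 / 2
    h1 <- foh_first_order(w, t, mu)
    f0 <- foh_first_order(h1, t, mu)
    f1 <- h1 - mu * f0
    return(list(f0 = f0, f1 = f1, f2 = w - d1 * f1 - d2 * f0))
  }
  # complex (or awkward) poles: generic state-space filtering
  out <- lti_ss_foh(A = matrix(c(0, -d2, 1, -d1), 2, 2), B = c(0, 1),
                    C = c(1, 0), D = 0, u = w, t = t)
  f0 <- out$x[1, ]; f1 <- out$x[2, ]
  list(f0 = f0, f1 = f1, f2 = w - d1 * f1 - d2 * f0)
}

# reflect an estimate into the stable region (a1, a2 > 0)
stabilize_tf <- function(th, floor = 1e-8) {
  proj <- th[1] <= 0 || th[2] <= 0
  th[1] <- max(abs(th[1]), floor)
  th[2] <- max(abs(th[2]), floor)
  list(theta = th, projected = proj)
}

srivc_regression <- function(fy, fu, fz = NULL) {
  Phi <- cbind(-fy$f1, -fy$f0, fu$f2, fu$f1)
  Z <- if (is.null(fz)) Phi else cbind(-fz$f1, -fz$f0, fu$f2, fu$f1)
  M <- crossprod(Z, Phi)
  if (abs(det(M)) < 1e-300 || qr(M)$rank < 4)
    stop("regressor matrix is rank deficient: input does not excite the system")
  as.numeric(solve(M, crossprod(Z, fy$f2)))
}

#' Continuous-time linear identification of the two-Maxwell transfer function
#'
#' Estimates \eqn{(a_1, a_2, b_0, b_1)} of
#' \eqn{\ddot y + a_1\dot y + a_2 y = b_0\ddot u + b_1\dot u} from a sampled
#' strain/load record by iterative instrumental-variable estimation with
#' continuous-time prefiltering: an initial state-variable filter provides
#' least-squares starting values (a small grid of filter cutoffs is tried
#' and the candidate whose model best reproduces the measured output wins);
#' each subsequent iteration refilters the data and the instruments —
#' the noise-free simulated output of the current model — through
#' \eqn{1/\hat A(s)} and re-solves the IV normal equations, until the
#' relative parameter change drops below `tol`. Unstable iterates are
#' reflected into the stable region.
#'
#' @param dataset a [ts_dataset]; input is the strain, output the load.
#' @param max_iter maximum IV iterations.
#' @param tol relative parameter-change convergence tolerance.
#' @param svf_cutoffs optional numeric vector of state-variable-filter
#'   cutoff frequencies (rad/s) to try at initialization; the default is a
#'   log-spaced grid between 2/T_record and a tenth of the sampling rate.
#' @return An object of class `viscofit` with `structure = "linear"`,
#'   holding the estimated [linear_tf], the physical `(g1, g2, tau1, tau2)`
#'   when the poles are real, residuals and the loss.
#' @export
srivc <- function(dataset, max_iter = 50, tol = 1e-6, svf_cutoffs = NULL) {
  stopifnot(inherits(dataset, "ts_dataset"))
  t <- dataset$t; u <- dataset$strain; y <- dataset$load
  if (all(abs(u - u[1]) < 1e-14))
    stop("regressor matrix is rank deficient: input does not excite the system")
  T_rec <- diff(range(t))
  rate <- 1 / stats::median(diff(t))
  if (is.null(svf_cutoffs))
    svf_cutoffs <- exp(seq(log(2 / T_rec), log(max(2 * pi * rate / 10, 4 / T_rec)),
                           length.out = 6))

  sim_tf <- function(th) simulate_lti(linear_tf(th[1], th[2], th[3], th[4]),
                                      u, t)$y
  # initialization: least squares under each candidate SVF, keep the best
  best <- NULL
  for (lam in svf_cutoffs) {
    th <- tryCatch({
      fy <- svf_filtered(y, t, 2 * lam, lam^2)
      fu <- svf_filtered(u, t, 2 * lam, lam^2)
      srivc_regression(fy, fu)
    }, error = function(e) NULL)
    if (is.null(th)) next
    th <- stabilize_tf(th)$theta
    sse <- sum((y - sim_tf(th))^2)
    if (is.finite(sse) && (is.null(best) || sse < best$sse))
      best <- list(theta = th, sse = sse)
  }
  if (is.null(best))
    stop("regressor matrix is rank deficient: input does not excite the system")

  theta <- best$theta
  converged <- FALSE
  projected <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    x_hat <- sim_tf(theta)
    th_new <- tryCatch({
      fy <- svf_filtered(y, t, theta[1], theta[2])
      fu <- svf_filtered(u, t, theta[1], theta[2])
      fz <- svf_filtered(x_hat, t, theta[1], theta[2])
      srivc_regression(fy, fu, fz)
    }, error = function(e) NULL)
    if (is.null(th_new)) break
    st <- stabilize_tf(th_new)
    projected <- st$projected
    th_new <- st$theta
    delta <- max(abs(th_new - theta) / pmax(abs(theta), 1e-12))
    theta <- th_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (projected)
    warning("unstable estimate projected to the stable region")
  if (!converged && n_iter >= max_iter)
    warning("srivc did not converge in ", max_iter,
            " iterations; returning best iterate")

  tf <- linear_tf(theta[1], theta[2], theta[3], theta[4])
  phys <- tryCatch(tf_to_maxwell(tf), error = function(e) NULL)
  y_hat <- sim_tf(theta)
  res <- y - y_hat
  structure(list(
    structure = "linear", tf = tf, params = phys,
    free = c("a1", "a2", "b0", "b1"), fixed = character(),
    fitted = y_hat, residuals = res, loss = sum(res^2),
    n_iter = n_iter, converged = converged, projected = projected,
    data = dataset, call = match.call()
  ), class = "viscofit")
}
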