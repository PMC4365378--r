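# Grey-box prediction-error minimisation: the model structure (the
# physical ODEs) is fixed, free parameters are estimated by
# Levenberg-Marquardt on the simulated-output residuals. Every residual
# evaluation is a full forward simulation.

structure_param_names <- function(structure) {
  switch(structure,
    model1 = ,
    model1_neohookean = c("C1", "C2", "g1", "g2", "tau1", "tau2"),
    hammerstein = c("p0", "p1", "p2", "g1", "g2", "tau1", "tau2"),
    stop("unknown grey-box structure: ", structure))
}

# positive parameters are optimised on the log scale
positive_params <- c("g1", "g2", "tau1", "tau2")

build_params <- function(structure, vals, e0, A0) {
  if (structure %in% c("model1", "model1_neohookean"))
    model1_params(vals[["C1"]], vals[["C2"]], vals[["g1"]], vals[["g2"]],
                  vals[["tau1"]], vals[["tau2"]], e0 = e0, A0 = A0)
  else
    model2_params(vals[["p0"]], vals[["p1"]], vals[["p2"]],
                  vals[["g1"]], vals[["g2"]],
                  vals[["tau1"]], vals[["tau2"]], A0 = A0)
}

# random log-uniform / uniform initialisation within broad physical bounds
random_init <- function(structure, dataset, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  T_rec <- diff(range(dataset$t))
  taus <- sort(exp(stats::runif(2, log(0.05 * T_rec / 50), log(0.5 * T_rec))))
  gs <- exp(stats::runif(2, log(0.01), log(100)))
  if (structure %in% c("model1", "model1_neohookean")) {
    cs <- stats::runif(2, -10, 10)
    init <- list(C1 = cs[1], C2 = if (structure == "model1") cs[2] else 0,
                 g1 = gs[1], g2 = gs[2], tau1 = taus[1], tau2 = taus[2])
  } else {
    ps <- stats::runif(3, -10, 10)
    init <- list(p0 = ps[1], p1 = ps[2], p2 = ps[3],
                 g1 = gs[1], g2 = gs[2], tau1 = taus[1], tau2 = taus[2])
  }
  init
}

#' Grey-box Levenberg-Marquardt fit of a nonlinear viscoelastic model
#'
#' Minimises the sum of squared prediction errors
#' \eqn{\sum_k (y_{meas}(t_k) - y_{model}(t_k))^2} over the free parameters
#' of the chosen structure, with a full forward simulation per residual
#' evaluation (numeric Jacobians). Parameters named in `fixed` are held at
#' their `init` values — the identifiability normalization: model 1 carries
#' an exact scale ridge \eqn{(C, g) \to (kC, g/k)} and the Hammerstein
#' model the analogous \eqn{(p, g)} ridge, so one scale parameter must be
#' pinned for a unique estimate. Positive parameters (`g1`, `g2`, `tau1`,
#' `tau2`) are optimised on the log scale. A failed simulation inside a
#' trial step returns a large finite penalty, which makes the
#' Levenberg-Marquardt damping increase and the step get rejected.
#'
#' @param dataset a [ts_dataset].
#' @param structure `"model1"`, `"model1_neohookean"` or `"hammerstein"`.
#' @param init named list of initial values for all structure parameters;
#'   `NULL` draws a random seed-controlled initialisation within broad
#'   physical bounds.
#' @param fixed character vector of parameter names held constant.
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @param tol relative convergence tolerance (ftol/ptol).
#' @param seed used only when `init` is `NULL`.
#' @return An object of class `viscofit`.
#' @export
fit_greybox <- function(dataset, structure, init = NULL, fixed = character(),
                        max_iter = 100, tol = 1e-10, seed = NULL) {
  stopifnot(inherits(dataset, "ts_dataset"))
  pnames <- structure_param_names(structure)
  if (structure == "model1_neohookean") fixed <- union(fixed, "C2")
  if (is.null(init)) init <- random_init(structure, dataset, seed)
  if (structure == "model1_neohookean") init$C2 <- 0
  if (!all(pnames %in% names(init)))
    stop("'init' must name all parameters: ", paste(pnames, collapse = ", "))
  if (!all(fixed %in% pnames))
    stop("'fixed' must be a subset of the structure parameters")
  free <- setdiff(pnames, fixed)

  kin <- dataset_kinematics(dataset)
  y <- dataset$load
  vals0 <- init[pnames]
  uselog <- free %in% positive_params & unlist(vals0[free]) > 0
  enc <- function(v) { v[uselog] <- log(v[uselog]); v }
  dec <- function(p) { p[uselog] <- exp(p[uselog]); p }

  resfun <- function(p) {
    vals <- vals0
    vals[free] <- as.list(dec(p))
    r <- tryCatch({
      pr <- build_params(structure, vals, e0 = dataset$e0, A0 = dataset$A0)
      y - simulate_structure(structure, pr, kin)$y
    }, error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) rep(1e6, length(y)) else r
  }

  if (length(free) == 0L) {
    r <- resfun(numeric(0))
    out <- list(par = numeric(0), niter = 0L, info = 1L, rsstrace = sum(r^2))
  } else {
    out <- minpack.lm::nls.lm(
      par = enc(unlist(vals0[free])), fn = resfun,
      control = minpack.lm::nls.lm.control(
        maxiter = max_iter, ftol = tol, ptol = tol, gtol = 0))
  }

  vals <- vals0
  if (length(free)) vals[free] <- as.list(dec(out$par))
  pr <- build_params(structure, vals, e0 = dataset$e0, A0 = dataset$A0)
  res <- resfun(if (length(free)) out$par else numeric(0))
  y_hat <- y - res
  fit <- list(
    structure = structure, params = vals, param_obj = pr,
    free = free, fixed = fixed,
    fitted = y_hat, residuals = res, loss = sum(res^2),
    n_iter = out$niter, converged = out$info %in% 1:4,
    rsstrace = out$rsstrace,
    data = dataset, call = match.call())
  class(fit) <- "viscofit"
  fit
}
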