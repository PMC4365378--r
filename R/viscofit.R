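#' Fit a viscoelastic compression model to a test record
#'
#' The single identification front-end. `structure = "linear"` estimates
#' the second-order continuous-time two-Maxwell transfer function by the
#' iterative instrumental-variable scheme of [srivc]; the nonlinear
#' structures (`"model1"`, its Neo-Hookean special case, `"hammerstein"`)
#' are estimated by grey-box Levenberg-Marquardt prediction-error
#' minimisation via [fit_greybox]. Following the identification procedure
#' used for these gels, the time constants of a model-1 fit are typically
#' fixed at the values of a prior linear fit (pass them in `init` and name
#' them in `fixed`); releasing them is allowed.
#'
#' @param data a [ts_dataset] (input = strain, output = load).
#' @param structure one of `"linear"`, `"model1"`, `"model1_neohookean"`,
#'   `"hammerstein"`.
#' @param init named list of initial parameter values (grey-box
#'   structures); `NULL` draws a seed-controlled random initialisation.
#' @param fixed character vector of parameters held at their `init` values
#'   (identifiability normalization; see [fit_greybox]).
#' @param ... further arguments passed to [srivc] or [fit_greybox]
#'   (`max_iter`, `tol`, `seed`, `svf_cutoffs`).
#' @return An object of class `viscofit` with methods `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals`, `plot`, `simulate` and
#'   [validate].
#' @examples
#' spec <- protocol_spec("cycles", crosshead_speed = 1)
#' truth <- maxwell_to_tf(1, 1, 1, 20)
#' ds <- generate_dataset("linear", truth, spec, seed = 7)
#' fit <- viscofit(ds, "linear")
#' coef(fit)
#' @export
viscofit <- function(data, structure = c("linear", "model1",
                                         "model1_neohookean", "hammerstein"),
                     init = NULL, fixed = character(), ...) {
  structure <- match.arg(structure)
  if (structure == "linear") srivc(data, ...)
  else fit_greybox(data, structure, init = init, fixed = fixed, ...)
}

#' @export
coef.viscofit <- function(object, ...) {
  if (object$structure == "linear") {
    out <- unlist(object$tf[c("a1", "a2", "b0", "b1")])
    if (!is.null(object$params))
      out <- c(out, unlist(object$params))
    out
  } else {
    drop_geo <- setdiff(names(object$params), c("e0", "A0"))
    unlist(object$params[drop_geo])
  }
}

#' @export
fitted.viscofit <- function(object, ...) object$fitted

#' @export
residuals.viscofit <- function(object, ...) object$residuals

#' Predict the load response on a new record or protocol
#'
#' Pure forward simulation of the fitted model: no re-fitting. `newdata`
#' may be a [ts_dataset] (its strain trajectory is used), a
#' [kinematic_signal], or a [protocol_spec] (the protocol waveform is
#' generated first).
#'
#' @param object a `viscofit`.
#' @param newdata input record; `NULL` predicts on the identification data.
#' @param ... unused.
#' @return Numeric vector of predicted loads (N).
#' @export
predict.viscofit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  kin <- if (inherits(newdata, "kinematic_signal")) newdata
         else if (inherits(newdata, "ts_dataset")) dataset_kinematics(newdata)
         else if (inherits(newdata, "protocol_spec")) make_protocol_signal(newdata)
         else stop("'newdata' must be a ts_dataset, kinematic_signal or protocol_spec")
  if (object$structure == "linear")
    simulate_lti(object$tf, kin$eps, kin$t)$y
  else
    simulate_structure(object$structure, object$param_obj, kin)$y
}

#' @export
print.viscofit <- function(x, ...) {
  cat("Viscoelastic model fit (", x$structure, " structure)\n", sep = "")
  if (x$structure == "linear") {
    print(x$tf)
    if (!is.null(x$params))
      cat(sprintf("  physical: g1 = %.4g, g2 = %.4g, tau1 = %.4g s, tau2 = %.4g s\n",
                  x$params$g1, x$params$g2, x$params$tau1, x$params$tau2))
  } else {
    cf <- coef(x)
    cat("  ", paste(sprintf("%s = %.4g", names(cf), cf), collapse = ", "), "\n")
    if (length(x$fixed))
      cat("  fixed:", paste(x$fixed, collapse = ", "), "\n")
  }
  cat(sprintf("  loss = %.6g on %d samples; %d iterations, %sconverged\n",
              x$loss, length(x$residuals), x$n_iter,
              if (x$converged) "" else "NOT "))
  invisible(x)
}

#' @export
summary.viscofit <- function(object, ...) {
  s <- list(fit = object,
            fit_percent = fit_percent(object$fitted, object$data$load),
            sigma = stats::sd(object$residuals),
            n = length(object$residuals))
  class(s) <- "summary.viscofit"
  s
}

#' @export
print.summary.viscofit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  identification-data FIT = %.1f%%; residual sd = %.4g N\n",
              x$fit_percent, x$sigma))
  invisible(x)
}

#' @export
plot.viscofit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$data$t, x$data$load, type = "l", col = "grey40",
                 xlab = "time (s)", ylab = "load (N)",
                 main = paste("Measured vs fitted -", x$structure), ...)
  graphics::lines(x$data$t, x$fitted, col = "red3")
  graphics::legend("topright", c("measured", "model"), lty = 1,
                   col = c("grey40", "red3"), bty = "n")
  graphics::plot(x$data$t, x$residuals, type = "l",
                 xlab = "time (s)", ylab = "residual (N)")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Simulate new noisy records from a fitted model
#'
#' Applies the fitted model to a protocol (defaulting to the protocol of
#' the identification record when available) and adds Gaussian measurement
#' noise, mirroring how the synthetic records are produced.
#'
#' @param object a `viscofit`.
#' @param nsim number of records.
#' @param seed integer seed.
#' @param newdata a [protocol_spec]; `NULL` reuses the identification
#'   record's protocol.
#' @param noise_sd load-noise standard deviation; `NULL` for 1% of peak.
#' @param ... unused.
#' @return A list of `nsim` [ts_dataset] objects.
#' @export
simulate.viscofit <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                              noise_sd = NULL, ...) {
  spec <- newdata %||% (if (!is.null(object$data$meta$protocol))
    do.call(protocol_spec, object$data$meta$protocol) else
      stop("no protocol available: supply 'newdata'"))
  params <- if (object$structure == "linear") object$tf else object$param_obj
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    generate_dataset(object$structure, params, spec, noise_sd = noise_sd,
                     label = paste0("sim", i)))
}

#' Validate a fitted model on an independent record
#'
#' The measured input of `newdata` is applied to the identified model and
#' the simulated output compared with the measured one through the FIT
#' metric — validation is never a re-fit. Records sharing the label of the
#' identification data are refused: validation must be performed on data
#' disjoint from identification.
#'
#' @param object a `viscofit`.
#' @param newdata a [ts_dataset] with a label different from the
#'   identification record's.
#' @param ... unused.
#' @return A list with `fit_percent`, the predicted load `y_model`, and
#'   the validation `label`, of class `viscofit_validation`.
#' @export
validate <- function(object, newdata, ...) UseMethod("validate")

#' @rdname validate
#' @export
validate.viscofit <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "ts_dataset"))
  if (identical(newdata$label, object$data$label))
    stop("validation data shares the identification label '",
         newdata$label, "': independent data required")
  y_model <- predict(object, newdata)
  out <- list(fit_percent = fit_percent(y_model, newdata$load),
              y_model = y_model, label = newdata$label,
              structure = object$structure)
  class(out) <- "viscofit_validation"
  out
}

#' @export
print.viscofit_validation <- function(x, ...) {
  cat(sprintf("Validation of %s model on '%s': FIT = %.1f%%\n",
              x$structure, x$label, x$fit_percent))
  invisible(x)
}
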