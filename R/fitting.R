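# Parameter identification by Levenberg-Marquardt least squares.
#
# Parameters are fitted on the log scale (so bounds and positivity are
# natural) against one or more concentration-time datasets, with the
# objective being the sum of squared residuals on log concentrations by
# default (uniform weights).

#' Construct a fit specification
#'
#' @param parameters data.frame with columns `name` (addressable
#'   scenario parameter, see [scenario_parameter()]), `init`, `lower`,
#'   `upper`. May have zero rows.
#' @param data list of datasets, each a list with `compound` (profile
#'   name in the simulation output), `times_h` and `conc_nmol_L`.
#' @param sc the base [scenario()].
#' @param objective `"log"` (least squares on log concentrations,
#'   default) or `"linear"`.
#' @param duration_h simulation duration used during fitting.
#' @return object of class `fit_spec`.
#' @export
fit_spec <- function(parameters, data, sc, objective = c("log", "linear"),
                     duration_h = 96) {
  objective <- match.arg(objective)
  stopifnot(is.data.frame(parameters),
            all(c("name", "init", "lower", "upper") %in%
                  names(parameters)))
  if (nrow(parameters) > 0) {
    bad <- parameters$init < parameters$lower |
      parameters$init > parameters$upper
    if (any(bad)) {
      stop("initial value outside bounds for: ",
           paste(parameters$name[bad], collapse = ", "), call. = FALSE)
    }
  }
  npoints <- sum(vapply(data, function(d) length(d$times_h), integer(1)))
  if (nrow(parameters) > 0 && npoints < nrow(parameters)) {
    stop("need at least one data point per fitted parameter",
         call. = FALSE)
  }
  structure(list(parameters = parameters, data = data, sc = sc,
                 objective = objective, duration_h = duration_h),
            class = "fit_spec")
}

apply_fit_parameters <- function(sc, names, values) {
  for (i in seq_along(names)) {
    sc <- set_scenario_parameter(sc, names[i], values[i])
  }
  sc
}

fit_residuals <- function(spec, values) {
  sc <- apply_fit_parameters(spec$sc, spec$parameters$name, values)
  times <- sort(unique(unlist(lapply(spec$data, `[[`, "times_h"))))
  sim <- simulate_scenario(sc, duration_h = max(spec$duration_h, times),
                           output_grid_h = times)
  unlist(lapply(spec$data, function(d) {
    prof <- sim$profiles[[d$compound]]
    pred <- prof$conc_nmol_L[match(d$times_h, prof$time_h)]
    if (spec$objective == "log") {
      log(pmax(pred, 1e-12)) - log(pmax(d$conc_nmol_L, 1e-12))
    } else {
      pred - d$conc_nmol_L
    }
  }))
}

#' Fit model parameters to concentration-time data
#'
#' Minimises the least-squares objective with the Levenberg-Marquardt
#' algorithm (`minpack.lm::nls.lm`) over log-transformed parameters, so
#' box bounds are respected by construction. Deterministic for fixed
#' data, initial values and solver settings. On non-convergence the best
#' iterate is returned with `converged = FALSE`.
#'
#' @param spec a [fit_spec()].
#' @return list with `values` (named fitted parameter vector),
#'   `converged`, `message`, `iterations`, `objective_trace` (sum of
#'   squared residuals per accepted iteration), `residual` (final sum of
#'   squares) and `scenario` (the scenario at the fitted values).
#' @export
fit_parameters <- function(spec) {
  stopifnot(inherits(spec, "fit_spec"))
  pars <- spec$parameters
  if (nrow(pars) == 0) {
    return(list(values = stats::setNames(numeric(0), character(0)),
                converged = TRUE, message = "no parameters to fit",
                iterations = 0L, objective_trace = numeric(0),
                residual = sum(fit_residuals(spec, numeric(0))^2),
                scenario = spec$sc))
  }
  fn <- function(theta) fit_residuals(spec, exp(theta))
  res <- minpack.lm::nls.lm(
    par = log(pars$init), fn = fn,
    lower = log(pars$lower), upper = log(pars$upper),
    control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-10,
                                         ptol = 1e-10))
  values <- stats::setNames(exp(res$par), pars$name)
  list(values = values,
       converged = res$info %in% 1:4,
       message = res$message,
       iterations = res$niter,
       objective_trace = res$rsstrace,
       residual = res$deviance,
       scenario = apply_fit_parameters(spec$sc, pars$name, values))
}
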