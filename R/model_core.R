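#' @useDynLib odemval
#' @importFrom stats median quantile rnorm runif setNames cor
#' @importFrom utils read.csv write.csv
NULL

#' Experimental condition
#'
#' A condition is one experimental context of the osmostress benchmark: which
#' of the two upstream activation routes (the Sln1 route and the Sho1 route)
#' is genetically active, and the NaCl dose applied as the osmotic shock.
#' The three cell types of the study are encoded as \code{Sln1} mutant
#' (1, 0), \code{Sho1} mutant (0, 1) and wild type (1, 1).
#'
#' @param sln1_active 0/1 flag, activity of the Sln1 route.
#' @param sho1_active 0/1 flag, activity of the Sho1 route.
#' @param dose NaCl concentration in molar; must be positive.
#' @return An object of class \code{odem_condition}.
#' @examples
#' condition(1, 1, 0.5)       # wild type at 0.5 M
#' condition_for("Sho1", 0.07)
#' @export
condition <- function(sln1_active, sho1_active, dose) {
  if (!sln1_active %in% c(0, 1) || !sho1_active %in% c(0, 1))
    stop("branch activity flags must be 0 or 1")
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose <= 0)
    stop("dose must be a single positive number (molar)")
  structure(list(sln1_active = as.numeric(sln1_active),
                 sho1_active = as.numeric(sho1_active),
                 dose = dose),
            class = "odem_condition")
}

#' @export
print.odem_condition <- function(x, ...) {
  cat(sprintf("condition: sln1=%d sho1=%d dose=%.3g M\n",
              as.integer(x$sln1_active), as.integer(x$sho1_active), x$dose))
  invisible(x)
}

# branch-activity flags of the three named cell types
.cell_type_flags <- list(Sln1 = c(1, 0), Sho1 = c(0, 1), WT = c(1, 1))

#' @rdname condition
#' @param cell_type one of \code{"Sln1"}, \code{"Sho1"}, \code{"WT"}.
#' @export
condition_for <- function(cell_type, dose) {
  fl <- .cell_type_flags[[cell_type]]
  if (is.null(fl)) stop("unknown cell type: ", cell_type)
  condition(fl[1], fl[2], dose)
}

#' Cell types known to the benchmark design
#' @return Character vector of cell-type labels.
#' @export
cell_types <- function() names(.cell_type_flags)

#' Parameter set with box bounds
#'
#' Holds a named vector of nonnegative rate constants together with
#' per-parameter lower/upper bounds used by the bounded least-squares fit.
#'
#' @param values named numeric vector of parameter values.
#' @param lower,upper bounds, recycled to \code{length(values)}; lower bounds
#'   must be nonnegative and the values must lie inside the bounds.
#' @return An object of class \code{odem_parameter_set}.
#' @export
parameter_set <- function(values, lower = 0, upper = Inf) {
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("parameter values must be named")
  lower <- rep_len(lower, length(values))
  upper <- rep_len(upper, length(values))
  if (any(lower < 0)) stop("lower bounds must be nonnegative")
  if (any(values < lower - 1e-12) || any(values > upper + 1e-12))
    stop("parameter values must lie within their bounds")
  structure(list(values = values,
                 lower = setNames(lower, names(values)),
                 upper = setNames(upper, names(values))),
            class = "odem_parameter_set")
}

#' @export
print.odem_parameter_set <- function(x, ...) {
  cat("parameter set (", length(x$values), " parameters)\n", sep = "")
  print(data.frame(value = x$values, lower = x$lower, upper = x$upper))
  invisible(x)
}

param_values <- function(params) {
  if (inherits(params, "odem_parameter_set")) params$values else params
}

#' ODE model structure
#'
#' A model structure bundles the pieces needed to simulate one candidate
#' kinetic model: state and parameter names, a deterministic right-hand side,
#' an observation map from the state trajectory to named observables, and an
#' initial-state rule.  The right-hand side may be an R function
#' \code{function(t, state, params, condition)} returning the derivative
#' vector, or a compiled-code specification (as used by the built-in
#' benchmark) of the form \code{list(func=, initfunc=, dllname=)} together
#' with a \code{map_params} function that assembles the full low-level
#' parameter vector (fixed constants and condition inputs included) from the
#' free parameter values and the condition.
#'
#' @param name identifier for the structure.
#' @param state_names ordered character vector of state names.
#' @param parameter_names ordered character vector of free-parameter names.
#' @param rhs R right-hand-side function, or \code{NULL} when compiled.
#' @param observe function mapping the deSolve output matrix to a data frame
#'   of observables (must keep a \code{time} column).
#' @param initial_state function mapping a condition to a named state vector.
#' @param compiled optional compiled-code specification (see Details).
#' @param map_params optional function \code{(values, condition) -> numeric}
#'   for compiled models.
#' @param obs_map optional named character vector mapping observable names
#'   to solver output columns; enables a fast prediction path inside the
#'   fitting loop that bypasses the full observation function.
#' @return An object of class \code{odem_model}.
#' @export
model_structure <- function(name, state_names, parameter_names, rhs = NULL,
                            observe, initial_state, compiled = NULL,
                            map_params = NULL, obs_map = NULL) {
  if (is.null(rhs) && is.null(compiled))
    stop("either an R rhs function or a compiled specification is required")
  if (!is.null(compiled) && is.null(map_params))
    stop("compiled models need a map_params function")
  structure(list(name = name,
                 state_names = state_names,
                 parameter_names = parameter_names,
                 rhs = rhs,
                 observe = observe,
                 initial_state = initial_state,
                 compiled = compiled,
                 map_params = map_params,
                 obs_map = obs_map),
            class = "odem_model")
}

#' @export
print.odem_model <- function(x, ...) {
  cat(sprintf("ODE model structure '%s': %d states, %d free parameters (%s)\n",
              x$name, length(x$state_names), length(x$parameter_names),
              if (is.null(x$compiled)) "R rhs" else "compiled rhs"))
  invisible(x)
}

#' Simulate a model structure at one condition
#'
#' Integrates the model with a stiff-capable solver (\code{deSolve::lsoda})
#' and returns the observable trajectories at the requested times.  The
#' result is deterministic given identical inputs and tolerances.
#'
#' @param model an \code{odem_model}.
#' @param params an \code{odem_parameter_set} or named numeric vector aligned
#'   with \code{model$parameter_names}.
#' @param condition an \code{odem_condition}.
#' @param times increasing time grid in minutes, \code{times[1] >= 0}.
#' @param rtol,atol integrator tolerances.
#' @return A data frame with a \code{time} column and one column per
#'   observable.
#' @export
simulate_model <- function(model, params, condition, times,
                           rtol = 1e-8, atol = 1e-10) {
  values <- param_values(params)
  if (!all(model$parameter_names %in% names(values)))
    stop("missing parameters: ",
         paste(setdiff(model$parameter_names, names(values)), collapse = ", "))
  values <- values[model$parameter_names]
  if (any(!is.finite(values))) stop("non-finite parameter values")
  if (is.unsorted(times, strictly = TRUE) || times[1] < 0)
    stop("times must be strictly increasing and start at t >= 0")
  y0 <- model$initial_state(condition)

  fail <- function(why) {
    stop(sprintf(
      "integration failure (%s) for model '%s' at condition sln1=%d sho1=%d dose=%.3g",
      why, model$name, as.integer(condition$sln1_active),
      as.integer(condition$sho1_active), condition$dose), call. = FALSE)
  }

  # lsoda reports trouble via warnings and possibly a truncated output matrix
  warned <- character(0)
  out <- withCallingHandlers(
    tryCatch({
      if (!is.null(model$compiled)) {
        parms <- model$map_params(values, condition)
        deSolve::lsoda(y0, times, func = model$compiled$func, parms = parms,
                       dllname = model$compiled$dllname,
                       initfunc = model$compiled$initfunc,
                       rtol = rtol, atol = atol)
      } else {
        fn <- function(t, y, parms) list(model$rhs(t, y, values, condition))
        deSolve::lsoda(y0, times, func = fn, parms = NULL,
                       rtol = rtol, atol = atol)
      }
    }, error = function(e) fail(conditionMessage(e))),
    warning = function(w) {
      warned <<- c(warned, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (nrow(out) < length(times)) fail("solver stopped early")
  if (any(!is.finite(out))) fail("non-finite state values")
  obs <- model$observe(out)
  if (any(!is.finite(as.matrix(obs)))) fail("non-finite observables")
  obs
}

# lean prediction path for the fitting loop: integrates once and returns the
# raw solver matrix; callers extract observable columns via model$obs_map.
# Errors (integration failure, non-finite output) propagate as conditions
# for the caller's penalty handling.
sim_raw <- function(model, values, condition, times, rtol, atol) {
  y0 <- model$initial_state(condition)
  out <- suppressWarnings({
    if (!is.null(model$compiled)) {
      parms <- model$map_params(values, condition)
      deSolve::lsoda(y0, times, func = model$compiled$func, parms = parms,
                     dllname = model$compiled$dllname,
                     initfunc = model$compiled$initfunc,
                     rtol = rtol, atol = atol)
    } else {
      fn <- function(t, y, parms) list(model$rhs(t, y, values, condition))
      deSolve::lsoda(y0, times, func = fn, parms = NULL,
                     rtol = rtol, atol = atol)
    }
  })
  if (nrow(out) < length(times) || any(!is.finite(out)))
    stop("integration failure")
  out
}

# observable vectors at `times`, using the fast column map when available
sim_observables <- function(model, values, condition, times, rtol, atol) {
  if (!is.null(model$obs_map)) {
    out <- sim_raw(model, values, condition, times, rtol, atol)
    lapply(as.list(model$obs_map), function(col) out[, col])
  } else {
    as.list(simulate_model(model, values, condition, times,
                           rtol = rtol, atol = atol))
  }
}
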