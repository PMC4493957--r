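# Bounded nonlinear least-squares parameter estimation and Fisher-information
# identifiability.  The optimizer backend is minpack.lm::nls.lm, a bounded
# Levenberg-Marquardt trust-region implementation (the R analogue of Matlab's
# lsqnonlin used in this kind of study).

#' Fitting options
#'
#' @param start_mode \code{"fixed"} starts the optimizer at the supplied
#'   point (normally the generating parameters, the study's main protocol);
#'   \code{"multi"} is the multi-start protocol of
#'   \code{\link{multistart_fit}}.
#' @param n_starts number of random starting points in multi-start mode.
#' @param bounds_mode how fitting bounds are derived from a reference
#'   parameter set when the set carries none: \code{"wide"} uses [0, 10p],
#'   \code{"double"} the prior-information protocol (0, 2p].
#' @param weighting \code{"none"} (default) minimizes raw residuals;
#'   \code{"relative"} divides each residual by the absolute value of its
#'   datum (zero-valued data keep unit weight), which matches the
#'   proportional noise model and makes the estimator asymptotically
#'   efficient with respect to the Fisher information of
#'   \code{\link{fisher_sd}}.
#' @param maxiter,ftol,ptol optimizer limits and tolerances
#'   (see \code{minpack.lm::nls.lm.control}).
#' @param rtol,atol integrator tolerances used inside the residual function.
#' @return A list of class \code{odem_fit_options}.
#' @export
fit_options <- function(start_mode = c("fixed", "multi"), n_starts = 80,
                        bounds_mode = c("wide", "double"),
                        weighting = c("none", "relative"),
                        maxiter = 100, ftol = 1e-8, ptol = 1e-8,
                        rtol = 1e-8, atol = 1e-10) {
  if (n_starts < 1) stop("n_starts must be >= 1")
  structure(list(start_mode = match.arg(start_mode), n_starts = n_starts,
                 bounds_mode = match.arg(bounds_mode),
                 weighting = match.arg(weighting),
                 maxiter = maxiter, ftol = ftol, ptol = ptol,
                 rtol = rtol, atol = atol),
            class = "odem_fit_options")
}

# group training subsets by condition so each condition is integrated once
group_by_condition <- function(training) {
  keys <- vapply(training, function(s) paste(s$cell_type, s$dose), "")
  split(seq_along(training), keys)
}

# stacked model predictions at the data points of all training subsets,
# in a fixed order (subsets as given, times within subset)
stacked_predictions <- function(model, values, training, groups,
                                rtol, atol) {
  out <- vector("list", length(training))
  for (g in groups) {
    times <- sort(unique(unlist(lapply(training[g], function(s) s$times))))
    sim <- sim_observables(model, values, subset_condition(training[[g[1]]]),
                           times, rtol = rtol, atol = atol)
    for (i in g) {
      idx <- match(training[[i]]$times, times)
      out[[i]] <- sim[[training[[i]]$observable]][idx]
    }
  }
  unlist(out)
}

#' Fit a model structure to a training set
#'
#' Minimizes the stacked residual vector (data minus prediction over all
#' training subsets, the always-present downstream subsets included) by
#' bounded Levenberg-Marquardt least squares.  Residuals are unweighted raw
#' differences by default; see the \code{weighting} fit option for the
#' relative (proportional-noise-matched) alternative.  Integration failures at a trial point are mapped to a large
#' residual penalty (and counted) rather than aborting the fit; optimizer
#' non-convergence is reported through the \code{converged} flag, never as
#' an error.
#'
#' @param model an \code{odem_model}.
#' @param training list of \code{odem_subset} objects (Hog1PP training
#'   subsets plus downstream subsets).
#' @param start starting \code{odem_parameter_set}; its bounds are the
#'   fitting bounds (non-finite uppers are replaced per
#'   \code{options$bounds_mode}).
#' @param options an \code{odem_fit_options}.
#' @return A list of class \code{odem_fit}: \code{estimates}
#'   (\code{odem_parameter_set}), \code{residual_ss}, \code{converged},
#'   \code{n_function_evals}, \code{start_point}, \code{n_penalty},
#'   \code{message}.
#' @export
fit_model <- function(model, training, start, options = fit_options()) {
  values0 <- start$values[model$parameter_names]
  if (any(is.na(values0)))
    stop("start does not cover the model's parameters")
  lower <- start$lower[model$parameter_names]
  upper <- start$upper[model$parameter_names]
  bad <- !is.finite(upper)
  if (any(bad))
    upper[bad] <- switch(options$bounds_mode,
                         wide = pmax(10 * values0[bad], 1),
                         double = 2 * values0[bad])
  groups <- group_by_condition(training)
  data_vec <- unlist(lapply(training, function(s) s$values))
  wts <- if (options$weighting == "relative") {
    ifelse(data_vec == 0, 1, 1 / abs(data_vec))
  } else rep(1, length(data_vec))
  n_penalty <- 0L
  resid_fn <- function(par) {
    names(par) <- model$parameter_names
    pred <- tryCatch(
      stacked_predictions(model, par, training, groups,
                          options$rtol, options$atol),
      error = function(e) {
        n_penalty <<- n_penalty + 1L
        NULL
      })
    if (is.null(pred)) return(rep(1e6, length(data_vec)))
    (data_vec - pred) * wts
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = options$maxiter,
                                     ftol = options$ftol,
                                     ptol = options$ptol)
  res <- minpack.lm::nls.lm(par = values0, fn = resid_fn,
                            lower = unname(lower), upper = unname(upper),
                            control = ctrl)
  est <- setNames(pmin(pmax(res$par, lower), upper), model$parameter_names)
  if (n_penalty > 0)
    warning(sprintf("fit of '%s': %d trial point(s) hit an integration failure penalty",
                    model$name, n_penalty))
  structure(list(
    estimates = parameter_set(est, lower = lower, upper = upper),
    residual_ss = res$deviance,
    converged = res$info %in% 1:4,
    n_function_evals = res$niter,
    start_point = values0,
    n_penalty = n_penalty,
    message = res$message), class = "odem_fit")
}

#' @export
print.odem_fit <- function(x, ...) {
  cat(sprintf("fit: rss = %.6g, converged = %s (%d iterations)\n",
              x$residual_ss, x$converged, x$n_function_evals))
  invisible(x)
}

#' Multi-start fitting protocol
#'
#' Emulates the realistic setting in which only parameter ranges are known:
#' bounds are taken as (0, 2 p_true] per parameter, \code{n_starts} starting
#' points are drawn uniformly in those ranges (seeded), and each is fitted
#' with \code{\link{fit_model}}.  The summary reports the fraction of runs
#' whose final residual sum of squares lies within \code{rss_tol} (relative)
#' of the best minimum found, and the minimum pairwise correlation among the
#' estimate vectors of the runs that coincide with the best minimum to the
#' tighter tolerance \code{cor_tol}.  Two tolerances are used because they
#' answer different questions: \code{rss_tol} (1 percent) counts runs that
#' reached the optimal basin in a practical sense, while the correlation is
#' meaningful only among runs that genuinely found the same minimum — for a
#' sloppy model, fits differing by a percent in residual can sit far apart
#' along weakly identified parameter directions.
#'
#' @param model,training as in \code{\link{fit_model}}.
#' @param true_params generating \code{odem_parameter_set}; bounds are
#'   derived from its values.
#' @param options an \code{odem_fit_options} (\code{n_starts} is used).
#' @param seed integer seed for the start draws.
#' @param rss_tol relative tolerance defining "reached the best minimum"
#'   (default 1 percent).
#' @param cor_tol tighter relative tolerance defining "same minimum" for
#'   the estimate-correlation summary (default 0.1 percent).
#' @return A list of class \code{odem_multistart}: \code{fits},
#'   \code{best_rss}, \code{fraction_best}, \code{min_correlation},
#'   \code{n_at_same_minimum}, \code{starts}.
#' @export
multistart_fit <- function(model, training, true_params,
                           options = fit_options(start_mode = "multi"),
                           seed = 1, rss_tol = 0.01, cor_tol = 1e-3) {
  p_true <- true_params$values[model$parameter_names]
  upper <- 2 * p_true
  lower <- rep(.Machine$double.eps, length(p_true))
  set.seed(seed)
  starts <- matrix(runif(options$n_starts * length(p_true)),
                   nrow = options$n_starts)
  starts <- sweep(starts, 2, upper, `*`)
  colnames(starts) <- model$parameter_names
  fits <- lapply(seq_len(options$n_starts), function(i) {
    sp <- parameter_set(pmax(starts[i, ], lower), lower = lower, upper = upper)
    fit_model(model, training, sp, options)
  })
  rss <- vapply(fits, function(f) f$residual_ss, numeric(1))
  best <- min(rss)
  at_best <- rss <= best * (1 + rss_tol)
  same_min <- rss <= best * (1 + cor_tol)
  est <- t(vapply(fits[same_min], function(f) f$estimates$values,
                  numeric(length(p_true))))
  min_cor <- if (nrow(est) > 1 && ncol(est) > 1) min(cor(t(est))) else 1
  structure(list(fits = fits, best_rss = best,
                 fraction_best = mean(at_best),
                 min_correlation = min_cor,
                 n_at_same_minimum = sum(same_min),
                 starts = starts, seed = seed),
            class = "odem_multistart")
}

#' @export
print.odem_multistart <- function(x, ...) {
  cat(sprintf(
    "multi-start fit: %d starts, best rss = %.6g, %.0f%% reached it (min estimate correlation %.3f)\n",
    length(x$fits), x$best_rss, 100 * x$fraction_best, x$min_correlation))
  invisible(x)
}

#' Fisher-information identifiability report
#'
#' Builds the sensitivity matrix S (the derivative of every training-data
#' prediction with respect to every parameter, by central finite
#' differences), forms the Fisher information matrix \code{FIM = S' W S}
#' with \code{W = diag(1 / (noise_cv * prediction)^2)} (points with a zero
#' prediction carry no information and are skipped), and reports the
#' Cramer-Rao standard deviation of each estimate,
#' \code{sd_i = sqrt((FIM^-1)_ii)}, normalized as a percentage of the
#' estimate.  A pseudo-inverse is used when the FIM is numerically singular;
#' a parameter whose sensitivity column is identically zero is reported as
#' non-identifiable (infinite normalized sd).
#'
#' @param model an \code{odem_model}.
#' @param estimates an \code{odem_parameter_set} at which to evaluate.
#' @param training list of training subsets.
#' @param noise_cv proportional noise level of the data.
#' @param rel_step,abs_step finite-difference step: \code{max(rel_step * p,
#'   abs_step)}.
#' @param rtol,atol integrator tolerances.
#' @return A list of class \code{odem_identifiability}:
#'   \code{normalized_sd} (percent, per parameter), \code{sd}, \code{fim},
#'   \code{fim_condition_number}, \code{pseudo_inverse_used},
#'   \code{non_identifiable}.
#' @export
fisher_sd <- function(model, estimates, training, noise_cv,
                      rel_step = 1e-4, abs_step = 1e-8,
                      rtol = 1e-8, atol = 1e-10) {
  if (noise_cv <= 0) stop("noise_cv must be positive")
  values <- estimates$values[model$parameter_names]
  groups <- group_by_condition(training)
  predict_at <- function(v)
    stacked_predictions(model, v, training, groups, rtol, atol)
  xhat <- predict_at(values)
  S <- matrix(0, nrow = length(xhat), ncol = length(values),
              dimnames = list(NULL, model$parameter_names))
  for (j in seq_along(values)) {
    h <- max(rel_step * abs(values[j]), abs_step)
    up <- values; up[j] <- up[j] + h
    dn <- values; dn[j] <- dn[j] - h
    S[, j] <- (predict_at(up) - predict_at(dn)) / (2 * h)
  }
  w <- ifelse(xhat == 0, 0, 1 / (noise_cv * xhat)^2)
  fim <- crossprod(S * sqrt(w))
  fim <- (fim + t(fim)) / 2
  zero_col <- apply(S, 2, function(col) all(col == 0))
  kappa <- tryCatch(kappa(fim, exact = TRUE), error = function(e) Inf)
  pinv_used <- FALSE
  inv <- tryCatch({
    if (!is.finite(kappa) || kappa > 1e12) stop("ill-conditioned")
    solve(fim)
  }, error = function(e) {
    pinv_used <<- TRUE
    MASS::ginv(fim)
  })
  sd <- sqrt(pmax(diag(inv), 0))
  nsd <- 100 * sd / abs(values)
  nsd[zero_col] <- Inf
  if (any(zero_col))
    warning("non-identifiable parameter(s): ",
            paste(model$parameter_names[zero_col], collapse = ", "))
  structure(list(normalized_sd = setNames(nsd, model$parameter_names),
                 sd = setNames(sd, model$parameter_names),
                 fim = fim,
                 fim_condition_number = kappa,
                 pseudo_inverse_used = pinv_used,
                 non_identifiable = model$parameter_names[zero_col]),
            class = "odem_identifiability")
}

#' @export
print.odem_identifiability <- function(x, ...) {
  cat("Fisher-information identifiability (normalized sd, %):\n")
  print(round(x$normalized_sd, 2))
  if (x$pseudo_inverse_used) cat("(pseudo-inverse used)\n")
  invisible(x)
}
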