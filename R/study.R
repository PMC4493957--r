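# Orchestration of the full simulation study: noise realizations x
# partitioning schemes x the two model structures, plus aggregation of the
# summary quantities (median PE, wrong-decision counts, model separation,
# parameter bias / identifiability).

#' Study configuration
#'
#' @param model_pair a list with \code{true}, \code{simplified} and
#'   \code{params} as returned by \code{\link{make_benchmark_models}}.
#' @param design an \code{odem_design}.
#' @param schemes character vector of scheme names (any of \code{"Sln1"},
#'   \code{"Sho1"}, \code{"WT"}, \code{"lowest_dose"}, \code{"highest_dose"},
#'   \code{"Sln1_Sho1"}, \code{"Sln1_WT"}, \code{"Sho1_WT"},
#'   \code{"low_doses"}, \code{"high_doses"}, \code{"srcv"}) or a list of
#'   \code{odem_scheme} objects.
#' @param n_realizations number of noise realizations (study default 100).
#' @param master_seed integer seed governing every random draw of the study.
#' @param noise_cv proportional noise level (default 0.10).
#' @param fit_options an \code{odem_fit_options}.
#' @param dense_dt spacing in minutes of the dense grid on which model
#'   separation areas are evaluated (default 1 min over the design span).
#' @param record_identifiability if \code{TRUE}, a Fisher-information report
#'   is computed for the true structure at every fit (slower).
#' @param srcv_redraw if \code{TRUE} (default) SRCV folds are redrawn for
#'   every realization from seeds derived from the master seed; if
#'   \code{FALSE} a single fold assignment is drawn once and reused.
#' @param cores number of worker processes for realizations (results are
#'   independent of the degree of parallelism; seeds are bound to
#'   realization indices).
#' @return A list of class \code{odem_study_config}.
#' @export
study_config <- function(model_pair, design = build_design(),
                         schemes = c("Sln1", "Sho1", "WT",
                                     "lowest_dose", "highest_dose",
                                     "Sln1_Sho1", "Sln1_WT", "Sho1_WT",
                                     "low_doses", "high_doses", "srcv"),
                         n_realizations = 100, master_seed = 1,
                         noise_cv = 0.10, fit_options = odemval::fit_options(),
                         dense_dt = 1, record_identifiability = FALSE,
                         srcv_redraw = TRUE, cores = 1) {
  structure(list(model_pair = model_pair, design = design, schemes = schemes,
                 n_realizations = n_realizations, master_seed = master_seed,
                 noise_cv = noise_cv, fit_options = fit_options,
                 dense_dt = dense_dt,
                 record_identifiability = record_identifiability,
                 srcv_redraw = srcv_redraw, cores = cores),
            class = "odem_study_config")
}

resolve_schemes <- function(config, srcv_seed) {
  if (is.list(config$schemes) &&
      all(vapply(config$schemes, inherits, TRUE, "odem_scheme"))) {
    out <- config$schemes
    names(out) <- vapply(out, function(s) s$name, "")
    return(out)
  }
  avail <- all_schemes(config$design, srcv_seed = NULL)
  out <- list()
  for (nm in config$schemes) {
    if (nm == "srcv") {
      out$srcv <- srcv_partition(config$design, seed = srcv_seed)
    } else if (nm %in% names(avail)) {
      out[[nm]] <- avail[[nm]]
    } else stop("unknown scheme name: ", nm)
  }
  out
}

# offset master seed into an independent stream (SRCV fold draws)
offset_seed <- function(seed, offset) {
  ((as.numeric(seed) + offset - 1) %% 2147483646) + 1
}

# evaluate one (scheme run, realization): fit both structures, predict the
# validation subsets, return per-subset measures
eval_run <- function(run, realization, config, dense_times) {
  pair <- config$model_pair
  fo <- config$fit_options
  training <- c(unname(realization$hog1pp[run$training]),
                unname(realization$downstream))
  fit_t <- fit_model(pair$true, training, pair$params, fo)
  fit_s <- fit_model(pair$simplified, training,
                     params_for_model(pair$params, pair$simplified), fo)
  data_times <- config$design$times
  grid <- sort(unique(c(data_times, dense_times)))
  di <- match(data_times, grid)
  per_subset <- lapply(run$validation, function(id) {
    sub <- realization$hog1pp[[id]]
    cond <- subset_condition(sub)
    pt <- sim_observables(pair$true, fit_t$estimates$values, cond, grid,
                          rtol = fo$rtol, atol = fo$atol)$Hog1PP
    ps <- sim_observables(pair$simplified, fit_s$estimates$values, cond, grid,
                          rtol = fo$rtol, atol = fo$atol)$Hog1PP
    data.frame(scope = id,
               pe_true = pe_single(sub$values, pt[di]),
               pe_simplified = pe_single(sub$values, ps[di]),
               delta_ts = pracma::trapz(grid, abs(pt - ps)) / max(sub$values))
  })
  list(measures = do.call(rbind, per_subset), fit_true = fit_t,
       fit_simplified = fit_s, training = training)
}

eval_realization <- function(realization, schemes, config, dense_times) {
  records <- list(); params <- list()
  true_values <- config$model_pair$params$values
  for (nm in names(schemes)) {
    sch <- schemes[[nm]]
    run_rows <- list()
    for (ri in seq_along(sch$runs)) {
      ev <- eval_run(sch$runs[[ri]], realization, config, dense_times)
      m <- ev$measures
      m$realization <- realization$index
      m$scheme <- nm
      m$run <- ri
      m$wrong <- wrong_decision(m$pe_true, m$pe_simplified)
      run_rows[[ri]] <- m
      est <- ev$fit_true$estimates$values
      prow <- data.frame(realization = realization$index, scheme = nm,
                         run = ri, parameter = names(est),
                         estimate = unname(est),
                         true_value = unname(true_values[names(est)]),
                         nbi = unname(normalized_bias(est,
                                                      true_values[names(est)])),
                         converged = ev$fit_true$converged,
                         row.names = NULL)
      if (config$record_identifiability) {
        idr <- fisher_sd(config$model_pair$true, ev$fit_true$estimates,
                         ev$training, noise_cv = max(config$noise_cv, 1e-6),
                         rtol = config$fit_options$rtol,
                         atol = config$fit_options$atol)
        prow$normalized_sd <- unname(idr$normalized_sd[prow$parameter])
      }
      params[[length(params) + 1L]] <- prow
    }
    rows <- do.call(rbind, run_rows)
    if (sch$consensus) {
      # average measures over subsets within a run, then over runs,
      # before the selection verdict
      run_means <- do.call(rbind, lapply(run_rows, function(m)
        data.frame(pe_true = mean(m$pe_true),
                   pe_simplified = mean(m$pe_simplified),
                   delta_ts = mean(m$delta_ts))))
      cons <- data.frame(scope = "consensus",
                         pe_true = mean(run_means$pe_true),
                         pe_simplified = mean(run_means$pe_simplified),
                         delta_ts = mean(run_means$delta_ts),
                         realization = realization$index, scheme = nm,
                         run = NA_integer_)
      cons$wrong <- wrong_decision(cons$pe_true, cons$pe_simplified)
      rows <- rbind(rows, cons)
    }
    records[[nm]] <- rows
  }
  list(records = do.call(rbind, records),
       params = do.call(rbind, params))
}

#' Run the simulation study
#'
#' Generates the seeded noisy realizations, and for every realization and
#' partitioning scheme run fits both model structures on the training data
#' (downstream data always included), predicts every validation subset,
#' and records percentage errors, model separation, the selection verdict,
#' and the normalized bias of the true structure's parameter estimates.
#' For consensus schemes (the adapted schemes and SRCV) the measures are
#' averaged over validation subsets and runs before the verdict.  The whole
#' study is reproducible from the master seed and independent of the degree
#' of parallelism.
#'
#' @param config an \code{odem_study_config}.
#' @return A list of class \code{odem_study_result} with \code{records} (one
#'   row per realization/scheme/run/scope), \code{parameters} (per-parameter
#'   estimates and bias), \code{config} and \code{n_excluded} (fits whose
#'   evaluation failed and were excluded, with a warning).
#' @export
run_study <- function(config) {
  design <- config$design
  pair <- config$model_pair
  realizations <- generate_realizations(
    pair$true, pair$params, design, n = config$n_realizations,
    master_seed = config$master_seed, cv = config$noise_cv)
  dense_times <- seq(min(design$times), max(design$times),
                     by = config$dense_dt)
  srcv_master <- offset_seed(config$master_seed, 999983)
  srcv_seeds <- derive_seeds(srcv_master, config$n_realizations)
  fixed_srcv_seed <- srcv_seeds[1]

  worker <- function(r) {
    seed_r <- if (config$srcv_redraw) srcv_seeds[r] else fixed_srcv_seed
    schemes <- resolve_schemes(config, srcv_seed = seed_r)
    tryCatch(eval_realization(realizations[[r]], schemes, config,
                              dense_times),
             error = function(e) e)
  }
  res <- if (config$cores > 1) {
    parallel::mclapply(seq_len(config$n_realizations), worker,
                       mc.cores = config$cores)
  } else lapply(seq_len(config$n_realizations), worker)

  failed <- vapply(res, inherits, TRUE, "error")
  if (any(failed))
    warning(sprintf("%d realization(s) failed and were excluded: %s",
                    sum(failed),
                    paste(unique(vapply(res[failed], conditionMessage, "")),
                          collapse = "; ")))
  res <- res[!failed]
  records <- do.call(rbind, lapply(res, `[[`, "records"))
  params <- do.call(rbind, lapply(res, `[[`, "params"))
  rownames(records) <- NULL
  rownames(params) <- NULL
  structure(list(records = records, parameters = params,
                 config = config, n_excluded = sum(failed)),
            class = "odem_study_result")
}

#' @export
print.odem_study_result <- function(x, ...) {
  cat(sprintf("study result: %d realizations, schemes: %s\n",
              length(unique(x$records$realization)),
              paste(unique(x$records$scheme), collapse = ", ")))
  cat(sprintf("%d decision records; %d excluded realization(s)\n",
              nrow(x$records), x$n_excluded))
  invisible(x)
}

#' Summarize a study result
#'
#' Per scheme and validation scope: medians of the percentage errors of
#' both structures and of the model separation, interquartile range of the
#' true structure's PE, wrong-decision counts, and the number of box-plot
#' outliers (points beyond the 1.5 x IQR whiskers, the approximately 99.3
#' percent coverage convention for normal data).
#'
#' @param result an \code{odem_study_result}.
#' @return A data frame of aggregates (class \code{odem_study_summary}).
#' @export
summarize_study <- function(result) {
  rec <- result$records
  if (nrow(rec) == 0) stop("empty study result")
  key <- interaction(rec$scheme, rec$scope, drop = TRUE)
  agg <- do.call(rbind, lapply(split(rec, key), function(g) {
    bx <- grDevices::boxplot.stats(g$pe_true)
    data.frame(scheme = g$scheme[1], scope = g$scope[1],
               n = nrow(g),
               median_pe_true = median(g$pe_true),
               median_pe_simplified = median(g$pe_simplified),
               median_delta_ts = median(g$delta_ts),
               iqr_pe_true = quantile(g$pe_true, 0.75) -
                 quantile(g$pe_true, 0.25),
               n_outliers_pe_true = length(bx$out),
               wrong_decisions = sum(g$wrong))
  }))
  rownames(agg) <- NULL
  agg <- agg[order(agg$scheme, agg$scope), ]
  class(agg) <- c("odem_study_summary", class(agg))
  agg
}

#' Box plot of percentage errors for one scheme
#'
#' @param result an \code{odem_study_result}.
#' @param scheme scheme name to plot.
#' @param which \code{"pe_true"}, \code{"pe_simplified"} or
#'   \code{"delta_ts"}.
#' @param ... passed to \code{boxplot}.
#' @return Invisibly, the boxplot statistics.
#' @export
plot_study_boxes <- function(result, scheme, which = "pe_true", ...) {
  rec <- result$records
  rec <- rec[rec$scheme == scheme & rec$scope != "consensus", ]
  if (nrow(rec) == 0) stop("no per-subset records for scheme ", scheme)
  bx <- graphics::boxplot(rec[[which]] ~ rec$scope, outcol = "red",
                          outpch = 16, las = 2,
                          xlab = "", ylab = which,
                          main = paste(scheme, "scheme"), ...)
  invisible(bx)
}

fmt_num_cols <- function(df, cols) {
  for (col in intersect(cols, names(df)))
    df[[col]] <- sprintf("%.17g", df[[col]])
  df
}

#' Write study outputs as CSV
#'
#' Writes \code{records.csv}, \code{parameters.csv} and
#' \code{aggregates.csv} into a directory.  Numeric columns are formatted
#' with 17 significant digits, so identical configurations and seeds give
#' byte-identical files.
#'
#' @param result an \code{odem_study_result}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_csv <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("records.csv", "parameters.csv",
                            "aggregates.csv"))
  write.csv(fmt_num_cols(result$records,
                         c("pe_true", "pe_simplified", "delta_ts")),
            paths[1], row.names = FALSE, quote = FALSE)
  write.csv(fmt_num_cols(result$parameters,
                         c("estimate", "true_value", "nbi", "normalized_sd")),
            paths[2], row.names = FALSE, quote = FALSE)
  agg <- summarize_study(result)
  write.csv(fmt_num_cols(as.data.frame(agg),
                         c("median_pe_true", "median_pe_simplified",
                           "median_delta_ts", "iqr_pe_true")),
            paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Build a study configuration from a YAML file
#'
#' Recognized keys: \code{schemes}, \code{n_realizations},
#' \code{master_seed}, \code{noise_cv}, \code{dense_dt},
#' \code{record_identifiability}, \code{srcv_redraw}, \code{cores}, and an
#' optional \code{model} block passed to
#' \code{\link{make_benchmark_models}} as parameter overrides.
#'
#' @param path YAML file path.
#' @return An \code{odem_study_config}.
#' @export
study_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  pair <- make_benchmark_models(
    defaults = if (!is.null(cfg$model$parameters))
      unlist(cfg$model$parameters) else NULL)
  args <- list(model_pair = pair)
  for (key in c("schemes", "n_realizations", "master_seed", "noise_cv",
                "dense_dt", "record_identifiability", "srcv_redraw",
                "cores"))
    if (!is.null(cfg[[key]])) args[[key]] <- cfg[[key]]
  if (!is.null(cfg$schemes)) args$schemes <- unlist(cfg$schemes)
  do.call(study_config, args)
}
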