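# Experimental design, noise-free profiles and seeded noisy realizations.

.default_doses <- c(0.07, 0.1, 0.2, 0.5, 0.6, 0.8)

subset_id <- function(cell_type, dose)
  paste0(cell_type, "@", vapply(dose, format, ""))

#' Build the cell-type-by-dose experimental design
#'
#' The default design is the full factorial of 3 cell types (Sln1 mutant,
#' Sho1 mutant, wild type) and 6 NaCl doses, giving 18 Hog1PP time-series
#' subsets of 15 points over 160 minutes, plus a single downstream
#' experiment (mRNA, protein, glycerol) in wild-type cells at 0.5 M which is
#' always part of the training data and never partitioned.
#'
#' @param cell_types character vector of cell-type labels (see
#'   \code{\link{cell_types}}).
#' @param doses numeric vector of NaCl doses in molar.
#' @param times Hog1PP sampling grid in minutes; the default is a uniform
#'   15-point grid on [0, 160].
#' @param downstream_cell_type,downstream_dose condition of the downstream
#'   experiment.
#' @return An object of class \code{odem_design}.
#' @examples
#' d <- build_design()
#' length(hog1pp_ids(d))   # 18
#' @export
build_design <- function(cell_types = c("Sln1", "Sho1", "WT"),
                         doses = .default_doses,
                         times = seq(0, 160, length.out = 15),
                         downstream_cell_type = "WT",
                         downstream_dose = 0.5) {
  if (anyDuplicated(cell_types) || anyDuplicated(doses))
    stop("duplicate (cell type, dose) pairs in design")
  if (!all(cell_types %in% names(.cell_type_flags)))
    stop("unknown cell types: ",
         paste(setdiff(cell_types, names(.cell_type_flags)), collapse = ", "))
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  structure(list(cell_types = cell_types,
                 doses = sort(doses),
                 times = times,
                 downstream_cell_type = downstream_cell_type,
                 downstream_dose = downstream_dose,
                 downstream_observables = c("mRNA", "protein", "glycerol")),
            class = "odem_design")
}

#' @export
print.odem_design <- function(x, ...) {
  cat(sprintf(
    "design: %d cell types x %d doses = %d Hog1PP subsets; %d time points on [%g, %g] min\n",
    length(x$cell_types), length(x$doses),
    length(x$cell_types) * length(x$doses),
    length(x$times), min(x$times), max(x$times)))
  cat(sprintf("downstream experiment: %s at %g M (%s)\n",
              x$downstream_cell_type, x$downstream_dose,
              paste(x$downstream_observables, collapse = ", ")))
  invisible(x)
}

#' Hog1PP subset identifiers of a design
#'
#' Identifiers are \code{"<cell type>@<dose>"}, ordered cell type first.
#'
#' @param design an \code{odem_design}.
#' @return Character vector of subset ids.
#' @export
hog1pp_ids <- function(design) {
  as.vector(vapply(design$cell_types,
                   function(ct) subset_id(ct, design$doses),
                   character(length(design$doses))))
}

new_subset <- function(cell_type, dose, observable, times, values) {
  stopifnot(length(times) == length(values))
  structure(list(id = subset_id(cell_type, dose),
                 cell_type = cell_type, dose = dose,
                 observable = observable,
                 times = times, values = values),
            class = "odem_subset")
}

#' @export
print.odem_subset <- function(x, ...) {
  cat(sprintf("subset %s [%s]: %d points, range [%.3g, %.3g]\n",
              x$id, x$observable, length(x$times),
              min(x$values), max(x$values)))
  invisible(x)
}

subset_condition <- function(subset) condition_for(subset$cell_type, subset$dose)

#' Simulate the noise-free dataset of a design
#'
#' Simulates the model once per design cell and returns the Hog1PP subsets
#' plus the downstream subsets (mRNA, protein, glycerol at the downstream
#' condition), all noise-free and fully deterministic.
#'
#' @param model an \code{odem_model} (normally the benchmark true structure).
#' @param params generating parameters.
#' @param design an \code{odem_design}.
#' @param rtol,atol integrator tolerances.
#' @return A list with named lists \code{hog1pp} (keyed by subset id) and
#'   \code{downstream} (keyed by observable), class \code{odem_dataset}.
#' @export
generate_noise_free <- function(model, params, design,
                                rtol = 1e-8, atol = 1e-10) {
  hog <- list()
  for (ct in design$cell_types) {
    for (d in design$doses) {
      sim <- simulate_model(model, params, condition_for(ct, d),
                            design$times, rtol = rtol, atol = atol)
      sub <- new_subset(ct, d, "Hog1PP", design$times, sim$Hog1PP)
      hog[[sub$id]] <- sub
    }
  }
  dsim <- simulate_model(model, params,
                         condition_for(design$downstream_cell_type,
                                       design$downstream_dose),
                         design$times, rtol = rtol, atol = atol)
  down <- lapply(design$downstream_observables, function(obs)
    new_subset(design$downstream_cell_type, design$downstream_dose,
               obs, design$times, dsim[[obs]]))
  names(down) <- design$downstream_observables
  structure(list(hog1pp = hog, downstream = down), class = "odem_dataset")
}

#' Add proportional Gaussian noise to a subset
#'
#' Each value v is replaced by v + e with e ~ Normal(0, (cv * v)^2),
#' independently per time point; a value of exactly zero therefore stays
#' exactly zero.  The default cv of 0.10 is the 10 percent proportional
#' noise level of the study design.
#'
#' @param subset an \code{odem_subset}.
#' @param cv noise coefficient of variation (sd as a fraction of the value).
#' @param seed optional integer seed making the draw reproducible.
#' @return The subset with noisy values.
#' @export
add_noise <- function(subset, cv = 0.10, seed = NULL) {
  if (cv < 0) stop("cv must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  subset$values <- subset$values +
    rnorm(length(subset$values), mean = 0, sd = cv * abs(subset$values))
  subset
}

# deterministic child seeds: k draws from a stream seeded by `seed`
derive_seeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max, k)
}

#' Generate seeded noisy realizations of the full design
#'
#' Produces \code{n} independent noisy copies of the complete dataset (the
#' study default is 100).  All realizations share the same noise-free
#' backbone; per-realization and per-subset seeds are derived
#' deterministically from the master seed, so regenerating with the same
#' master seed reproduces every value exactly and any single realization can
#' be rebuilt from its stored seed.
#'
#' @param model,params,design as in \code{\link{generate_noise_free}}.
#' @param n number of realizations.
#' @param master_seed integer master seed.
#' @param cv proportional noise level.
#' @param noise_free optionally, a precomputed \code{odem_dataset} backbone.
#' @return A list of \code{odem_realization} objects, each with elements
#'   \code{index}, \code{seed}, \code{hog1pp} and \code{downstream}.
#' @export
generate_realizations <- function(model, params, design, n = 100,
                                  master_seed = 1, cv = 0.10,
                                  noise_free = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (is.null(noise_free))
    noise_free <- generate_noise_free(model, params, design)
  seeds <- derive_seeds(master_seed, n)
  lapply(seq_len(n), function(r)
    realize_one(noise_free, r, seeds[r], cv))
}

realize_one <- function(noise_free, index, seed, cv) {
  ids <- c(names(noise_free$hog1pp), names(noise_free$downstream))
  sub_seeds <- derive_seeds(seed, length(ids))
  hog <- noise_free$hog1pp
  for (i in seq_along(hog))
    hog[[i]] <- add_noise(hog[[i]], cv = cv, seed = sub_seeds[i])
  down <- noise_free$downstream
  off <- length(hog)
  for (i in seq_along(down))
    down[[i]] <- add_noise(down[[i]], cv = cv, seed = sub_seeds[off + i])
  structure(list(index = index, seed = seed,
                 hog1pp = hog, downstream = down),
            class = "odem_realization")
}

#' @export
print.odem_realization <- function(x, ...) {
  cat(sprintf("realization %d (seed %d): %d Hog1PP subsets + %d downstream\n",
              x$index, x$seed, length(x$hog1pp), length(x$downstream)))
  invisible(x)
}

realization_to_df <- function(x) {
  subs <- c(x$hog1pp, x$downstream)
  do.call(rbind, lapply(subs, function(s)
    data.frame(subset_cell_type = s$cell_type,
               subset_dose_M = s$dose,
               observable = s$observable,
               time_min = s$times,
               value = s$values)))
}

#' Write / read one realization as tidy CSV
#'
#' Columns: subset_cell_type, subset_dose_M, observable, time_min, value.
#' Numeric columns are written with 17 significant digits so that the
#' round-trip is exact at full double precision.
#'
#' @param x an \code{odem_realization} (or \code{odem_dataset}).
#' @param path file path.
#' @return \code{read_realization_csv} returns an \code{odem_dataset}.
#' @export
write_realization_csv <- function(x, path) {
  df <- realization_to_df(x)
  for (col in c("subset_dose_M", "time_min", "value"))
    df[[col]] <- sprintf("%.17g", df[[col]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_realization_csv
#' @export
read_realization_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(subset_cell_type = "character",
                                subset_dose_M = "numeric",
                                observable = "character",
                                time_min = "numeric",
                                value = "numeric"))
  key <- paste(df$subset_cell_type, df$subset_dose_M, df$observable)
  hog <- list(); down <- list()
  for (k in unique(key)) {
    rows <- df[key == k, ]
    s <- new_subset(rows$subset_cell_type[1], rows$subset_dose_M[1],
                    rows$observable[1], rows$time_min, rows$value)
    if (s$observable == "Hog1PP") hog[[s$id]] <- s else down[[s$observable]] <- s
  }
  structure(list(hog1pp = hog, downstream = down), class = "odem_dataset")
}
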