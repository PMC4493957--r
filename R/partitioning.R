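# Hold-out partitioning schemes and stratified random cross-validation.
#
# A partition scheme assigns the 18 Hog1PP subsets to training/validation
# roles, possibly over several runs.  The downstream (mRNA, protein,
# glycerol) data are implicitly always part of every training set and are
# never partitioned; "training" and "validation" refer to Hog1PP data only.

new_scheme <- function(name, runs, consensus, design) {
  ids <- hog1pp_ids(design)
  for (r in runs) {
    if (length(intersect(r$training, r$validation)) > 0)
      stop("training and validation overlap in scheme ", name)
    if (!all(c(r$training, r$validation) %in% ids))
      stop("unknown subset ids in scheme ", name)
  }
  structure(list(name = name, runs = runs, consensus = consensus),
            class = "odem_scheme")
}

#' @export
print.odem_scheme <- function(x, ...) {
  cat(sprintf("partition scheme '%s': %d run(s), %s decisions\n", x$name,
              length(x$runs), if (x$consensus) "consensus" else "per-subset"))
  for (i in seq_along(x$runs))
    cat(sprintf("  run %d: %d training / %d validation\n", i,
                length(x$runs[[i]]$training), length(x$runs[[i]]$validation)))
  invisible(x)
}

#' Gene-deletion hold-out schemes (single cell type trains)
#'
#' One scheme per cell type: the training set holds all doses of that cell
#' type and the remaining subsets (the other two cell types at every dose)
#' are validated separately, i.e. a validation/selection verdict is reached
#' on each validation subset on its own.
#'
#' @param design an \code{odem_design}.
#' @return Named list of \code{odem_scheme} objects (one per cell type).
#' @export
scenario1_schemes <- function(design) {
  out <- lapply(design$cell_types, function(ct) {
    train <- subset_id(ct, design$doses)
    new_scheme(ct,
               list(list(training = train,
                         validation = setdiff(hog1pp_ids(design), train))),
               consensus = FALSE, design = design)
  })
  names(out) <- design$cell_types
  out
}

#' Dose-response hold-out schemes (single dose trains)
#'
#' Two schemes: the training set holds the lowest (respectively highest)
#' dose of every cell type, and the remaining subsets are validated
#' separately.
#'
#' @param design an \code{odem_design}.
#' @return Named list with elements \code{lowest_dose} and
#'   \code{highest_dose}.
#' @export
scenario2_schemes <- function(design) {
  one <- function(d, name) {
    train <- vapply(design$cell_types, function(ct) subset_id(ct, d), "")
    new_scheme(name,
               list(list(training = unname(train),
                         validation = setdiff(hog1pp_ids(design), train))),
               consensus = FALSE, design = design)
  }
  list(lowest_dose = one(min(design$doses), "lowest_dose"),
       highest_dose = one(max(design$doses), "highest_dose"))
}

#' Adapted hold-out schemes with varied training sets
#'
#' Five schemes, each training on 12 subsets and validating on the
#' remaining 6, with consensus decisions (measures averaged over all
#' validation subsets before a verdict is reached): the three cell-type
#' pairs (Sln1/Sho1, Sln1/WT, Sho1/WT) and the two dose halves (the four
#' lowest doses of every cell type, or the four highest).
#'
#' @param design an \code{odem_design}; the dose-half schemes require the
#'   default 6-dose grid shape (doses splittable as 4 training + 2
#'   validation).
#' @return Named list of five \code{odem_scheme} objects.
#' @export
adapted_schemes <- function(design) {
  ids <- hog1pp_ids(design)
  out <- list()
  cts <- design$cell_types
  for (i in seq_along(cts)) for (j in seq_along(cts)) {
    if (i >= j) next
    name <- paste0(cts[i], "_", cts[j])
    train <- c(subset_id(cts[i], design$doses), subset_id(cts[j], design$doses))
    out[[name]] <- new_scheme(name,
      list(list(training = train, validation = setdiff(ids, train))),
      consensus = TRUE, design = design)
  }
  n_train_doses <- length(design$doses) - 2L
  low <- design$doses[seq_len(n_train_doses)]
  high <- rev(design$doses)[seq_len(n_train_doses)]
  dose_scheme <- function(doses, name) {
    train <- as.vector(vapply(cts, function(ct) subset_id(ct, doses),
                              character(length(doses))))
    new_scheme(name,
               list(list(training = train, validation = setdiff(ids, train))),
               consensus = TRUE, design = design)
  }
  out$low_doses <- dose_scheme(low, "low_doses")
  out$high_doses <- dose_scheme(high, "high_doses")
  out
}

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' Stratified random cross-validation partition
#'
#' Randomly partitions the Hog1PP subsets into training and validation sets
#' over \code{n_runs} runs under the stratification constraints: every run's
#' training set contains the same amount of data from each cell type and
#' each dose level (on the default 3 x 6 grid: 12 training subsets, 4 per
#' cell type and 2 per dose; equivalently 6 validation subsets, 2 per cell
#' type and 1 per dose), and across the runs every subset appears in
#' validation exactly once.  The assignment is drawn uniformly over all
#' feasible configurations: each dose's cell-type subsets are assigned to
#' runs by a random permutation, and the draw is accepted only when every
#' cell type is balanced across runs.
#'
#' @param design an \code{odem_design}; the constraints require as many runs
#'   as cell types and a dose count divisible by \code{n_runs}, otherwise an
#'   infeasibility error is raised.
#' @param n_runs number of cross-validation runs (default 3).
#' @param seed optional integer seed.
#' @return An \code{odem_scheme} named \code{"srcv"} with \code{n_runs} runs
#'   and consensus decisions.
#' @export
srcv_partition <- function(design, n_runs = 3, seed = NULL) {
  n_ct <- length(design$cell_types)
  n_d <- length(design$doses)
  if (n_ct != n_runs || n_d %% n_runs != 0)
    stop(sprintf(paste0(
      "stratification infeasible: need as many runs as cell types and a ",
      "dose count divisible by the run count (got %d cell types, %d doses, ",
      "%d runs)"), n_ct, n_d, n_runs))
  if (!is.null(seed)) set.seed(seed)
  pm <- perms(n_runs)
  # rejection sampling: uniform over the feasible set
  repeat {
    rows <- pm[sample.int(nrow(pm), n_d, replace = TRUE), , drop = FALSE]
    counts <- apply(rows, 2, tabulate, nbins = n_runs)
    if (all(counts == n_d / n_runs)) break
  }
  ids <- matrix(hog1pp_ids(design), nrow = n_d)  # doses x cell types
  colnames(ids) <- design$cell_types
  runs <- lapply(seq_len(n_runs), function(r) {
    val <- ids[rows == r]
    list(training = setdiff(as.vector(ids), val), validation = val)
  })
  new_scheme("srcv", runs, consensus = TRUE, design = design)
}

#' All built-in partitioning schemes of a design
#'
#' Convenience enumeration of the three single-cell-type schemes, the two
#' single-dose schemes, the five adapted schemes and (optionally) one SRCV
#' scheme.
#'
#' @param design an \code{odem_design}.
#' @param srcv_seed seed for the SRCV draw, or \code{NULL} to omit SRCV.
#' @return Named list of \code{odem_scheme} objects.
#' @export
all_schemes <- function(design, srcv_seed = NULL) {
  out <- c(scenario1_schemes(design), scenario2_schemes(design),
           adapted_schemes(design))
  if (!is.null(srcv_seed))
    out$srcv <- srcv_partition(design, seed = srcv_seed)
  out
}

#' Serialize / deserialize a partition scheme as JSON
#'
#' @param scheme an \code{odem_scheme}.
#' @param path optional file path; with \code{path = NULL} the JSON string
#'   is returned.
#' @return \code{scheme_to_json} returns the JSON string (invisibly when
#'   written to a file); \code{scheme_from_json} returns the scheme.
#' @export
scheme_to_json <- function(scheme, path = NULL) {
  x <- list(name = scheme$name, consensus = scheme$consensus,
            runs = lapply(scheme$runs, function(r)
              list(training = r$training, validation = r$validation)))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname scheme_to_json
#' @param json JSON string or file path to read from.
#' @export
scheme_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  structure(list(name = x$name,
                 runs = lapply(x$runs, function(r)
                   list(training = unlist(r$training),
                        validation = unlist(r$validation))),
                 consensus = isTRUE(x$consensus)),
            class = "odem_scheme")
}
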