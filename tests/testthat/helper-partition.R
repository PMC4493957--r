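# Brute-force oracles for the SRCV stratification, shared by the
# partitioning tests and the acceptance suite.

# run-assignment matrix (doses x cell types) of an SRCV scheme
srcv_assignment <- function(scheme, design) {
  mat <- matrix(NA_integer_, length(design$doses), length(design$cell_types),
                dimnames = list(vapply(design$doses, format, ""),
                                design$cell_types))
  for (r in seq_along(scheme$runs))
    for (id in scheme$runs[[r]]$validation) {
      parts <- strsplit(id, "@", fixed = TRUE)[[1]]
      mat[parts[2], parts[1]] <- r
    }
  mat
}

# brute-force oracle: all feasible SRCV assignments on the 3x6 grid
# (rows = doses as permutations of runs 1:3, columns balanced 2-2-2)
enumerate_feasible <- function() {
  perms3 <- matrix(c(1,2,3, 1,3,2, 2,1,3, 2,3,1, 3,1,2, 3,2,1),
                   ncol = 3, byrow = TRUE)
  combos <- expand.grid(rep(list(1:6), 6))
  keep <- list()
  for (i in seq_len(nrow(combos))) {
    m <- perms3[unlist(combos[i, ]), , drop = FALSE]
    if (all(apply(m, 2, tabulate, nbins = 3) == 2))
      keep[[length(keep) + 1L]] <- m
  }
  keep
}
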