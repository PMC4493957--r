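fake_result <- function(pe_true, scheme = "s", scope = "x") {
  n <- length(pe_true)
  structure(list(
    records = data.frame(scope = scope, pe_true = pe_true,
                         pe_simplified = pe_true + 1,
                         delta_ts = seq_len(n),
                         realization = seq_len(n), scheme = scheme,
                         run = 1L, wrong = pe_true > pe_true + 1),
    parameters = data.frame(), config = NULL, n_excluded = 0L),
    class = "odem_study_result")
}

test_that("summary medians and box-plot outlier counts follow the whisker rule", {
  agg <- summarize_study(fake_result(c(1, 2, 3, 4, 100)))
  expect_equal(agg$median_pe_true, 3)
  expect_equal(agg$n_outliers_pe_true, 1)   # 100 beyond the 1.5 IQR whisker
  expect_equal(agg$wrong_decisions, 0)
  expect_equal(agg$iqr_pe_true, 2)
  empty <- fake_result(1)
  empty$records <- empty$records[0, ]
  expect_error(summarize_study(empty), "empty")
})

test_that("wrong-decision counts equal the number of flagged records", {
  res <- fake_result(c(5, 6, 7))
  res$records$pe_simplified <- c(4.9, 7, 6.5)
  res$records$wrong <- wrong_decision(res$records$pe_true,
                                      res$records$pe_simplified)
  agg <- summarize_study(res)
  expect_equal(agg$wrong_decisions, sum(res$records$wrong))
  expect_equal(agg$wrong_decisions, 2L)
})

noise_free_cfg <- study_config(
  bench,
  schemes = c("Sln1", "lowest_dose", "Sln1_WT", "srcv"),
  n_realizations = 2, master_seed = 5, noise_cv = 0)

nf_study <- suppressWarnings(run_study(noise_free_cfg))

test_that("noise-free study: true structure predicts perfectly, no wrong decisions", {
  expect_equal(nf_study$n_excluded, 0)
  expect_lt(max(nf_study$records$pe_true), 1e-6)
  expect_equal(sum(nf_study$records$wrong), 0)
  # the simplified structure cannot reach the true structure's zero error
  cons <- nf_study$records[nf_study$records$scope == "consensus", ]
  expect_true(all(cons$pe_simplified > cons$pe_true))
  # parameter estimates equal the generating values
  expect_lt(max(nf_study$parameters$nbi), 1e-4)
})

test_that("study records have the expected shape", {
  rec <- nf_study$records
  # per-subset rows: Sln1 12, lowest_dose 15, Sln1_WT 6, srcv 18; consensus
  # rows for the two consensus schemes
  per_real <- 12 + 15 + 6 + 1 + 18 + 1
  expect_equal(nrow(rec), 2 * per_real)
  expect_setequal(unique(rec$scheme),
                  c("Sln1", "lowest_dose", "Sln1_WT", "srcv"))
  expect_equal(sum(rec$scheme == "srcv" & rec$scope == "consensus"), 2)
  expect_true(all(rec$delta_ts >= 0))
  # parameters table: one row per parameter per fit of the true structure
  expect_equal(nrow(nf_study$parameters),
               2 * (1 + 1 + 1 + 3) * length(bench$true$parameter_names))
})

test_that("the study is reproducible from its master seed", {
  again <- suppressWarnings(run_study(noise_free_cfg))
  expect_equal(nf_study$records, again$records)
  expect_equal(nf_study$parameters, again$parameters)
})

test_that("study CSV outputs are byte-identical across reruns", {
  d1 <- tempfile(); d2 <- tempfile()
  write_study_csv(nf_study, d1)
  write_study_csv(suppressWarnings(run_study(noise_free_cfg)), d2)
  for (f in c("records.csv", "parameters.csv", "aggregates.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("summary medians agree with medians recomputed from raw records", {
  agg <- summarize_study(nf_study)
  rec <- nf_study$records
  for (i in seq_len(nrow(agg))) {
    g <- rec[rec$scheme == agg$scheme[i] & rec$scope == agg$scope[i], ]
    expect_equal(agg$median_pe_true[i], median(g$pe_true))
    expect_equal(agg$median_delta_ts[i], median(g$delta_ts))
  }
})

test_that("study configs resolve schemes by name and reject unknown ones", {
  cfg <- study_config(bench, schemes = c("Sho1_WT", "srcv"))
  schemes <- odemval:::resolve_schemes(cfg, srcv_seed = 4)
  expect_named(schemes, c("Sho1_WT", "srcv"))
  bad <- study_config(bench, schemes = "not_a_scheme")
  expect_error(odemval:::resolve_schemes(bad, srcv_seed = 1),
               "unknown scheme")
})

test_that("study configuration round-trips through YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("schemes: [Sln1, srcv]",
               "n_realizations: 7",
               "master_seed: 42",
               "noise_cv: 0.05",
               "model:",
               "  parameters:",
               "    k_act_sln: 2.5"), path)
  cfg <- study_config_from_yaml(path)
  expect_equal(cfg$schemes, c("Sln1", "srcv"))
  expect_equal(cfg$n_realizations, 7)
  expect_equal(cfg$master_seed, 42)
  expect_equal(cfg$noise_cv, 0.05)
  expect_equal(cfg$model_pair$params$values[["k_act_sln"]], 2.5)
})
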