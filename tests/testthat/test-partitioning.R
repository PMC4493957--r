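ids18 <- hog1pp_ids(default_design)

test_that("single-cell-type schemes train on 6 subsets and validate the other 12", {
  schemes <- scenario1_schemes(default_design)
  expect_named(schemes, c("Sln1", "Sho1", "WT"))
  for (sch in schemes) {
    run <- sch$runs[[1]]
    expect_length(run$training, 6)
    expect_length(run$validation, 12)
    expect_length(intersect(run$training, run$validation), 0)
    expect_false(sch$consensus)
  }
  expect_true(all(startsWith(schemes$Sln1$runs[[1]]$training, "Sln1@")))
  # each cell type trains exactly once: training sets tile all 18 subsets
  expect_setequal(unlist(lapply(schemes, function(s) s$runs[[1]]$training)),
                  ids18)
})

test_that("single-dose schemes train on the extreme dose of every cell type", {
  schemes <- scenario2_schemes(default_design)
  low <- schemes$lowest_dose$runs[[1]]
  expect_setequal(low$training, c("Sln1@0.07", "Sho1@0.07", "WT@0.07"))
  expect_length(low$validation, 15)
  high <- schemes$highest_dose$runs[[1]]
  expect_true(all(endsWith(high$training, "@0.8")))
  expect_length(high$validation, 15)
})

test_that("adapted schemes use 12 training / 6 validation with consensus", {
  schemes <- adapted_schemes(default_design)
  expect_named(schemes, c("Sln1_Sho1", "Sln1_WT", "Sho1_WT",
                          "low_doses", "high_doses"))
  for (sch in schemes) {
    run <- sch$runs[[1]]
    expect_length(run$training, 12)
    expect_length(run$validation, 6)
    expect_true(sch$consensus)
    expect_length(intersect(run$training, run$validation), 0)
  }
  # complement structure
  expect_setequal(schemes$Sho1_WT$runs[[1]]$validation,
                  paste0("Sln1@", c(0.07, 0.1, 0.2, 0.5, 0.6, 0.8)))
  # low-doses scheme validates the two highest doses of every cell type
  expect_setequal(schemes$low_doses$runs[[1]]$validation,
                  c(t(outer(c("Sln1@", "Sho1@", "WT@"), c(0.6, 0.8), paste0))))
})

test_that("SRCV folds satisfy the stratification constraints and 3-run coverage", {
  for (seed in c(1, 7, 99)) {
    sch <- srcv_partition(default_design, seed = seed)
    expect_length(sch$runs, 3)
    expect_true(sch$consensus)
    val_all <- unlist(lapply(sch$runs, `[[`, "validation"))
    # each subset validates exactly once across the runs
    expect_setequal(val_all, ids18)
    expect_length(val_all, 18)
    for (run in sch$runs) {
      expect_length(run$training, 12)
      expect_length(run$validation, 6)
      ct <- sub("@.*", "", run$validation)
      dose <- sub(".*@", "", run$validation)
      expect_true(all(table(ct) == 2))        # 2 validation subsets per cell type
      expect_true(all(table(dose) == 1))      # 1 per dose
      ct_tr <- sub("@.*", "", run$training)
      dose_tr <- sub(".*@", "", run$training)
      expect_true(all(table(ct_tr) == 4))     # training: 4 per cell type
      expect_true(all(table(dose_tr) == 2))   # and 2 per dose
    }
  }
})

test_that("SRCV sampler emits only members of the brute-force feasible set", {
  feasible <- enumerate_feasible()
  expect_gt(length(feasible), 1)  # randomization is meaningful
  keys <- vapply(feasible, function(m) paste(m, collapse = ""), "")
  sampled <- vapply(1:100, function(s) {
    m <- srcv_assignment(srcv_partition(default_design, seed = s),
                         default_design)
    paste(m, collapse = "")
  }, "")
  expect_true(all(sampled %in% keys))
  # different seeds give different assignments (with near-certainty)
  expect_gt(length(unique(sampled)), 1)
})

test_that("SRCV draws differ across seeds and reproduce under a fixed seed", {
  a <- srcv_partition(default_design, seed = 5)
  b <- srcv_partition(default_design, seed = 5)
  expect_identical(a, b)
  diffs <- vapply(1:10, function(i) {
    x <- srcv_partition(default_design, seed = i)
    y <- srcv_partition(default_design, seed = i + 1000)
    !identical(x$runs, y$runs)
  }, TRUE)
  expect_true(any(diffs))
})

test_that("SRCV refuses infeasible stratification constraints", {
  small <- build_design(cell_types = c("Sln1", "WT"),
                        doses = c(0.1, 0.5, 0.8))
  expect_error(srcv_partition(small, n_runs = 3), "infeasible")
})

test_that("schemes round-trip through JSON", {
  sch <- srcv_partition(default_design, seed = 3)
  js <- scheme_to_json(sch)
  back <- scheme_from_json(js)
  expect_equal(back$name, sch$name)
  expect_equal(back$consensus, sch$consensus)
  expect_equal(back$runs, sch$runs)
  path <- tempfile(fileext = ".json")
  scheme_to_json(sch, path)
  expect_equal(scheme_from_json(path)$runs, sch$runs)
})

test_that("scheme construction rejects overlapping or unknown subsets", {
  expect_error(
    odemval:::new_scheme("bad",
                         list(list(training = "Sln1@0.07",
                                   validation = "Sln1@0.07")),
                         FALSE, default_design),
    "overlap")
  expect_error(
    odemval:::new_scheme("bad",
                         list(list(training = "Sln1@0.33", validation = "WT@0.8")),
                         FALSE, default_design),
    "unknown subset ids")
})
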