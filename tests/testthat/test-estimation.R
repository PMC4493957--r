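noise_free <- generate_noise_free(bench$true, bench$params, default_design)
full_training <- c(unname(noise_free$hog1pp), unname(noise_free$downstream))

test_that("noise-free data started at truth are recovered exactly", {
  fit <- fit_model(bench$true, full_training, bench$params)
  expect_true(fit$converged)
  expect_lt(fit$residual_ss, 1e-10)
  expect_true(all(normalized_bias(fit$estimates$values,
                                  bench$params$values) < 0.5))
})

test_that("the optimizer never increases the residual sum of squares", {
  real <- generate_realizations(bench$true, bench$params, default_design,
                                n = 1, master_seed = 77,
                                noise_free = noise_free)[[1]]
  run <- scenario2_schemes(default_design)$lowest_dose$runs[[1]]
  training <- training_for(real, run)
  # start away from the truth
  start_v <- bench$params$values * 1.3
  start <- parameter_set(start_v, lower = bench$params$lower,
                         upper = pmax(bench$params$upper, start_v))
  fit <- suppressWarnings(fit_model(bench$true, training, start))
  expect_lte(fit$residual_ss, rss_at(bench$true, start_v, training) + 1e-8)
  expect_true(all(fit$estimates$values >= fit$estimates$lower - 1e-12))
  expect_true(all(fit$estimates$values <= fit$estimates$upper + 1e-12))
})

test_that("parameters are recovered with small bias from noisy full-design data", {
  # Which parameters the full design identifies is itself a model property:
  # take those whose Cramer-Rao normalized sd at the truth is below 10%.
  # For them, the median normalized bias over 20 noisy realizations (10%
  # noise, fits started at truth) must stay below 15%.
  crb <- fisher_sd(bench$true, bench$params, full_training, noise_cv = 0.10)
  identifiable <- names(which(crb$normalized_sd < 10))
  expect_gte(length(identifiable), 3)
  reals <- generate_realizations(bench$true, bench$params, default_design,
                                 n = 20, master_seed = 301,
                                 noise_free = noise_free)
  nbi <- sapply(reals, function(r) {
    training <- c(unname(r$hog1pp), unname(r$downstream))
    fit <- suppressWarnings(fit_model(bench$true, training, bench$params))
    normalized_bias(fit$estimates$values, bench$params$values)
  })
  med <- apply(nbi, 1, median)
  expect_true(all(med[identifiable] < 15),
              info = paste(identifiable, round(med[identifiable], 1),
                           collapse = ", "))
})

test_that("Fisher sd matches the closed-form Cramer-Rao value on the decay toy", {
  toy <- make_decay_model()
  k <- 0.1
  times <- 0:14
  sub <- make_decay_subset(decay_truth(k), times)
  est <- parameter_set(c(k = k), upper = 1)
  rep <- fisher_sd(toy, est, list(sub), noise_cv = 0.10)
  analytic_sd <- 0.10 / sqrt(sum(times^2))
  expect_lt(abs(rep$sd[["k"]] - analytic_sd) / analytic_sd, 0.01)
  expect_equal(rep$normalized_sd[["k"]], 100 * rep$sd[["k"]] / k)
  expect_false(rep$pseudo_inverse_used)
  # doubling the noise level doubles every normalized sd
  rep2 <- fisher_sd(toy, est, list(sub), noise_cv = 0.20)
  expect_equal(rep2$normalized_sd[["k"]], 2 * rep$normalized_sd[["k"]],
               tolerance = 1e-10)
})

test_that("the FIM is symmetric positive semidefinite on the benchmark", {
  training <- full_training[c(1, 7, 13, 19)]  # one subset per cell type + mRNA
  rep <- fisher_sd(bench$true, bench$params, training, noise_cv = 0.10)
  expect_equal(rep$fim, t(rep$fim))
  ev <- eigen(rep$fim, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-8 * max(ev)))
})

test_that("a parameter with zero sensitivity is flagged non-identifiable", {
  # Sln1-mutant data alone carry no information at all about the Sho1
  # complex formation rate, whose pathway is genetically inactive
  sln1_only <- unname(noise_free$hog1pp[startsWith(names(noise_free$hog1pp),
                                                   "Sln1@")])
  rep <- suppressWarnings(
    fisher_sd(bench$true, bench$params, sln1_only, noise_cv = 0.10))
  expect_true("k_bind_sho" %in% rep$non_identifiable)
  expect_equal(rep$normalized_sd[["k_bind_sho"]], Inf)
  expect_true(rep$pseudo_inverse_used)
})

test_that("Sho1-branch parameters are better identified from Sho1-mutant than WT data", {
  # Compared through the Sho1-branch subblock of the information matrix
  # (conditional Cramer-Rao, other parameters treated as known): in a
  # training set without the Sho1 mutant, the joint covariance of every
  # parameter is inflated by the near-unidentifiable co-estimated branch,
  # so the branch-specific comparison is the meaningful one.
  sho_training <- c(unname(noise_free$hog1pp[startsWith(names(noise_free$hog1pp),
                                                        "Sho1@")]),
                    unname(noise_free$downstream))
  wt_training <- c(unname(noise_free$hog1pp[startsWith(names(noise_free$hog1pp),
                                                       "WT@")]),
                   unname(noise_free$downstream))
  rep_sho <- fisher_sd(bench$true, bench$params, sho_training, noise_cv = 0.10)
  rep_wt <- fisher_sd(bench$true, bench$params, wt_training, noise_cv = 0.10)
  sho_pars <- c("k_bind_sho", "k_unbind_sho", "k_phos_sho", "k_dephos_sho",
                "k_hog_sho")
  cond_sd <- function(rep) {
    sub <- rep$fim[sho_pars, sho_pars]
    100 * sqrt(diag(solve(sub))) / bench$params$values[sho_pars]
  }
  expect_true(all(cond_sd(rep_sho) < cond_sd(rep_wt)))
})

test_that("multi-start fitting from 2x-range draws lands in one consistent minimum", {
  real <- generate_realizations(bench$true, bench$params, default_design,
                                n = 1, master_seed = 88,
                                noise_free = noise_free)[[1]]
  run <- scenario2_schemes(default_design)$lowest_dose$runs[[1]]
  training <- training_for(real, run)
  ms <- suppressWarnings(
    multistart_fit(bench$true, training, bench$params,
                   options = fit_options(start_mode = "multi", n_starts = 80),
                   seed = 19))
  expect_gte(ms$fraction_best, 0.1)
  expect_gt(ms$min_correlation, 0.99)
  # reproducible under the same seed
  ms2 <- suppressWarnings(
    multistart_fit(bench$true, training, bench$params,
                   options = fit_options(start_mode = "multi", n_starts = 80),
                   seed = 19))
  expect_equal(ms$best_rss, ms2$best_rss)
  expect_equal(ms$fraction_best, ms2$fraction_best)
  # all starts inside (0, 2 p_true]
  expect_true(all(ms$starts > 0))
  expect_true(all(sweep(ms$starts, 2,
                        2 * bench$params$values[colnames(ms$starts)],
                        `<=`)))
})

test_that("all starts at the truth reach the same minimum with fraction one", {
  toy <- make_decay_model()
  sub <- make_decay_subset(decay_truth(0.1))
  ms <- multistart_fit(toy, list(sub), parameter_set(c(k = 0.1), upper = 0.2),
                       options = fit_options(start_mode = "multi",
                                             n_starts = 5),
                       seed = 2)
  expect_equal(ms$fraction_best, 1.0)
  expect_equal(ms$min_correlation, 1)
})
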