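# Shared fixtures: the benchmark pair (built once per test run) and a
# single-parameter exponential-decay toy model with a closed-form solution,
# used as an analytic oracle for the estimation machinery.

bench <- make_benchmark_models()
default_design <- build_design()

# x' = -k x, x(t0) = x0 (fixed, known); observable "x" has the closed form
# x0 * exp(-k t) on a grid starting at t = 0, and sensitivity dx/dk = -t x,
# so the Fisher information under proportional noise cv is
# sum(t_i^2) / cv^2 exactly.  The default grid starts at 0 so that the
# closed form and the integrated trajectory coincide.
make_decay_model <- function(x0 = 10) {
  model_structure(
    name = "exp_decay",
    state_names = "x",
    parameter_names = "k",
    rhs = function(t, y, params, condition) -params[["k"]] * y,
    observe = function(out) data.frame(time = out[, "time"], x = out[, "x"]),
    initial_state = function(condition) c(x = x0))
}

# a decay-model "measurement": an odem_subset-like record at a WT condition
# (the condition is irrelevant to the toy dynamics but keys the solver cache)
make_decay_subset <- function(values, times = 0:14) {
  structure(list(id = "decay@1", cell_type = "WT", dose = 1,
                 observable = "x", times = times, values = values),
            class = "odem_subset")
}

decay_truth <- function(k, x0 = 10, times = 0:14) x0 * exp(-k * times)

# residual sum of squares of a model at given parameter values, computed
# independently of fit_model's internals
rss_at <- function(model, values, training) {
  pred <- unlist(lapply(training, function(s) {
    sim <- simulate_model(model, values, condition_for(s$cell_type, s$dose),
                          s$times)
    sim[[s$observable]]
  }))
  sum((unlist(lapply(training, `[[`, "values")) - pred)^2)
}

# training list for one scheme run: Hog1PP training subsets + downstream
training_for <- function(realization, run) {
  c(unname(realization$hog1pp[run$training]), unname(realization$downstream))
}
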