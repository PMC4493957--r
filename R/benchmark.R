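# Built-in two-branch osmostress benchmark (true / simplified pair).

.bench_state_names <- c("P", "C", "CP", "H", "HPP", "M", "PR", "G")

.bench_param_names <- c(
  "k_act_sln", "k_deact_sln",                     # Sln1 route on/off
  "k_bind_sho", "k_unbind_sho",                   # Sho1.Pbs2 complex
  "k_phos_sho", "k_dephos_sho",                   # complex (de)phosphorylation
  "k_hog_sln", "k_hog_sho", "k_hog_dephos",       # Hog1 cycle
  "k_mrna_syn", "k_mrna_deg",                     # transcription
  "k_prot_syn", "k_prot_deg",                     # translation
  "k_gly_prot",                                   # glycerol via protein
  "k_gly_hog",                                    # glycerol via Hog1PP (removable)
  "K_gly_inh")                                    # signal-closing glycerol level

# Defaults tuned so that the surrogate reproduces the qualitative phenomena
# the framework is designed to probe: asymmetric branch fluxes (the whole
# Sho1 route runs at 0.4x the Sln1 analogues), a transient Hog1PP pulse that
# adapts away within 160 min, peak Hog1PP monotone in dose over 0.07-0.8 M,
# and a Hog1PP-dependent glycerol term that carries a substantial share of
# the adaptation flux so that removing it is a consequential simplification.
.bench_defaults <- c(
  k_act_sln    = 2.0,
  k_deact_sln  = 0.6,
  k_bind_sho   = 0.8,    # 0.4 * k_act_sln
  k_unbind_sho = 0.24,   # 0.4 * k_deact_sln
  k_phos_sho   = 0.8,
  k_dephos_sho = 0.3,
  k_hog_sln    = 0.6,
  k_hog_sho    = 0.24,   # 0.4 * k_hog_sln
  k_hog_dephos = 0.3,
  k_mrna_syn   = 0.08,
  k_mrna_deg   = 0.06,
  k_prot_syn   = 0.08,
  k_prot_deg   = 0.04,
  k_gly_prot   = 0.004,
  k_gly_hog    = 0.024,
  K_gly_inh    = 0.15)

.bench_initial_state <- function(condition) {
  c(P = 0, C = 0, CP = 0, H = 100, HPP = 0, M = 0, PR = 0, G = 0)
}

.bench_observe <- function(out) {
  data.frame(time = out[, "time"],
             Hog1PP = out[, "HPP"],
             mRNA = out[, "M"],
             protein = out[, "PR"],
             glycerol = out[, "G"])
}

# assemble the 19-element low-level parameter vector for the C rhs;
# `fixed` carries parameters frozen out of a structure (k_gly_hog = 0 in the
# simplified model)
.bench_map_params <- function(fixed = numeric(0)) {
  function(values, condition) {
    full <- numeric(length(.bench_param_names))
    names(full) <- .bench_param_names
    full[names(values)] <- values
    full[names(fixed)] <- fixed
    c(unname(full),
      condition$sln1_active, condition$sho1_active, condition$dose)
  }
}

#' Built-in benchmark model pair
#'
#' Returns the surrogate osmostress benchmark used throughout the package: a
#' \emph{true} structure in which active Hog1 (Hog1PP) directly stimulates
#' glycerol production, and a \emph{simplified} structure identical in every
#' state, parameter and term except that this post-translational
#' Hog1PP-to-glycerol interaction is removed (its coefficient fixed to zero).
#' Synthetic data are generated from the true structure; model selection asks
#' whether validation data can tell the two structures apart.
#'
#' The model has 8 states: the active Sln1-route Pbs2 pool, the Sho1.Pbs2
#' complex and its phosphorylated form, unphosphorylated Hog1 and Hog1PP
#' (conserved sum of 100, so Hog1PP is a percentage), stress mRNA, protein
#' and internal glycerol.  Both activation branches are driven by the osmotic
#' signal \code{dose / (1 + (G/K_gly_inh)^2)}, which accumulated glycerol
#' shuts off; this closes the adaptation loop.  All Sho1-route rate constants
#' default to 0.4 times their Sln1-route analogues, which makes the two
#' branches asymmetric in flux.
#'
#' @param defaults optional named vector overriding default parameter values.
#' @param bound_factor upper bounds of the returned parameter set are
#'   \code{bound_factor} times the default values (lower bounds are 0).  The
#'   default of 2 encodes the study's prior assumption that parameter ranges
#'   are known to span intervals twice as big as the true values.
#' @return A list with elements \code{true} and \code{simplified} (both
#'   \code{odem_model}) and \code{params} (the default
#'   \code{odem_parameter_set} of the true structure).
#' @examples
#' bm <- make_benchmark_models()
#' sim <- simulate_model(bm$true, bm$params, condition_for("WT", 0.5),
#'                       times = seq(0, 160, by = 10))
#' max(sim$Hog1PP)
#' @export
make_benchmark_models <- function(defaults = NULL, bound_factor = 2) {
  values <- .bench_defaults
  if (!is.null(defaults)) {
    if (!all(names(defaults) %in% .bench_param_names))
      stop("unknown parameter names in defaults")
    values[names(defaults)] <- defaults
  }
  true <- model_structure(
    name = "benchmark_true",
    state_names = .bench_state_names,
    parameter_names = .bench_param_names,
    observe = .bench_observe,
    initial_state = .bench_initial_state,
    compiled = list(func = "hog_derivs", initfunc = "hog_init",
                    dllname = "odemval"),
    map_params = .bench_map_params(),
    obs_map = c(Hog1PP = "HPP", mRNA = "M", protein = "PR",
                glycerol = "G"))
  simp_names <- setdiff(.bench_param_names, "k_gly_hog")
  simplified <- model_structure(
    name = "benchmark_simplified",
    state_names = .bench_state_names,
    parameter_names = simp_names,
    observe = .bench_observe,
    initial_state = .bench_initial_state,
    compiled = list(func = "hog_derivs", initfunc = "hog_init",
                    dllname = "odemval"),
    map_params = .bench_map_params(fixed = c(k_gly_hog = 0)),
    obs_map = c(Hog1PP = "HPP", mRNA = "M", protein = "PR",
                glycerol = "G"))
  params <- parameter_set(values, lower = 0, upper = bound_factor * values)
  list(true = true, simplified = simplified, params = params)
}

#' Restrict a parameter set to the parameters of a structure
#'
#' Used to derive the starting point for fitting the simplified structure
#' from the generating parameters of the true structure.
#'
#' @param params an \code{odem_parameter_set}.
#' @param model an \code{odem_model}.
#' @return An \code{odem_parameter_set} holding only the model's parameters.
#' @export
params_for_model <- function(params, model) {
  keep <- model$parameter_names
  parameter_set(params$values[keep], lower = params$lower[keep],
                upper = params$upper[keep])
}

#' Read a benchmark model configuration from YAML
#'
#' The file may contain \code{parameters} (named values), \code{lower} and
#' \code{upper} bounds, and a logical \code{feedback} flag; with
#' \code{feedback: false} the structure returned as \code{model} is the
#' simplified one (no Hog1PP-to-glycerol term).
#'
#' @param path path to a YAML file.
#' @return A list with \code{model}, \code{params} and the full benchmark
#'   pair in \code{pair}.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ov <- if (!is.null(cfg$parameters)) unlist(cfg$parameters) else NULL
  pair <- make_benchmark_models(defaults = ov)
  params <- pair$params
  if (!is.null(cfg$lower) || !is.null(cfg$upper)) {
    lo <- params$lower; up <- params$upper
    if (!is.null(cfg$lower)) lo[names(cfg$lower)] <- unlist(cfg$lower)
    if (!is.null(cfg$upper)) up[names(cfg$upper)] <- unlist(cfg$upper)
    params <- parameter_set(params$values, lower = lo, upper = up)
  }
  feedback <- if (is.null(cfg$feedback)) TRUE else isTRUE(cfg$feedback)
  model <- if (feedback) pair$true else pair$simplified
  list(model = model,
       params = if (feedback) params else params_for_model(params, model),
       pair = pair)
}
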