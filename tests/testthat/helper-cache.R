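# Solutions and simulations shared across test files (solving the default
# configuration takes a few seconds, so each is computed once per run).
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

default_params <- function() task_params()

single_default <- function() cached("single_default",
  solve_single_trial(default_params()))

avg_default <- function() cached("avg_default",
  solve_average_reward(default_params()))

fixed_default <- function(kind) cached(paste0("fixed_", kind),
  fixed_policy(kind, default_params()))

# 10,000 continuing trials under the default average-reward policy
sim_default <- function() cached("sim_default",
  run_trials(avg_default(), 10000, seed = 42))

opto_solutions <- function() cached("opto_solutions", list(
  optimal = avg_default(),
  always_strong = fixed_default("always_strong"),
  always_weak = fixed_default("always_weak")))

opto_run <- function(condition) cached(paste0("opto_", condition),
  run_optogenetic_condition(condition, default_params(), n_trials = 10000,
                            seed = 42, solutions = opto_solutions()))

# sequential session at the regime of the phasic-ACh simulations
session_default <- function() cached("session_default",
  run_session(cached("session_config", session_config()), 10000, seed = 42))

# episodic sweeps behind the breaking-point checks (no baselines: only the
# optimal policy's occupancy is needed)
sweep_cached <- function(param, values) {
  key <- paste0("sweep_", param)
  cached(key, sweep_parameter(param, values, mode = "single",
                              include_baselines = FALSE))
}
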