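# Shared fixtures: small parameter sets and setups built in code.

# default parameter set with overrides
fix_params <- function(...) {
  over <- list(...)
  do.call(model_parameters, over)
}

# a small, fast batch setup (diauxic growth within ~6 h)
fix_batch_setup <- function(params = fix_params(), G0 = 2, C_M0 = 0.2,
                            t_END = 8, ...) {
  experiment_setup(
    initial_state = state_vector(G = G0, P = 5e-5, C_M = C_M0),
    t0 = 0, t_END = t_END, params = params, ...
  )
}

# a small exponential fed-batch setup
fix_fedbatch_setup <- function(params = fix_params(), mu = 0.15, t_F = 2,
                               t_END = 10, c_F = 50, M_F = 0.5, y_R = 0.5,
                               C_M0 = 0.5, ...) {
  experiment_setup(
    initial_state = state_vector(G = 0.5, P = 5e-5, C_M = C_M0),
    t0 = 0, t_END = t_END,
    feeding = feeding_profile("exponential", t_F = t_F, mu = mu, c_F = c_F,
                              M_F = M_F, y_R = y_R),
    params = params, ...
  )
}

# a plain state for kernel-level tests
fix_state <- function(...) {
  args <- list(...)
  defaults <- list(G = 1, P = 0.05, E = 0.5, C_M = 2, R = 0.3, I = 0.1,
                   D = 0.1, V = 1)
  defaults[names(args)] <- args
  do.call(state_vector, defaults)
}

# state with C_M = 1 g, R = 0 and P chosen so the intracellular [P] is exact:
# [P] = P / ((P + C_M) c)  =>  P = [P] c C_M / (1 - [P] c)
fix_state_concP <- function(conc_P, params, ...) {
  P <- conc_P * params$c / (1 - conc_P * params$c)
  fix_state(C_M = 1, R = 0, P = P, E = 0, I = 0, ...)
}

# minimal object quacking like a simulation_result, for arithmetic oracles
fix_fake_sim <- function(time_h, ...) {
  cols <- list(...)
  tr <- data.frame(time_h = time_h, cols)
  structure(list(trajectory = tr,
                 events = data.frame(time_h = numeric(0), event = character(0)),
                 setup = NULL, dt_report = diff(time_h)[1]),
            class = "simulation_result")
}

# cache scenario simulations across tests within a file
.sim_cache <- new.env(parent = emptyenv())
fix_scenario_sim <- function(name, ...) {
  key <- paste(name, ..., sep = "|")
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- run_simulation(load_scenario(name), ...)
  }
  .sim_cache[[key]]
}
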