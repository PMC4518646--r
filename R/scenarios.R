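# Packaged growth scenarios and configuration (de)serialization.

#' List the packaged growth scenarios
#'
#' Scenario bundles (initial state + timing + feeding + calibrated strain
#' parameters) for the four yeast strains: an aerobic batch culture
#' (LBG H 1022), a short two-phase fed-batch (CBS 8066), extended
#' exponential fed-batches of the prototroph CEN.PK113-7D and the auxotroph
#' CEN.PK2-1C at three specific feed rates, and the variable
#' (logistically-decreasing mu*) feeding run. Several tabulated setup values
#' in the sources are typographically ambiguous; the packaged files mark the
#' adopted readings as `reconstructed`, and every value can be overridden in
#' a user configuration file.
#'
#' @return Character vector of scenario names accepted by
#'   [load_scenario()].
#' @export
#' @examples
#' list_scenarios()
list_scenarios <- function() {
  dir <- system.file("extdata", "scenarios", package = "fedbatchsim")
  sort(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
}

#' Load an experiment configuration
#'
#' Reads a packaged scenario by name, or any scenario configuration file in
#' the same YAML layout, validates every field and returns a ready-to-run
#' [experiment_setup()]. Validation failures enumerate the offending
#' fields.
#'
#' @param name a packaged scenario name (see [list_scenarios()]) or a path
#'   to a YAML configuration file.
#' @return An [experiment_setup()].
#' @export
#' @examples
#' setup <- load_scenario("cenpk113_7d_fedbatch_016")
#' setup$feeding$mu
load_scenario <- function(name) {
  path <- if (file.exists(name)) {
    name
  } else {
    p <- system.file("extdata", "scenarios", paste0(name, ".yaml"),
                     package = "fedbatchsim")
    if (!nzchar(p)) {
      stop("unknown scenario '", name, "'; packaged scenarios: ",
           paste(list_scenarios(), collapse = ", "), call. = FALSE)
    }
    p
  }
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("cannot parse configuration '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  setup_from_config(cfg)
}

#' Build an experiment setup from a parsed configuration list
#'
#' @param cfg a named list with blocks `initial_state`, `time`, `feeding`
#'   and `parameters` (see the packaged files under
#'   `system.file("extdata", "scenarios", package = "fedbatchsim")` for the
#'   layout).
#' @return An [experiment_setup()].
#' @export
setup_from_config <- function(cfg) {
  need <- c("initial_state", "time", "feeding", "parameters")
  missing_blocks <- setdiff(need, names(cfg))
  if (length(missing_blocks)) {
    stop("configuration is missing block(s): ",
         paste(missing_blocks, collapse = ", "), call. = FALSE)
  }
  is_block <- cfg$initial_state
  state <- tryCatch(
    state_vector(
      G = is_block$G0 %||% 0, P = is_block$P0 %||% 0,
      E = is_block$E0 %||% 0, C_M = is_block$C_M0 %||% 0,
      R = is_block$R0 %||% 0, I = is_block$I0 %||% 0,
      D = is_block$D0 %||% 0, V = is_block$V0 %||% 1
    ),
    error = function(e) stop("initial_state: ", conditionMessage(e),
                             call. = FALSE)
  )
  fb <- cfg$feeding
  feeding <- tryCatch(
    feeding_profile(
      mode = fb$mode %||% "none", t_F = fb$t_F, mu = fb$mu,
      t_switch = fb$t_switch %||% 3, m1 = fb$m1, m2 = fb$m2, m3 = fb$m3,
      c_F = fb$c_F, M_F = fb$M_F, y_R = fb$y_R
    ),
    error = function(e) stop("feeding: ", conditionMessage(e), call. = FALSE)
  )
  params <- tryCatch(
    do.call(model_parameters, cfg$parameters),
    error = function(e) stop("parameters: ", conditionMessage(e),
                             call. = FALSE)
  )
  experiment_setup(
    initial_state = state, t0 = cfg$time$t0 %||% 0, t_END = cfg$time$t_END,
    feeding = feeding, params = params,
    lag_enabled = isTRUE(cfg$lag_enabled),
    volume_mode = cfg$volume_mode %||% "consistent",
    name = cfg$name
  )
}

#' Serialize an experiment setup to a configuration list or file
#'
#' The written document round-trips: `load_scenario(write_scenario(setup,
#' path))` reproduces the setup exactly.
#'
#' @param setup an [experiment_setup()].
#' @param path optional file path; when given, a YAML file is written.
#' @return The configuration list (invisibly when `path` is given).
#' @export
write_scenario <- function(setup, path = NULL) {
  s <- setup$initial_state
  fb <- setup$feeding
  drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
  cfg <- list(
    name = setup$name,
    initial_state = list(G0 = s[["G"]], P0 = s[["P"]], E0 = s[["E"]],
                         C_M0 = s[["C_M"]], R0 = s[["R"]], I0 = s[["I"]],
                         D0 = s[["D"]], V0 = s[["V"]]),
    time = list(t0 = setup$t0, t_END = setup$t_END),
    feeding = drop_null(list(mode = fb$mode, t_F = fb$t_F, mu = fb$mu,
                             t_switch = if (fb$mode == "two_phase") fb$t_switch,
                             m1 = fb$m1, m2 = fb$m2, m3 = fb$m3,
                             c_F = fb$c_F, M_F = fb$M_F, y_R = fb$y_R)),
    lag_enabled = setup$lag_enabled,
    volume_mode = setup$volume_mode,
    parameters = drop_null(unclass(setup$params))
  )
  cfg <- drop_null(cfg)
  if (!is.null(path)) {
    yaml::write_yaml(cfg, path, precision = 15)
    return(invisible(cfg))
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
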