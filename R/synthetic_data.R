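# Pseudo-experimental observation sets: hourly sampling of the three
# monitored concentrations with multiplicative measurement noise, for
# calibration and parameter-recovery studies.

#' Measurement-noise specification
#'
#' Emulates the sampling and noise characteristics of bioreactor
#' monitoring: samples withdrawn at a fixed interval (hourly by default),
#' analysed in replicate (triplicate by default), with relative measurement
#' error below a few percent. Noise is multiplicative Gaussian —
#' `value = truth * (1 + eps)`, `eps ~ N(0, cv)` — truncated at zero to
#' keep concentrations physical; the reported observation is the replicate
#' mean, so the effective noise on reported points is roughly
#' `cv / sqrt(replicates)`.
#'
#' @param cv coefficient of variation of a single measurement (default
#'   0.05, i.e. relative sd of 5%).
#' @param interval sampling interval in hours (default 1).
#' @param replicates technical replicates averaged per reported point
#'   (default 3).
#' @param seed integer seed making generation reproducible.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(cv = 0.05, interval = 1, replicates = 3, seed = 1) {
  if (!is.numeric(cv) || cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (!is.numeric(interval) || interval <= 0) {
    stop("sampling interval must be positive", call. = FALSE)
  }
  if (!is.numeric(replicates) || replicates < 1) {
    stop("need at least one replicate", call. = FALSE)
  }
  structure(list(cv = cv, interval = interval,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Generate a synthetic observation set from a simulation
#'
#' Samples the simulated mass, glucose and ethanol concentrations at the
#' specified interval, corrupts each with multiplicative Gaussian noise per
#' replicate (truncated at zero), and reports replicate means. Identical
#' seeds give identical observation sets; the global RNG state is left
#' untouched.
#'
#' @param sim a [run_simulation()] result spanning the sampling times.
#' @param spec a [noise_spec()].
#' @param channels which channels to sample (default all three).
#' @return An [observation_set()].
#' @export
#' @examples
#' sim <- run_simulation(load_scenario("lbg_h1022_batch"))
#' obs <- generate_observations(sim, noise_spec(cv = 0.05, seed = 42))
#' head(obs)
generate_observations <- function(sim, spec = noise_spec(),
                                  channels = OBS_CHANNELS) {
  stopifnot(inherits(sim, "simulation_result"), inherits(spec, "noise_spec"))
  channels <- match.arg(channels, OBS_CHANNELS, several.ok = TRUE)
  tr <- sim$trajectory
  t_min <- tr$time_h[1]
  t_max <- tr$time_h[nrow(tr)]
  times <- seq(ceiling(t_min / spec$interval) * spec$interval, t_max,
               by = spec$interval)
  if (length(times) == 0) stop("no sampling times within the simulated span",
                               call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(spec$seed)
  rows <- lapply(channels, function(ch) {
    truth <- .predict_at(sim, times, ch)
    vals <- vapply(truth, function(mu) {
      reps <- pmax(mu * (1 + stats::rnorm(spec$replicates, 0, spec$cv)), 0)
      mean(reps)
    }, numeric(1))
    data.frame(time_h = times, channel = ch, value_g_per_l = vals)
  })
  observation_set(do.call(rbind, rows))
}

#' Parameter-recovery experiment
#'
#' The self-consistency check behind calibration: simulate a scenario at
#' known ("true") parameters, corrupt the trajectory into synthetic
#' observations, re-fit the free parameters from a perturbed start, and
#' report the relative error of each recovered parameter — repeated over
#' `n_seeds` independent noise realizations.
#'
#' @param setup an [experiment_setup()] whose parameters are the truth.
#' @param free character vector of parameter names to recover.
#' @param spec a [noise_spec()]; its seed is the base seed, incremented per
#'   replicate run.
#' @param n_seeds number of noise realizations (default 10).
#' @param start_factor multiplicative perturbation applied to the true
#'   values to form the calibration start (alternating `*` and `/` across
#'   the free set; default 1.2, i.e. +/-20%).
#' @param dt_report,control forwarded to [calibrate()].
#' @return An object of class `recovery_report`: per-seed recovered values
#'   and relative errors, plus per-parameter summaries (median absolute
#'   relative error, bias, spread).
#' @export
recovery_experiment <- function(setup, free, spec = noise_spec(),
                                n_seeds = 10, start_factor = 1.2,
                                dt_report = 0.1,
                                control = list(reltol = 1e-6, maxit = 2000)) {
  stopifnot(inherits(setup, "experiment_setup"))
  if (length(free) == 0) stop("the free parameter set must be non-empty",
                              call. = FALSE)
  truth <- vapply(free, function(nm) setup$params[[nm]], numeric(1))
  start <- truth * start_factor^rep_len(c(1, -1), length(free))
  names(start) <- free
  base_sim <- run_simulation(setup, dt_report = dt_report)

  runs <- lapply(seq_len(n_seeds), function(k) {
    spec_k <- spec
    spec_k$seed <- spec$seed + k - 1L
    obs <- generate_observations(base_sim, spec_k)
    fit <- calibrate(setup, obs, free = free, start = start,
                     dt_report = dt_report, control = control)
    rel_err <- fit$fitted[free] / truth - 1
    data.frame(seed = spec_k$seed, parameter = free,
               truth = unname(truth), recovered = unname(fit$fitted[free]),
               rel_error = unname(rel_err), sse = fit$sse)
  })
  per_run <- do.call(rbind, runs)
  summary <- do.call(rbind, lapply(free, function(nm) {
    e <- per_run$rel_error[per_run$parameter == nm]
    data.frame(parameter = nm, truth = truth[[nm]],
               median_abs_rel_error = stats::median(abs(e)),
               bias = mean(e), sd = stats::sd(e))
  }))
  structure(list(per_run = per_run, summary = summary, free = free,
                 n_seeds = n_seeds, cv = spec$cv),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d seeds at cv = %g\n", x$n_seeds, x$cv))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
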