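# Experiment setup and ODE integration over a bioreactor timeline.

#' Define a bioreactor experiment
#'
#' Bundles initial state, timing, feeding profile and kinetic parameters
#' into a validated setup ready for [run_simulation()].
#'
#' @param initial_state a [state_vector()] (masses in g, V0 in l).
#' @param t0,t_END simulation start and end times (h).
#' @param feeding a [feeding_profile()]; the default is batch (no feeding).
#' @param params a [model_parameters()] object.
#' @param lag_enabled apply the lag-phase multiplier on glucose uptake?
#'   Requires lag parameters in `params`.
#' @param volume_mode `"consistent"` (default) integrates
#'   `dV/dt = feed rate` from `V0`; `"tabulated"` uses the tabulated
#'   closed-form volume law instead (exponential feeding only), see
#'   [literal_volume()].
#' @param name optional scenario name carried into outputs.
#' @return An object of class `experiment_setup`.
#' @export
#' @examples
#' setup <- experiment_setup(
#'   initial_state = state_vector(G = 9, E = 0.1, P = 5e-5, C_M = 0.17),
#'   t0 = 3, t_END = 21, params = model_parameters()
#' )
experiment_setup <- function(initial_state, t0 = 0, t_END,
                             feeding = feeding_profile("none"),
                             params, lag_enabled = FALSE,
                             volume_mode = c("consistent", "tabulated"),
                             name = NULL) {
  volume_mode <- match.arg(volume_mode)
  validate_state(initial_state)
  params <- validate_parameters(params)
  feeding <- validate_feeding_profile(feeding)
  if (!is.numeric(t0) || !is.numeric(t_END) || t_END <= t0) {
    stop("need t0 < t_END", call. = FALSE)
  }
  if (feeding$mode != "none" &&
      (feeding$t_F < t0 || feeding$t_F > t_END)) {
    stop("feeding start t_F must lie within [t0, t_END]", call. = FALSE)
  }
  if (volume_mode == "tabulated" && feeding$mode != "exponential") {
    stop("tabulated volume mode requires an exponential feeding profile",
         call. = FALSE)
  }
  if (lag_enabled && is.null(params$l1)) {
    stop("lag_enabled = TRUE requires lag parameters l1, l2, l3", call. = FALSE)
  }
  structure(
    list(initial_state = initial_state[STATE_NAMES], t0 = t0, t_END = t_END,
         feeding = feeding, params = params, lag_enabled = lag_enabled,
         volume_mode = volume_mode, V0 = initial_state[["V"]], name = name),
    class = "experiment_setup"
  )
}

#' @export
print.experiment_setup <- function(x, ...) {
  cat("<experiment_setup>", if (!is.null(x$name)) x$name else "", "\n")
  cat(sprintf("  t0 = %g h, t_END = %g h, volume mode: %s, lag: %s\n",
              x$t0, x$t_END, x$volume_mode,
              if (x$lag_enabled) "on" else "off"))
  cat("  initial state:\n")
  print(x$initial_state)
  print(x$feeding)
  invisible(x)
}

#' Microbial mass concentration
#'
#' The observable matched to optical-density readings:
#' `[M] = (P + C_M + R + D) / V`, i.e. viable biomass plus dead cells per
#' litre of medium. Vectorised over rows of a trajectory data frame.
#'
#' @param state a named state vector, or a data frame with columns
#'   `P, C_M, R, D, V`.
#' @return Mass concentration (g l^-1).
#' @export
#' @examples
#' mass_concentration(state_vector(P = 2, C_M = 4, R = 1, D = 3, V = 2))  # 5
mass_concentration <- function(state) {
  if (is.data.frame(state)) {
    if (any(state$V <= 0)) stop("volume must be positive", call. = FALSE)
    return((state$P + state$C_M + state$R + state$D) / state$V)
  }
  validate_state(state)
  (state[["P"]] + state[["C_M"]] + state[["R"]] + state[["D"]]) / state[["V"]]
}

#' Non-viable fraction of the population
#'
#' `D / (P + C_M + R + D)`: the share of total cell mass in the dead pool,
#' comparable to 1 minus plate-count viability.
#'
#' @inheritParams mass_concentration
#' @return Fraction in \[0, 1\].
#' @export
nonviable_fraction <- function(state) {
  if (is.data.frame(state)) {
    tot <- state$P + state$C_M + state$R + state$D
    if (any(tot <= 0)) stop("total cell mass is zero: fraction undefined",
                            call. = FALSE)
    return(state$D / tot)
  }
  validate_state(state)
  tot <- state[["P"]] + state[["C_M"]] + state[["R"]] + state[["D"]]
  if (tot <= 0) stop("total cell mass is zero: fraction undefined",
                     call. = FALSE)
  state[["D"]] / tot
}

# integrate one segment with root-finding on [P] - tau; returns rows at the
# requested times plus the restart state and any crossing times found
.integrate_segment <- function(y, times, parms, method, atol, rtol,
                               use_root, maxsteps) {
  crossings <- numeric(0)
  rows <- NULL
  t_cur <- times[1]
  remaining <- times
  guard <- 0
  repeat {
    guard <- guard + 1
    if (guard > 500) {
      stop("death-switch root finding did not settle (", guard,
           " restarts) near t = ", signif(t_cur, 6), call. = FALSE)
    }
    out <- deSolve::ode(
      y = y, times = remaining, func = .rhs_desolve, parms = parms,
      method = method, atol = atol, rtol = rtol, maxsteps = maxsteps,
      rootfunc = if (use_root) .root_death_switch else NULL
    )
    istate <- attr(out, "istate")
    troot <- attr(out, "troot")
    out <- as.data.frame(unclass(out))
    if (nrow(out) > 0) {
      hit_root <- use_root && !is.null(troot) && length(troot) > 0
      if (hit_root) {
        # the last row is the root point; keep it only if it is a grid time
        t_last <- out$time[nrow(out)]
        keep <- out$time %in% remaining
        rows <- rbind(rows, out[keep, , drop = FALSE])
        crossings <- c(crossings, t_last)
        y <- unlist(out[nrow(out), STATE_NAMES])
        t_cur <- t_last
        remaining <- c(t_cur, remaining[remaining > t_cur + 1e-12])
        if (length(remaining) <= 1) break
        next
      }
      rows <- rbind(rows, out)
    }
    if (!is.null(istate) && istate[1] < 0) {
      stop("integration failed near t = ",
           signif(out$time[nrow(out)], 6), " (istate = ", istate[1], ")",
           call. = FALSE)
    }
    break
  }
  rows <- rows[!duplicated(rows$time), , drop = FALSE]
  rows <- rows[order(rows$time), , drop = FALSE]
  y_end <- unlist(rows[nrow(rows), STATE_NAMES])
  list(rows = rows, y_end = y_end, crossings = crossings)
}

#' Simulate a bioreactor experiment
#'
#' Integrates the mass balances from `t0` to `t_END` with a stiff-capable
#' solver. The timeline is split at feeding start (and, for two-phase
#' feeding, at the exponential-to-constant switch), and the discontinuous
#' death switch is handled event-accurately by root-finding on
#' `[P] - tau` with integration restarts at each crossing; alternatively a
#' smoothed switch can be requested. Output is reported on a dense fixed
#' grid independent of the solver's internal steps.
#'
#' @param setup an [experiment_setup()].
#' @param dt_report reporting interval (h) of the output grid; default
#'   0.05 h.
#' @param atol,rtol absolute/relative solver tolerances.
#' @param method a `deSolve` method name; default `"lsoda"` switches
#'   automatically between stiff and non-stiff regimes.
#' @param death_switch `"event"` (sharp switch + root finding, default) or
#'   `"smooth"` (steep-logistic switch, no events).
#' @param smooth_steepness steepness of the smoothed switch (l g^-1).
#' @param maxsteps maximum internal solver steps per output interval.
#' @return An object of class `simulation_result`: a list with `trajectory`
#'   (data frame: `time_h`, the eight states `G_g` ... `V_l`, observables
#'   `M_conc`, `G_conc`, `E_conc`, `I_conc`, `nonviable_frac`, and the
#'   auxiliaries `conc_P`, `ge`, `mo`, `n_E`, `n_I`, `lag`, `d`), `events`
#'   (feeding start and death-switch crossing times), and the `setup`.
#' @export
#' @examples
#' setup <- load_scenario("lbg_h1022_batch")
#' sim <- run_simulation(setup)
#' head(as.data.frame(sim))
run_simulation <- function(setup, dt_report = 0.05, atol = 1e-8, rtol = 1e-8,
                           method = "lsoda",
                           death_switch = c("event", "smooth"),
                           smooth_steepness = 500, maxsteps = 50000) {
  stopifnot(inherits(setup, "experiment_setup"))
  death_switch <- match.arg(death_switch)
  parms <- list(params = setup$params, setup = setup,
                death_switch = if (death_switch == "event") "sharp" else "smooth",
                smooth_steepness = smooth_steepness)
  grid <- seq(setup$t0, setup$t_END, by = dt_report)
  if (grid[length(grid)] < setup$t_END) grid <- c(grid, setup$t_END)

  breaks <- setup$t0
  if (setup$feeding$mode != "none" && setup$feeding$t_F > setup$t0) {
    breaks <- c(breaks, setup$feeding$t_F)
  }
  if (setup$feeding$mode == "two_phase") {
    t_sw <- setup$feeding$t_F + setup$feeding$t_switch
    if (t_sw < setup$t_END) breaks <- c(breaks, t_sw)
  }
  breaks <- sort(unique(c(breaks, setup$t_END)))

  y <- setup$initial_state
  use_root <- death_switch == "event"
  all_rows <- NULL
  crossings <- numeric(0)
  for (i in seq_len(length(breaks) - 1)) {
    seg_times <- sort(unique(c(breaks[i], grid[grid > breaks[i] & grid < breaks[i + 1]],
                               breaks[i + 1])))
    seg <- .integrate_segment(y, seg_times, parms, method, atol, rtol,
                              use_root, maxsteps)
    y <- seg$y_end
    crossings <- c(crossings, seg$crossings)
    rows <- seg$rows
    if (!is.null(all_rows)) rows <- rows[rows$time > breaks[i] + 1e-12, , drop = FALSE]
    all_rows <- rbind(all_rows, rows)
  }
  traj <- all_rows[all_rows$time %in% grid | all_rows$time == setup$t_END, ,
                   drop = FALSE]
  traj <- traj[order(traj$time), , drop = FALSE]
  traj[STATE_NAMES] <- lapply(traj[STATE_NAMES], pmax, 0)
  traj$V <- pmax(traj$V, .Machine$double.eps)
  if (setup$volume_mode == "tabulated") {
    traj$V <- literal_volume(traj$time, setup$feeding, setup$V0)
  }

  aux <- lapply(seq_len(nrow(traj)), function(i) {
    compute_auxiliaries(unlist(traj[i, STATE_NAMES]), setup$params,
                        t = traj$time[i], lag_enabled = setup$lag_enabled,
                        death_switch = if (use_root) "sharp" else "smooth",
                        smooth_steepness = smooth_steepness, validate = FALSE)
  })
  pull <- function(field) vapply(aux, `[[`, numeric(1), field)
  trajectory <- data.frame(
    time_h = traj$time,
    G_g = traj$G, P_g = traj$P, E_g = traj$E, CM_g = traj$C_M,
    R_g = traj$R, I_g = traj$I, D_g = traj$D, V_l = traj$V,
    M_conc = (traj$P + traj$C_M + traj$R + traj$D) / traj$V,
    G_conc = pull("conc_G"), E_conc = pull("conc_E"), I_conc = pull("conc_I"),
    nonviable_frac = ifelse(traj$P + traj$C_M + traj$R + traj$D > 0,
                            traj$D / (traj$P + traj$C_M + traj$R + traj$D), 0),
    conc_P = pull("conc_P"), ge = pull("ge"), mo = pull("mo"),
    n_E = pull("n_E"), n_I = pull("n_I"), lag = pull("lag"), d = pull("d")
  )
  events <- data.frame(time_h = numeric(0), event = character(0))
  if (setup$feeding$mode != "none") {
    events <- rbind(events, data.frame(time_h = setup$feeding$t_F,
                                       event = "feeding_start"))
  }
  if (length(crossings)) {
    events <- rbind(events, data.frame(time_h = crossings,
                                       event = "death_switch_crossing"))
  }
  structure(list(trajectory = trajectory, events = events, setup = setup,
                 dt_report = dt_report),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  tr <- x$trajectory
  cat("<simulation_result>", if (!is.null(x$setup$name)) x$setup$name else "",
      "\n")
  cat(sprintf("  %d time points over [%g, %g] h\n", nrow(tr),
              tr$time_h[1], tr$time_h[nrow(tr)]))
  cat(sprintf("  final: [M] = %.3g g/l, [G] = %.3g g/l, [E] = %.3g g/l, non-viable = %.1f%%\n",
              tr$M_conc[nrow(tr)], tr$G_conc[nrow(tr)], tr$E_conc[nrow(tr)],
              100 * tr$nonviable_frac[nrow(tr)]))
  if (nrow(x$events)) {
    cat("  events:\n")
    for (i in seq_len(nrow(x$events))) {
      cat(sprintf("    %-22s t = %.3f h\n", x$events$event[i], x$events$time_h[i]))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.simulation_result <- function(x, ...) {
  x$trajectory[, c("time_h", "G_g", "P_g", "E_g", "CM_g", "R_g", "I_g",
                   "D_g", "V_l", "M_conc", "G_conc", "E_conc", "I_conc",
                   "nonviable_frac")]
}

#' Write a simulation trajectory to CSV
#'
#' @param sim a [run_simulation()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(sim, path) {
  utils::write.csv(as.data.frame(sim), path, row.names = FALSE)
  invisible(path)
}

#' Fixed-step 4th-order Runge-Kutta reference integration
#'
#' A deliberately simple explicit integrator used as an independent check of
#' the adaptive stiff solver: no step-size control, no event handling, no
#' Jacobian. Intended for verification at small steps, not production use.
#'
#' @param setup an [experiment_setup()].
#' @param h fixed step size (h); must divide the reporting interval.
#' @param dt_report reporting interval (h).
#' @return A data frame with `time_h`, state columns and the three main
#'   observables.
#' @export
run_simulation_rk4 <- function(setup, h = 1e-3, dt_report = 0.5) {
  stopifnot(inherits(setup, "experiment_setup"))
  steps_per_report <- round(dt_report / h)
  stopifnot(abs(steps_per_report * h - dt_report) < 1e-9)
  n_report <- ceiling((setup$t_END - setup$t0) / dt_report)
  y <- setup$initial_state
  f <- function(t, y) {
    y_pos <- pmax(y, 0)
    y_pos[["V"]] <- max(y[["V"]], .Machine$double.eps)
    derivatives(t, y_pos, setup$params, setup)
  }
  out <- matrix(NA_real_, nrow = n_report + 1, ncol = length(y) + 1)
  out[1, ] <- c(setup$t0, y)
  t <- setup$t0
  for (i in seq_len(n_report)) {
    for (j in seq_len(steps_per_report)) {
      k1 <- f(t, y)
      k2 <- f(t + h / 2, y + h / 2 * k1)
      k3 <- f(t + h / 2, y + h / 2 * k2)
      k4 <- f(t + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[i + 1, ] <- c(t, y)
  }
  df <- as.data.frame(out)
  names(df) <- c("time_h", STATE_NAMES)
  df[STATE_NAMES] <- lapply(df[STATE_NAMES], pmax, 0)
  df$M_conc <- (df$P + df$C_M + df$R + df$D) / df$V
  df$G_conc <- df$G / df$V
  df$E_conc <- df$E / df$V
  df
}
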