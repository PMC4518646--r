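# Least-squares calibration of model parameters against observed time
# series, with a derivative-free simplex search.

OBS_CHANNELS <- c("mass", "glucose", "ethanol")

# trajectory column carrying each observed channel; the mass channel is the
# optical-density observable [M] = (P + C_M + R + D)/V, which includes dead
# cells (optical density cannot distinguish them)
.channel_column <- c(mass = "M_conc", glucose = "G_conc", ethanol = "E_conc")

#' Construct an observation set
#'
#' Observed concentrations of the three monitored channels — microbial mass,
#' residual glucose and ethanol, all in g l^-1 — at sampled times.
#'
#' @param data a data frame with columns `time_h`, `channel` (one of
#'   `"mass"`, `"glucose"`, `"ethanol"`) and `value_g_per_l`.
#' @return An object of class `observation_set` (a validated data frame).
#' @export
observation_set <- function(data) {
  need <- c("time_h", "channel", "value_g_per_l")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    stop("observations need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(data)[need]
  bad <- setdiff(unique(data$channel), OBS_CHANNELS)
  if (length(bad)) {
    stop("unknown observation channel(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0) stop("observation set is empty", call. = FALSE)
  if (any(!is.finite(data$time_h)) || any(!is.finite(data$value_g_per_l))) {
    stop("observations contain non-finite values", call. = FALSE)
  }
  if (any(data$value_g_per_l < 0)) {
    stop("observed concentrations must be non-negative", call. = FALSE)
  }
  class(data) <- c("observation_set", "data.frame")
  data
}

#' Read observations from a CSV file
#'
#' Expects the dialect written by [write_observations()]: columns `time_h`,
#' `channel`, `value_g_per_l`.
#'
#' @param path CSV file path.
#' @return An [observation_set()].
#' @export
read_observations <- function(path) {
  observation_set(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_observations
#' @param obs an [observation_set()] to write.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE)
  invisible(path)
}

# model predictions at observation times, by linear interpolation of the
# reported trajectory
.predict_at <- function(sim, times, channel) {
  tr <- sim$trajectory
  if (any(times < min(tr$time_h) - 1e-9) || any(times > max(tr$time_h) + 1e-9)) {
    stop("observation times fall outside the simulated span [",
         min(tr$time_h), ", ", max(tr$time_h), "] h", call. = FALSE)
  }
  stats::approx(tr$time_h, tr[[.channel_column[[channel]]]], xout = times,
                rule = 2)$y
}

#' Sum of squared errors between observations and a simulation
#'
#' `SSE = sum over channels of (observed - predicted)^2`, with predictions
#' obtained by linear interpolation of the simulated trajectory at the
#' observation times. The mass channel is compared to the optical-density
#' observable `[M]` (viable biomass plus dead cells). Channels are
#' unweighted by default; per-channel weights can be supplied.
#'
#' @param obs an [observation_set()].
#' @param sim a [run_simulation()] result covering all observation times.
#' @param weights named numeric vector of per-channel weights
#'   (default all 1).
#' @return Non-negative scalar.
#' @export
sse <- function(obs, sim, weights = c(mass = 1, glucose = 1, ethanol = 1)) {
  total <- 0
  for (ch in intersect(OBS_CHANNELS, unique(obs$channel))) {
    rows <- obs[obs$channel == ch, ]
    pred <- .predict_at(sim, rows$time_h, ch)
    w <- if (ch %in% names(weights)) weights[[ch]] else 1
    total <- total + w * sum((rows$value_g_per_l - pred)^2)
  }
  total
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`, comparing observed values with model
#' predictions; can be negative for fits worse than the observed mean.
#'
#' @param observed numeric vector of measurements.
#' @param predicted numeric vector of model values at the same points.
#' @return Scalar `<= 1`.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) < 2 || length(observed) != length(predicted)) {
    stop("need >= 2 paired observations", call. = FALSE)
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observations have zero variance: R^2 undefined",
                        call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}

# free-parameter transforms: log for positive parameters, logit for (0,1]
# efficiencies, so the simplex search is unconstrained
.to_unconstrained <- function(values, names) {
  vapply(seq_along(names), function(i) {
    if (names[i] %in% PARAM_UNIT) stats::qlogis(values[i]) else log(values[i])
  }, numeric(1))
}

.from_unconstrained <- function(theta, names) {
  out <- vapply(seq_along(names), function(i) {
    if (names[i] %in% PARAM_UNIT) stats::plogis(theta[i]) else exp(theta[i])
  }, numeric(1))
  names(out) <- names
  out
}

#' Calibrate model parameters against observations
#'
#' Minimizes [sse()] over a chosen set of free parameters with the
#' Nelder-Mead simplex, starting from the values in `setup` (or supplied
#' start values). Positivity and (0,1] efficiency bounds are enforced by
#' log/logit reparameterization, so the search itself is unconstrained.
#' Candidate parameter sets that violate joint constraints (e.g.
#' `eta_FE + eta_FP > 1`) or crash the simulation are penalized with a
#' large finite objective rather than aborting the search. Deterministic
#' given start values and options.
#'
#' @param setup an [experiment_setup()] whose parameters provide the fixed
#'   values and the default starting point.
#' @param obs an [observation_set()].
#' @param free character vector of parameter names to fit (non-empty).
#' @param start optional named numeric vector of start values for the free
#'   parameters.
#' @param weights per-channel weights passed to [sse()].
#' @param dt_report reporting interval (h) of the internal simulations;
#'   0.1 h keeps objective evaluations cheap while the interpolation error
#'   stays far below measurement noise.
#' @param control passed to [stats::optim()]; defaults to `reltol = 1e-6`,
#'   `maxit = 2000`.
#' @param sim_options list of further arguments for [run_simulation()].
#' @return An object of class `calibration_result`: fitted free values,
#'   the full fitted parameter set, SSE at start and optimum, per-channel
#'   R^2, convergence flag, evaluation/penalty counts.
#' @export
calibrate <- function(setup, obs, free, start = NULL,
                      weights = c(mass = 1, glucose = 1, ethanol = 1),
                      dt_report = 0.1,
                      control = list(reltol = 1e-6, maxit = 2000),
                      sim_options = list()) {
  stopifnot(inherits(setup, "experiment_setup"))
  obs <- observation_set(as.data.frame(obs))
  if (length(free) == 0) stop("the free parameter set must be non-empty",
                              call. = FALSE)
  unknown <- setdiff(free, c(PARAM_POSITIVE, PARAM_UNIT, PARAM_NONNEG))
  if (length(unknown)) {
    stop("cannot calibrate unknown/untransformable parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  start_vals <- vapply(free, function(nm) {
    v <- if (!is.null(start) && nm %in% names(start)) start[[nm]]
         else setup$params[[nm]]
    if (is.null(v) || !is.finite(v) || v <= 0) {
      stop("no usable start value for ", nm, call. = FALSE)
    }
    v
  }, numeric(1))

  n_eval <- 0L
  n_penalty <- 0L
  penalty <- 1e10
  run_candidate <- function(values) {
    p <- setup$params
    for (nm in names(values)) p[[nm]] <- values[[nm]]
    p <- tryCatch(validate_parameters(p), error = function(e) NULL)
    if (is.null(p)) return(NULL)
    cand_setup <- setup
    cand_setup$params <- p
    tryCatch(
      do.call(run_simulation,
              c(list(setup = cand_setup, dt_report = dt_report), sim_options)),
      error = function(e) NULL
    )
  }
  objective <- function(theta) {
    n_eval <<- n_eval + 1L
    values <- .from_unconstrained(theta, free)
    sim <- run_candidate(values)
    if (is.null(sim)) {
      n_penalty <<- n_penalty + 1L
      return(penalty)
    }
    tryCatch(sse(obs, sim, weights), error = function(e) {
      n_penalty <<- n_penalty + 1L
      penalty
    })
  }

  theta0 <- .to_unconstrained(start_vals, free)
  sse_start <- objective(theta0)
  # Nelder-Mead is used for any dimension (it is the calibration algorithm
  # of record here); silence R's advisory about the 1-D case
  opt <- suppressWarnings(
    stats::optim(theta0, objective, method = "Nelder-Mead", control = control)
  )
  fitted_free <- .from_unconstrained(opt$par, free)
  # simplex may end on a penalized vertex in pathological cases; fall back
  if (opt$value > sse_start) {
    fitted_free <- start_vals
    opt$value <- sse_start
  }
  fitted_params <- setup$params
  for (nm in names(fitted_free)) fitted_params[[nm]] <- fitted_free[[nm]]
  fitted_setup <- setup
  fitted_setup$params <- validate_parameters(fitted_params)
  best_sim <- do.call(run_simulation,
                      c(list(setup = fitted_setup, dt_report = dt_report),
                        sim_options))
  r2 <- vapply(intersect(OBS_CHANNELS, unique(obs$channel)), function(ch) {
    rows <- obs[obs$channel == ch, ]
    if (nrow(rows) < 2 || stats::var(rows$value_g_per_l) == 0) return(NA_real_)
    r_squared(rows$value_g_per_l, .predict_at(best_sim, rows$time_h, ch))
  }, numeric(1))

  structure(
    list(fitted = fitted_free, params = fitted_setup$params,
         sse = opt$value, sse_start = sse_start, r_squared = r2,
         convergence = opt$convergence, n_eval = n_eval,
         n_penalized = n_penalty, iterations = opt$counts[["function"]],
         setup = fitted_setup),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n  fitted parameters:\n")
  for (nm in names(x$fitted)) cat(sprintf("    %-8s = %.6g\n", nm, x$fitted[[nm]]))
  cat(sprintf("  SSE: %.6g (from %.6g at start)\n", x$sse, x$sse_start))
  for (nm in names(x$r_squared)) {
    cat(sprintf("  R^2 (%s): %.4f\n", nm, x$r_squared[[nm]]))
  }
  cat(sprintf("  %d objective evaluations (%d penalized), convergence = %d\n",
              x$n_eval, x$n_penalized, x$convergence))
  invisible(x)
}

#' Write a calibration report as JSON
#'
#' @param result a [calibrate()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(result, path) {
  report <- list(
    fitted = as.list(result$fitted),
    sse = result$sse,
    sse_start = result$sse_start,
    r_squared = as.list(result$r_squared),
    convergence = result$convergence,
    n_eval = result$n_eval,
    n_penalized = result$n_penalized
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
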