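# Kinetic parameter set for the yeast growth model.

# state layout used throughout: seven mass pools (g) plus reactor volume (l)
STATE_NAMES <- c("G", "P", "E", "C_M", "R", "I", "D", "V")

# parameters constrained to be positive (log-transformed during calibration)
PARAM_POSITIVE <- c(
  "v_G", "k_G", "v_RP", "k_RP", "v_F", "k_F", "v_RE", "k_RE",
  "v_A", "k_A", "r_max", "tau", "c", "a", "b",
  "P_max", "E_max", "I_max"
)

# efficiencies constrained to (0, 1] (logit-transformed during calibration)
PARAM_UNIT <- c("eta_G", "eta_RP", "eta_FE", "eta_FP", "eta_RE", "eta_A")

# rates/sensitivities allowed to be zero (switching a process off is meaningful)
PARAM_NONNEG <- c("delta", "rho", "sigma_I", "sigma_E")

PARAM_LAG <- c("l1", "l2", "l3")

PARAM_NAMES <- c(PARAM_POSITIVE, PARAM_UNIT, PARAM_NONNEG, PARAM_LAG)

#' Kinetic and regulatory parameters of the yeast growth model
#'
#' Builds a validated parameter set for the process-based model of aerobic
#' *S. cerevisiae* growth on glucose. Defaults are the literature-derived
#' calibration starting values; strain-specific calibrated sets ship with the
#' packaged scenarios (see [load_scenario()]).
#'
#' @param v_G,k_G,eta_G maximum glucose uptake rate (h^-1), uptake
#'   half-saturation constant (g l^-1) and uptake efficiency P/G (-).
#' @param v_RP,k_RP,eta_RP maximum rate (h^-1), half-saturation (g l^-1) and
#'   efficiency C_M/P (-) of respiration of glycolytic intermediates.
#' @param v_F,k_F maximum fermentation rate (h^-1) and half-saturation
#'   (g l^-1).
#' @param eta_FE,eta_FP fermentation efficiencies E/P and C_M/P (-);
#'   their sum may not exceed 1.
#' @param v_RE,k_RE,eta_RE maximum rate (h^-1), half-saturation (g l^-1) and
#'   efficiency C_M/E (-) of ethanol respiration.
#' @param v_A,k_A,eta_A,r_max reserve accumulation rate (h^-1),
#'   half-saturation (g l^-1), efficiency R/P (-) and maximum reserve to
#'   active-mass ratio (-).
#' @param delta death rate (h^-1) applied to P, C_M and R while the death
#'   switch is on.
#' @param tau death threshold on the intracellular glycolytic-product
#'   concentration (g l^-1); must not exceed `P_max`.
#' @param rho secretion rate of the self-produced inhibitor, as a proportion
#'   of the growth fluxes (-).
#' @param sigma_I,sigma_E sensitivities of the inhibitor and ethanol negative
#'   feedbacks (-).
#' @param c cell volume to dry-weight ratio (l g^-1), converting intracellular
#'   masses to concentrations.
#' @param a,b shape parameters of the sigmoid metabolic switch between
#'   respiration (`ge`) and overflow fermentation (`mo`): a dimensionless,
#'   b in l g^-1.
#' @param l1,l2,l3 optional lag-phase shape parameters (l1, l2 dimensionless,
#'   l3 in h^-1); supply all three or none. Runs without them use lag = 1.
#' @param P_max,E_max,I_max maximum concentrations (g l^-1) of glycolytic
#'   products (intracellular), ethanol and inhibitor (medium) used to scale
#'   saturation and feedback terms.
#'
#' @return An object of class `model_parameters`: a named list of numeric
#'   scalars.
#' @seealso [compute_auxiliaries()], [compute_fluxes()], [load_scenario()]
#' @export
#' @examples
#' p <- model_parameters()
#' p$v_G
model_parameters <- function(v_G = 3.64, k_G = 0.18, eta_G = 0.92,
                             v_RP = 0.475, k_RP = 0.034, eta_RP = 0.6,
                             v_F = 11.8, k_F = 0.5, eta_FE = 0.47,
                             eta_FP = 0.09, v_RE = 0.19, k_RE = 0.1,
                             eta_RE = 0.68, v_A = 0.2, k_A = 0.05,
                             eta_A = 0.2, r_max = 0.25, delta = 0.025,
                             tau = 0.6, rho = 0.01, sigma_I = 1.0,
                             sigma_E = 1.4, c = 0.01, a = 2e-4, b = 30,
                             l1 = NULL, l2 = NULL, l3 = NULL,
                             P_max = 1, E_max = 100, I_max = 1) {
  p <- list(
    v_G = v_G, k_G = k_G, eta_G = eta_G,
    v_RP = v_RP, k_RP = k_RP, eta_RP = eta_RP,
    v_F = v_F, k_F = k_F, eta_FE = eta_FE, eta_FP = eta_FP,
    v_RE = v_RE, k_RE = k_RE, eta_RE = eta_RE,
    v_A = v_A, k_A = k_A, eta_A = eta_A, r_max = r_max,
    delta = delta, tau = tau, rho = rho,
    sigma_I = sigma_I, sigma_E = sigma_E, c = c, a = a, b = b,
    l1 = l1, l2 = l2, l3 = l3,
    P_max = P_max, E_max = E_max, I_max = I_max
  )
  validate_parameters(p)
}

#' Validate a model parameter set
#'
#' Checks positivity, efficiency bounds, `eta_FE + eta_FP <= 1`,
#' `tau <= P_max` and the all-or-none lag triplet, signalling an error that
#' names every offending field.
#'
#' @param p a named list of parameter values (see [model_parameters()]).
#' @return The validated `model_parameters` object, invisibly usable.
#' @export
validate_parameters <- function(p) {
  problems <- character(0)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in PARAM_POSITIVE) {
    if (!num1(p[[nm]]) || p[[nm]] <= 0) {
      problems <- c(problems, sprintf("%s must be a positive number", nm))
    }
  }
  for (nm in PARAM_UNIT) {
    if (!num1(p[[nm]]) || p[[nm]] <= 0 || p[[nm]] > 1) {
      problems <- c(problems, sprintf("%s must lie in (0, 1]", nm))
    }
  }
  for (nm in PARAM_NONNEG) {
    if (!num1(p[[nm]]) || p[[nm]] < 0) {
      problems <- c(problems, sprintf("%s must be a non-negative number", nm))
    }
  }
  lag_given <- !vapply(p[PARAM_LAG], is.null, logical(1))
  if (any(lag_given) && !all(lag_given)) {
    problems <- c(problems, "lag parameters l1, l2, l3 must be given together")
  }
  if (all(lag_given)) {
    for (nm in PARAM_LAG) {
      if (!num1(p[[nm]]) || p[[nm]] <= 0) {
        problems <- c(problems, sprintf("%s must be a positive number", nm))
      }
    }
  }
  if (num1(p$eta_FE) && num1(p$eta_FP) && p$eta_FE + p$eta_FP > 1) {
    problems <- c(problems, "eta_FE + eta_FP must not exceed 1")
  }
  if (num1(p$tau) && num1(p$P_max) && p$tau > p$P_max) {
    problems <- c(problems, "tau must not exceed P_max")
  }
  if (length(problems)) {
    stop("invalid model parameters:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(p, class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters>\n")
  has_lag <- !is.null(x$l1)
  flat <- unlist(x[!vapply(x, is.null, logical(1))])
  print(flat)
  if (!has_lag) cat("(no lag phase: lag = 1)\n")
  invisible(x)
}

#' Test whether a state vector is valid
#'
#' A state holds the seven mass pools G, P, E, C_M, R, I, D (g) and the
#' medium volume V (l). All masses must be non-negative and V positive.
#'
#' @param state named numeric vector with elements
#'   `G, P, E, C_M, R, I, D, V`.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_state <- function(state) {
  if (!is.numeric(state) || !all(STATE_NAMES %in% names(state))) {
    stop("state must be a named numeric vector with elements ",
         paste(STATE_NAMES, collapse = ", "), call. = FALSE)
  }
  state <- state[STATE_NAMES]
  if (any(!is.finite(state))) stop("state contains non-finite values", call. = FALSE)
  if (any(state[setdiff(STATE_NAMES, "V")] < 0)) {
    bad <- setdiff(STATE_NAMES, "V")[state[setdiff(STATE_NAMES, "V")] < 0]
    stop("negative state component(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (state[["V"]] <= 0) stop("volume V must be positive", call. = FALSE)
  invisible(TRUE)
}

#' Construct a state vector
#'
#' @param G,P,E,C_M,R,I,D masses in grams of glucose, glycolytic
#'   intermediates, ethanol, cell material, reserves, inhibitor and dead
#'   cells.
#' @param V medium volume in litres.
#' @return Named numeric vector in canonical order.
#' @export
#' @examples
#' state_vector(G = 9, E = 0.1, P = 5e-5, C_M = 0.17)
state_vector <- function(G = 0, P = 0, E = 0, C_M = 0, R = 0, I = 0, D = 0,
                         V = 1) {
  s <- c(G = G, P = P, E = E, C_M = C_M, R = R, I = I, D = D, V = V)
  validate_state(s)
  s
}
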