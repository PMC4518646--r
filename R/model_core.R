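# Pure computational kernel: auxiliary quantities, process fluxes and the
# right-hand side of the seven mass-balance equations.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Auxiliary quantities of the yeast growth model
#'
#' Computes, for one state, the extracellular concentrations, the active
#' metabolite mass `B = P + C_M`, the intracellular glycolytic-product
#' concentration `[P] = P / ((B + R) c)` (cell-volume basis), the ethanol and
#' inhibitor feedback intensities, the sigmoid glucose-effect/overflow pair
#' `ge`/`mo`, the reserve ceiling, the lag factor and the death switch.
#'
#' The metabolic switch is `ge = 1 / (1 + a exp(b [P]))`, `mo = 1 - ge`:
#' respiration dominates at low intracellular sugar load, overflow
#' fermentation takes over as `[P]` rises. The death switch is a Heaviside
#' step at `[P] = tau` by default; a steep-logistic smoothed variant is
#' available for integrators without event support.
#'
#' When no cells are present (`B + R = 0`) the intracellular concentration
#' `[P]` is defined as 0.
#'
#' @param state named state vector, see [state_vector()].
#' @param params a [model_parameters()] object.
#' @param t simulation time in hours (enters only through the lag factor).
#' @param lag_enabled apply the lag-phase multiplier? Requires `l1, l2, l3`
#'   in `params`; otherwise lag = 1.
#' @param death_switch `"sharp"` (exact threshold, default) or `"smooth"`
#'   (logistic in `[P]` with steepness `smooth_steepness`).
#' @param smooth_steepness steepness (l g^-1) of the smoothed death switch.
#' @param validate check state invariants before computing (disable only in
#'   inner integration loops where the caller has already sanitised the
#'   state).
#' @return A list of class `model_auxiliaries` with elements `conc_G`,
#'   `conc_E`, `conc_I`, `conc_P` (g l^-1), `B` (g), `R_max` (g), `n_E`,
#'   `n_I`, `lag`, `ge`, `mo`, `d` (dimensionless).
#' @export
#' @examples
#' p <- model_parameters()
#' s <- state_vector(G = 9, P = 0.01, C_M = 0.17, V = 1)
#' aux <- compute_auxiliaries(s, p)
#' aux$ge + aux$mo  # identically 1
compute_auxiliaries <- function(state, params, t = 0, lag_enabled = FALSE,
                                death_switch = c("sharp", "smooth"),
                                smooth_steepness = 500, validate = TRUE) {
  death_switch <- match.arg(death_switch)
  if (validate) validate_state(state)
  V <- state[["V"]]
  B <- state[["P"]] + state[["C_M"]]
  BR <- B + state[["R"]]
  conc_G <- state[["G"]] / V
  conc_E <- state[["E"]] / V
  conc_I <- state[["I"]] / V
  conc_P <- if (BR > 0) state[["P"]] / (BR * params$c) else 0
  n_E <- params$sigma_E * conc_E / params$E_max
  n_I <- params$sigma_I * conc_I / params$I_max
  ge <- 1 / (1 + params$a * exp(params$b * conc_P))
  lag <- 1
  if (lag_enabled) {
    if (is.null(params$l1)) {
      stop("lag_enabled = TRUE but lag parameters l1, l2, l3 are not set",
           call. = FALSE)
    }
    lag <- 1 - params$l1 / (1 + params$l2 * exp(params$l3 * t))
  }
  d <- if (death_switch == "sharp") {
    as.numeric(conc_P > params$tau)
  } else {
    1 / (1 + exp(-smooth_steepness * (conc_P - params$tau)))
  }
  structure(
    list(conc_G = conc_G, conc_E = conc_E, conc_I = conc_I, conc_P = conc_P,
         B = B, R_max = BR * params$r_max, n_E = n_E, n_I = n_I,
         lag = lag, ge = ge, mo = 1 - ge, d = d),
    class = "model_auxiliaries"
  )
}

#' Process fluxes of the yeast growth model
#'
#' Evaluates the nine metabolic process rates (g h^-1): glucose uptake,
#' respiration of glycolytic products, fermentation, ethanol respiration,
#' reserve accumulation, inhibitor secretion and the three death losses,
#' plus the glucose mass inflow from feeding. All substrate dependencies
#' follow Michaelis-Menten kinetics with first-order dependence on the
#' active mass `B`, modulated by the regulatory factors of
#' [compute_auxiliaries()].
#'
#' Every limitation factor of the form `(1 - x)` — product saturation
#' `1 - [P]/P_max`, feedbacks `1 - n_E`, `1 - n_I`, reserve saturation
#' `1 - R/R_max` — is clamped to `[0, 1]`: the feedback intensities may
#' exceed 1 (e.g. `sigma_E = 1.4`), and a negative factor would reverse a
#' one-directional process.
#'
#' @inheritParams compute_auxiliaries
#' @param aux auxiliaries for the same state, from [compute_auxiliaries()].
#' @param feed_rate_glucose glucose mass inflow (g h^-1) from the feeding
#'   profile; reported as the `feeding` flux.
#' @return A list of class `model_fluxes` with elements `feeding`, `uptake`,
#'   `respiration_P`, `fermentation`, `respiration_E`, `accumulation`,
#'   `secretion`, `death_P`, `death_R`, `death_CM`, all non-negative,
#'   in g h^-1.
#' @export
compute_fluxes <- function(state, aux, params, feed_rate_glucose = 0,
                           validate = TRUE) {
  if (validate) validate_state(state)
  B <- aux$B
  f_E <- clamp01(1 - aux$n_E)
  f_I <- clamp01(1 - aux$n_I)
  f_P <- clamp01(1 - aux$conc_P / params$P_max)
  f_R <- if (aux$R_max > 0) clamp01(1 - state[["R"]] / aux$R_max) else 0
  mm <- function(conc, k) conc / (k + conc)

  uptake <- params$v_G * mm(aux$conc_G, params$k_G) * B * f_P * f_E * aux$lag
  respiration_P <- params$v_RP * mm(aux$conc_P, params$k_RP) * B * f_E * f_I * aux$ge
  fermentation <- params$v_F * mm(aux$conc_P, params$k_F) * B * f_E * f_I * aux$mo
  respiration_E <- params$v_RE * mm(aux$conc_E, params$k_RE) * B * f_E * f_I * aux$ge
  accumulation <- params$v_A * mm(aux$conc_P, params$k_A) * B * f_R * aux$mo
  secretion <- params$rho * (params$eta_RP * respiration_P +
                             params$eta_RE * respiration_E +
                             params$eta_FP * fermentation)
  structure(
    list(feeding = feed_rate_glucose,
         uptake = uptake,
         respiration_P = respiration_P,
         fermentation = fermentation,
         respiration_E = respiration_E,
         accumulation = accumulation,
         secretion = secretion,
         death_P = aux$d * params$delta * state[["P"]],
         death_R = aux$d * params$delta * state[["R"]],
         death_CM = aux$d * params$delta * state[["C_M"]]),
    class = "model_fluxes"
  )
}

#' Time derivatives of the model state
#'
#' Assembles the seven mass balances plus the volume balance from the
#' process fluxes:
#' \deqn{dG/dt = Feeding - Uptake}
#' \deqn{dP/dt = \eta_G Uptake - Resp_P - Ferm - Accum - Death_P}
#' \deqn{dE/dt = \eta_{FE} Ferm - Resp_E}
#' \deqn{dC_M/dt = \eta_{RP} Resp_P + \eta_{RE} Resp_E + \eta_{FP} Ferm -
#'   Secretion - Death_{CM}}
#' \deqn{dR/dt = \eta_A Accum - Death_R}
#' \deqn{dI/dt = Secretion; \quad dD/dt = Death_P + Death_{CM} + Death_R}
#' and `dV/dt` equal to the volumetric feed rate (zero in `tabulated`
#' volume mode, where V follows the printed closed form instead).
#'
#' @param t time (h).
#' @param state named state vector.
#' @param params a [model_parameters()] object.
#' @param setup an [experiment_setup()] carrying the feeding profile, the
#'   lag flag and the volume mode.
#' @param death_switch,smooth_steepness passed to [compute_auxiliaries()].
#' @return Named numeric vector of derivatives in state order (g h^-1;
#'   l h^-1 for V).
#' @export
derivatives <- function(t, state, params, setup,
                        death_switch = "sharp", smooth_steepness = 500) {
  if (identical(setup$volume_mode, "tabulated")) {
    state[["V"]] <- literal_volume(t, setup$feeding, setup$V0)
  }
  aux <- compute_auxiliaries(state, params, t = t,
                             lag_enabled = isTRUE(setup$lag_enabled),
                             death_switch = death_switch,
                             smooth_steepness = smooth_steepness,
                             validate = FALSE)
  feed_vol <- volumetric_feed_rate(t, setup$feeding)
  feed_glu <- glucose_feed_rate(t, setup$feeding)
  fl <- compute_fluxes(state, aux, params, feed_rate_glucose = feed_glu,
                       validate = FALSE)
  dV <- if (identical(setup$volume_mode, "tabulated")) 0 else feed_vol
  c(G = fl$feeding - fl$uptake,
    P = params$eta_G * fl$uptake - fl$respiration_P - fl$fermentation -
        fl$accumulation - fl$death_P,
    E = params$eta_FE * fl$fermentation - fl$respiration_E,
    C_M = params$eta_RP * fl$respiration_P + params$eta_RE * fl$respiration_E +
          params$eta_FP * fl$fermentation - fl$secretion - fl$death_CM,
    R = params$eta_A * fl$accumulation - fl$death_R,
    I = fl$secretion,
    D = fl$death_P + fl$death_CM + fl$death_R,
    V = dV)
}

# RHS wrapper for the integrators: tiny negative excursions produced by the
# solver are treated as zero mass when evaluating fluxes, which keeps all
# fluxes non-negative and the trajectory physical. This is an allocation-lean
# inline of compute_auxiliaries + compute_fluxes + derivatives (the solver
# calls it thousands of times per run); a test pins it to the reference path.
.rhs_desolve <- function(t, y, parms) {
  p <- parms$params
  setup <- parms$setup
  G <- max(y[[1]], 0); P <- max(y[[2]], 0); E <- max(y[[3]], 0)
  C_M <- max(y[[4]], 0); R <- max(y[[5]], 0); I <- max(y[[6]], 0)
  V <- max(y[[8]], .Machine$double.eps)
  feed_vol <- volumetric_feed_rate(t, setup$feeding)
  if (identical(setup$volume_mode, "tabulated")) {
    V <- literal_volume(t, setup$feeding, setup$V0)
  }
  B <- P + C_M
  BR <- B + R
  conc_P <- if (BR > 0) P / (BR * p$c) else 0
  n_E <- p$sigma_E * (E / V) / p$E_max
  n_I <- p$sigma_I * (I / V) / p$I_max
  ge <- 1 / (1 + p$a * exp(p$b * conc_P))
  mo <- 1 - ge
  lag <- 1
  if (isTRUE(setup$lag_enabled)) {
    lag <- 1 - p$l1 / (1 + p$l2 * exp(p$l3 * t))
  }
  d <- if (identical(parms$death_switch, "sharp")) {
    as.numeric(conc_P > p$tau)
  } else {
    1 / (1 + exp(-parms$smooth_steepness * (conc_P - p$tau)))
  }
  f_E <- min(max(1 - n_E, 0), 1)
  f_I <- min(max(1 - n_I, 0), 1)
  f_P <- min(max(1 - conc_P / p$P_max, 0), 1)
  R_max <- BR * p$r_max
  f_R <- if (R_max > 0) min(max(1 - R / R_max, 0), 1) else 0
  conc_G <- G / V
  conc_E <- E / V
  uptake <- p$v_G * conc_G / (p$k_G + conc_G) * B * f_P * f_E * lag
  resp_P <- p$v_RP * conc_P / (p$k_RP + conc_P) * B * f_E * f_I * ge
  ferm <- p$v_F * conc_P / (p$k_F + conc_P) * B * f_E * f_I * mo
  resp_E <- p$v_RE * conc_E / (p$k_RE + conc_E) * B * f_E * f_I * ge
  accum <- p$v_A * conc_P / (p$k_A + conc_P) * B * f_R * mo
  secretion <- p$rho * (p$eta_RP * resp_P + p$eta_RE * resp_E + p$eta_FP * ferm)
  death_P <- d * p$delta * P
  death_R <- d * p$delta * R
  death_CM <- d * p$delta * C_M
  feed_glu <- if (setup$feeding$mode == "none") 0 else setup$feeding$c_F * feed_vol
  dV <- if (identical(setup$volume_mode, "tabulated")) 0 else feed_vol
  list(c(feed_glu - uptake,
         p$eta_G * uptake - resp_P - ferm - accum - death_P,
         p$eta_FE * ferm - resp_E,
         p$eta_RP * resp_P + p$eta_RE * resp_E + p$eta_FP * ferm -
           secretion - death_CM,
         p$eta_A * accum - death_R,
         secretion,
         death_P + death_CM + death_R,
         dV))
}

# root function: intracellular [P] crossing the death threshold tau
.root_death_switch <- function(t, y, parms) {
  y_pos <- pmax(y, 0)
  if (identical(parms$setup$volume_mode, "tabulated")) {
    y_pos[["V"]] <- literal_volume(t, parms$setup$feeding, parms$setup$V0)
  }
  BR <- y_pos[["P"]] + y_pos[["C_M"]] + y_pos[["R"]]
  conc_P <- if (BR > 0) y_pos[["P"]] / (BR * parms$params$c) else 0
  conc_P - parms$params$tau
}
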