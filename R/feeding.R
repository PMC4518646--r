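# Feed-rate profiles: batch (none), exponential, exponential-then-constant
# and logistically-decreasing specific feed rate, plus the induced volume.

# log(1 + exp(x)) without overflow
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Define a reactor feeding profile
#'
#' Four modes are supported: `"none"` (batch), `"exponential"`
#' (`F(t) = F0 exp(mu (t - t_F))`, the classical constant specific feed
#' rate), `"two_phase"` (exponential for `t_switch` hours, then constant at
#' the rate reached at the switch, as in short fed-batch protocols), and
#' `"logistic_mu"` where the specific feed rate decreases logistically,
#' `mu*(t) = m1 - m1 / (1 + exp(-m2 (t - t_F - m3)))`, so that feeding slows
#' as the culture approaches its density limit.
#'
#' The initial volumetric feed rate is `F0 = M_F mu / (c_F y_R)` — the rate
#' that supplies a culture of mass `M_F` growing at `mu` with glucose at
#' yield `y_R` from a feed of concentration `c_F`. For `logistic_mu`, `mu`
#' in that expression is `mu*(t_F)`.
#'
#' @param mode one of `"none"`, `"exponential"`, `"two_phase"`,
#'   `"logistic_mu"`.
#' @param t_F feeding start time (h).
#' @param mu specific feed rate, SFR (h^-1), for the exponential modes.
#' @param t_switch duration (h) of the exponential phase in `two_phase`
#'   mode; default 3 h.
#' @param m1,m2,m3 logistic mu* parameters: plateau rate (h^-1), steepness
#'   (h^-1) and midpoint offset (h) after `t_F`.
#' @param c_F feed glucose concentration (g l^-1).
#' @param M_F cell mass at feeding start (g).
#' @param y_R maximum biomass yield on glucose (-).
#' @return An object of class `feeding_profile`.
#' @export
#' @examples
#' feeding_profile("exponential", t_F = 17, mu = 0.16, c_F = 500,
#'                 M_F = 3.66, y_R = 0.5)
feeding_profile <- function(mode = c("none", "exponential", "two_phase",
                                     "logistic_mu"),
                            t_F = NULL, mu = NULL, t_switch = 3,
                            m1 = NULL, m2 = NULL, m3 = NULL,
                            c_F = NULL, M_F = NULL, y_R = NULL) {
  mode <- match.arg(mode)
  prof <- structure(
    list(mode = mode, t_F = t_F, mu = mu, t_switch = t_switch,
         m1 = m1, m2 = m2, m3 = m3, c_F = c_F, M_F = M_F, y_R = y_R),
    class = "feeding_profile"
  )
  validate_feeding_profile(prof)
}

#' @rdname feeding_profile
#' @param profile a `feeding_profile` object to validate.
#' @export
validate_feeding_profile <- function(profile) {
  problems <- character(0)
  pos <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
  if (profile$mode != "none") {
    if (!is.numeric(profile$t_F) || profile$t_F < 0) {
      problems <- c(problems, "t_F must be a non-negative time")
    }
    for (nm in c("c_F", "M_F", "y_R")) {
      if (!pos(profile[[nm]])) {
        problems <- c(problems, sprintf("%s must be positive", nm))
      }
    }
  }
  if (profile$mode %in% c("exponential", "two_phase") && !pos(profile$mu)) {
    problems <- c(problems, "mu must be positive for exponential feeding")
  }
  if (profile$mode == "two_phase" && !pos(profile$t_switch)) {
    problems <- c(problems, "t_switch must be positive")
  }
  if (profile$mode == "logistic_mu") {
    for (nm in c("m1", "m2", "m3")) {
      if (!pos(profile[[nm]])) {
        problems <- c(problems, sprintf("%s must be positive", nm))
      }
    }
  }
  if (length(problems)) {
    stop("invalid feeding profile:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  profile
}

#' @export
print.feeding_profile <- function(x, ...) {
  cat("<feeding_profile> mode:", x$mode, "\n")
  if (x$mode != "none") {
    cat(sprintf("  t_F = %g h, c_F = %g g/l, M_F = %g g, y_R = %g\n",
                x$t_F, x$c_F, x$M_F, x$y_R))
    if (x$mode %in% c("exponential", "two_phase")) {
      cat(sprintf("  mu = %g 1/h", x$mu))
      if (x$mode == "two_phase") cat(sprintf(", t_switch = %g h", x$t_switch))
      cat("\n")
    } else {
      cat(sprintf("  mu*: m1 = %g 1/h, m2 = %g 1/h, m3 = %g h\n",
                  x$m1, x$m2, x$m3))
    }
    cat(sprintf("  F0 = %g l/h\n", initial_feed_rate(x)))
  }
  invisible(x)
}

#' Initial volumetric feed rate
#'
#' `F0 = M_F mu / (c_F y_R)` in l h^-1, with `mu` replaced by `mu*(t_F)` for
#' the `logistic_mu` mode. Defined for `t >= t_F`; the profile delivers 0
#' before feeding starts.
#'
#' @param profile a [feeding_profile()] with mode other than `"none"`.
#' @return Initial feed rate (l h^-1).
#' @export
#' @examples
#' pr <- feeding_profile("exponential", t_F = 17, mu = 0.16, c_F = 500,
#'                       M_F = 3.66, y_R = 0.5)
#' initial_feed_rate(pr)  # 0.0023424
initial_feed_rate <- function(profile) {
  if (profile$mode == "none") {
    stop("initial feed rate is undefined for a batch (no-feeding) profile",
         call. = FALSE)
  }
  mu0 <- if (profile$mode == "logistic_mu") {
    mu_star(profile$t_F, profile)
  } else {
    profile$mu
  }
  profile$M_F * mu0 / (profile$c_F * profile$y_R)
}

#' Logistically decreasing specific feed rate
#'
#' `mu*(t) = m1 - m1 / (1 + exp(-m2 (t - t_F - m3)))`: close to `m1` at
#' feeding start, halving at `t_F + m3`, and decaying to 0, so that the
#' imposed growth rate eases off as the culture matures.
#'
#' @param t time (h), scalar or vector.
#' @param profile a [feeding_profile()] with mode `"logistic_mu"`.
#' @return mu* (h^-1), same length as `t`.
#' @export
mu_star <- function(t, profile) {
  if (profile$mode != "logistic_mu") {
    stop("mu_star is defined only for logistic_mu profiles", call. = FALSE)
  }
  profile$m1 - profile$m1 / (1 + exp(-profile$m2 * (t - profile$t_F - profile$m3)))
}

# closed-form integral of mu* from t_F to t (t >= t_F), per element
.mu_star_integral <- function(t, profile) {
  u <- t - profile$t_F
  (profile$m1 / profile$m2) *
    (softplus(profile$m2 * profile$m3) - softplus(-profile$m2 * (u - profile$m3)))
}

#' Volumetric feed rate at time t
#'
#' Zero before `t_F` and for batch profiles. Exponential:
#' `F0 exp(mu (t - t_F))`; two-phase: exponential until
#' `t_F + t_switch`, then constant at the switch-instant rate (continuous);
#' logistic: `F0 exp(integral of mu* from t_F to t)`, with the integral in
#' closed form.
#'
#' @param t time (h), scalar or vector.
#' @param profile a [feeding_profile()].
#' @return Feed rate (l h^-1), same length as `t`.
#' @export
volumetric_feed_rate <- function(t, profile) {
  if (profile$mode == "none") return(rep(0, length(t)))
  F0 <- initial_feed_rate(profile)
  u <- t - profile$t_F
  rate <- switch(profile$mode,
    exponential = F0 * exp(profile$mu * u),
    two_phase = F0 * exp(profile$mu * pmin(u, profile$t_switch)),
    logistic_mu = F0 * exp(.mu_star_integral(t, profile))
  )
  ifelse(t < profile$t_F, 0, rate)
}

#' Glucose mass inflow at time t
#'
#' `c_F` times the volumetric feed rate, in g h^-1.
#'
#' @inheritParams volumetric_feed_rate
#' @export
glucose_feed_rate <- function(t, profile) {
  if (profile$mode == "none") return(rep(0, length(t)))
  profile$c_F * volumetric_feed_rate(t, profile)
}

#' Cumulative volume fed over \[t_F, t\]
#'
#' Closed forms for the exponential and two-phase profiles
#' (`(F0/mu)(exp(mu (t - t_F)) - 1)` during the exponential phase); adaptive
#' quadrature of the feed rate for `logistic_mu`.
#'
#' @inheritParams volumetric_feed_rate
#' @return Volume (l) delivered up to each time in `t`.
#' @export
cumulative_feed_volume <- function(t, profile) {
  if (profile$mode == "none") return(rep(0, length(t)))
  F0 <- initial_feed_rate(profile)
  u <- pmax(t - profile$t_F, 0)
  if (profile$mode == "exponential") {
    return((F0 / profile$mu) * (exp(profile$mu * u) - 1))
  }
  if (profile$mode == "two_phase") {
    u1 <- pmin(u, profile$t_switch)
    v_exp <- (F0 / profile$mu) * (exp(profile$mu * u1) - 1)
    v_const <- F0 * exp(profile$mu * profile$t_switch) * pmax(u - profile$t_switch, 0)
    return(v_exp + v_const)
  }
  vapply(t, function(ti) {
    if (ti <= profile$t_F) return(0)
    stats::integrate(function(s) volumetric_feed_rate(s, profile),
                     lower = profile$t_F, upper = ti,
                     rel.tol = 1e-10)$value
  }, numeric(1))
}

#' Closed-form medium volume as printed in the source tables
#'
#' The tabulated volume law `V(t) = M_F / (c_F y_R) * exp(mu (t - t_F))` for
#' `t >= t_F` (and `V0` before feeding). It is discontinuous at `t_F` and
#' generally inconsistent with `V0` plus the integrated feed; the default
#' simulation mode therefore integrates `dV/dt` instead, and this form is
#' kept behind the `tabulated` volume-mode flag for comparison. Defined
#' only for the exponential profile.
#'
#' @inheritParams volumetric_feed_rate
#' @param V0 initial volume (l) used before feeding starts.
#' @return Volume (l) at each time in `t`.
#' @export
literal_volume <- function(t, profile, V0) {
  if (profile$mode != "exponential") {
    stop("the literal volume law is defined only for exponential feeding",
         call. = FALSE)
  }
  ifelse(t < profile$t_F,
         V0,
         profile$M_F / (profile$c_F * profile$y_R) *
           exp(profile$mu * (t - profile$t_F)))
}
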