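# Computational kernel: auxiliaries, fluxes, mass balances.

test_that("metabolic switch ge/mo follows the sigmoid in [P] exactly", {
  p <- fix_params()
  # no glycolytic load: respiration fully active, overflow ~ a
  s0 <- fix_state(P = 0, R = 0, C_M = 1)
  aux0 <- compute_auxiliaries(s0, p)
  expect_equal(aux0$conc_P, 0)
  expect_equal(aux0$ge, 1 / (1 + 2e-4), tolerance = 1e-12)
  expect_equal(aux0$mo, 2e-4 / (1 + 2e-4), tolerance = 1e-6)
  # switch midpoint: a exp(b [P]) = 1  =>  [P] = log(1/a)/b
  p_mid <- log(1 / p$a) / p$b
  expect_equal(p_mid, 0.28391, tolerance = 1e-4)
  aux_mid <- compute_auxiliaries(fix_state_concP(p_mid, p), p)
  expect_equal(aux_mid$ge, 0.5, tolerance = 1e-6)
  expect_equal(aux_mid$mo, 0.5, tolerance = 1e-6)
})

test_that("ge + mo = 1 to machine precision and ge is strictly decreasing in [P]", {
  p <- fix_params()
  conc_P <- seq(0, 1, by = 0.01)
  ge <- 1 / (1 + p$a * exp(p$b * conc_P))
  for (cp in conc_P) {
    aux <- compute_auxiliaries(fix_state_concP(cp, p), p)
    expect_equal(aux$ge + aux$mo, 1, tolerance = 1e-15)
  }
  expect_true(all(diff(ge) < 0))
})

test_that("feedback intensities vanish without ethanol/inhibitor and death switch is a sharp threshold", {
  p <- fix_params()
  aux <- compute_auxiliaries(fix_state(E = 0, I = 0), p)
  expect_equal(aux$n_E, 0)
  expect_equal(aux$n_I, 0)
  # threshold boundary: d flips strictly above tau = 0.6
  expect_equal(compute_auxiliaries(fix_state_concP(0.599, p), p)$d, 0)
  expect_equal(compute_auxiliaries(fix_state_concP(0.601, p), p)$d, 1)
  # at [P] exactly equal to tau the cell survives (d = 0)
  s <- fix_state_concP(0.55, p)
  cp <- compute_auxiliaries(s, p)$conc_P
  p_at <- fix_params(tau = cp)
  expect_equal(compute_auxiliaries(s, p_at)$d, 0)
  p_below <- fix_params(tau = cp * (1 - 1e-12))
  expect_equal(compute_auxiliaries(s, p_below)$d, 1)
})

test_that("auxiliaries handle the empty-culture state and reject invalid volume", {
  p <- fix_params()
  s <- fix_state(P = 0, C_M = 0, R = 0)
  expect_equal(compute_auxiliaries(s, p)$conc_P, 0)
  s_bad <- fix_state()
  s_bad[["V"]] <- 0
  expect_error(compute_auxiliaries(s_bad, p), "volume")
  s_neg <- fix_state()
  s_neg[["G"]] <- -1
  expect_error(compute_fluxes(s_neg, compute_auxiliaries(fix_state(), p), p),
               "negative")
})

test_that("fluxes scale with active mass, clamp saturated feedbacks and obey half-saturation", {
  p <- fix_params()
  # no cells: every metabolic flux is zero
  s0 <- fix_state(P = 0, C_M = 0, R = 0)
  fl0 <- compute_fluxes(s0, compute_auxiliaries(s0, p), p)
  expect_equal(fl0$uptake, 0)
  expect_equal(fl0$respiration_P, 0)
  expect_equal(fl0$fermentation, 0)
  expect_equal(fl0$respiration_E, 0)
  expect_equal(fl0$accumulation, 0)
  # ethanol feedback beyond saturation: n_E = 1.4 > 1 clamps to factor 0
  s_sat <- fix_state(E = 100, V = 1)
  aux_sat <- compute_auxiliaries(s_sat, p)
  expect_gt(aux_sat$n_E, 1)
  fl_sat <- compute_fluxes(s_sat, aux_sat, p)
  expect_equal(fl_sat$uptake, 0)
  expect_equal(fl_sat$respiration_P, 0)
  expect_equal(fl_sat$respiration_E, 0)
  expect_equal(fl_sat$fermentation, 0)
  # no secretion without the secretion rate
  p0 <- fix_params(rho = 0)
  s <- fix_state()
  fl <- compute_fluxes(s, compute_auxiliaries(s, p0), p0)
  expect_equal(fl$secretion, 0)
  expect_gt(fl$respiration_P, 0)
  # Michaelis-Menten half-saturation of glycolytic-product respiration
  p1 <- fix_params(sigma_E = 0, sigma_I = 0)
  s_half <- fix_state_concP(p1$k_RP, p1)
  aux_half <- compute_auxiliaries(s_half, p1)
  fl_half <- compute_fluxes(s_half, aux_half, p1)
  expect_equal(fl_half$respiration_P,
               p1$v_RP * 0.5 * aux_half$B * aux_half$ge, tolerance = 1e-12)
})

test_that("the solver's inlined right-hand side matches the reference kernel", {
  fb <- fix_fedbatch_setup()
  parms <- list(params = fb$params, setup = fb, death_switch = "sharp",
                smooth_steepness = 500)
  set.seed(5)
  for (i in 1:20) {
    s <- state_vector(G = runif(1, 0, 5), P = runif(1, 0, 0.05),
                      E = runif(1, 0, 3), C_M = runif(1, 0, 3),
                      R = runif(1, 0, 0.5), I = runif(1, 0, 1),
                      D = runif(1, 0, 1), V = runif(1, 0.5, 2))
    t <- runif(1, 0, 10)
    fast <- fedbatchsim:::.rhs_desolve(t, s, parms)[[1]]
    ref <- derivatives(t, s, fb$params, fb)
    expect_equal(fast, unname(ref), tolerance = 1e-14)
  }
})

test_that("mass balances: absorbing zero state, conservation under unit efficiencies, one-way I and D", {
  setup <- fix_batch_setup()
  p <- setup$params
  # empty reactor is an equilibrium
  s0 <- state_vector(V = 1)
  expect_equal(unname(derivatives(0, s0, p, setup)), rep(0, 8))
  # with eta_G = eta_RP = eta_RE = eta_A = 1, eta_FE + eta_FP = 1, rho = 0,
  # d = 0 the five carbon pools only exchange mass: their sum grows exactly
  # by the feeding flux
  p_cons <- fix_params(eta_G = 1, eta_RP = 1, eta_RE = 1, eta_A = 1,
                       eta_FE = 0.6, eta_FP = 0.4, rho = 0, delta = 0)
  fb <- fix_fedbatch_setup(params = p_cons)
  set.seed(11)
  for (i in 1:25) {
    s <- state_vector(G = runif(1, 0, 5), P = runif(1, 0, 0.02),
                      E = runif(1, 0, 2), C_M = runif(1, 0, 3),
                      R = runif(1, 0, 0.5), I = runif(1, 0, 0.5),
                      D = runif(1, 0, 1), V = runif(1, 0.5, 2))
    t <- runif(1, 0, 10)
    d <- derivatives(t, s, p_cons, fb)
    feed <- glucose_feed_rate(t, fb$feeding)
    expect_equal(unname(d[["G"]] + d[["P"]] + d[["E"]] + d[["C_M"]] + d[["R"]]),
                 feed, tolerance = 1e-12)
    # inhibitor and dead pools never shrink, for any valid state
    d_any <- derivatives(t, s, p, fb)
    expect_gte(d_any[["I"]], 0)
    expect_gte(d_any[["D"]], 0)
  }
})
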