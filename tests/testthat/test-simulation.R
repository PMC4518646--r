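# ODE integration, observables, event handling.

test_that("observables follow their defining formulas", {
  s <- state_vector(P = 2, C_M = 4, R = 1, D = 3, V = 2)
  expect_equal(mass_concentration(s), 5)          # (7 + 3) / 2
  expect_equal(nonviable_fraction(s), 0.3)        # 3 / 10
  expect_equal(mass_concentration(state_vector(G = 5, V = 2)), 0)
  expect_equal(nonviable_fraction(state_vector(C_M = 7)), 0)
  expect_error(nonviable_fraction(state_vector(G = 1)), "zero")
  expect_error(mass_concentration(data.frame(P = 1, C_M = 1, R = 0, D = 0,
                                             V = 0)), "positive")
})

test_that("a culture-free reactor stays at its initial state", {
  setup <- experiment_setup(
    initial_state = state_vector(G = 5, P = 0, C_M = 0),
    t0 = 0, t_END = 5, params = fix_params()
  )
  tr <- run_simulation(setup)$trajectory
  expect_equal(tr$G_conc, rep(5, nrow(tr)), tolerance = 1e-10)
  expect_equal(tr$M_conc, rep(0, nrow(tr)))
  expect_equal(tr$E_conc, rep(0, nrow(tr)))
})

test_that("total carbon mass minus cumulative fed glucose is conserved under unit efficiencies", {
  p_cons <- fix_params(eta_G = 1, eta_RP = 1, eta_RE = 1, eta_A = 1,
                       eta_FE = 0.6, eta_FP = 0.4, rho = 0, delta = 0)
  setup <- fix_fedbatch_setup(params = p_cons, t_END = 8)
  tr <- run_simulation(setup, atol = 1e-10, rtol = 1e-10)$trajectory
  fed <- setup$feeding$c_F * cumulative_feed_volume(tr$time_h, setup$feeding)
  total <- tr$G_g + tr$P_g + tr$E_g + tr$CM_g + tr$R_g - fed
  expect_equal(total, rep(total[1], length(total)),
               tolerance = 1e-6)
})

test_that("inhibitor and dead pools are non-decreasing and all states stay non-negative", {
  tr <- fix_scenario_sim("cenpk113_7d_fedbatch_016")$trajectory
  expect_true(all(diff(tr$I_g) > -1e-9))
  expect_true(all(diff(tr$D_g) > -1e-9))
  states <- as.matrix(tr[, c("G_g", "P_g", "E_g", "CM_g", "R_g", "I_g", "D_g")])
  expect_true(all(states >= 0))
  expect_true(all(diff(tr$time_h) > 0))
})

test_that("death-switch crossings are located by the event handler", {
  sim <- fix_scenario_sim("cenpk113_7d_fedbatch_016")
  cross <- sim$events[sim$events$event == "death_switch_crossing", ]
  expect_gte(nrow(cross), 1)
  # at the first crossing, [P] sits at the threshold
  tr <- sim$trajectory
  i <- which.min(abs(tr$time_h - cross$time_h[1]))
  expect_equal(tr$conc_P[i], sim$setup$params$tau, tolerance = 0.02)
  # dead mass only appears after the crossing
  expect_equal(max(tr$D_g[tr$time_h < cross$time_h[1]]), 0, tolerance = 1e-8)
  expect_gt(tr$D_g[nrow(tr)], 0)
})

test_that("identical setups reproduce bit-identical trajectories", {
  setup <- fix_batch_setup()
  a <- run_simulation(setup)
  b <- run_simulation(setup)
  expect_identical(a$trajectory, b$trajectory)
})

test_that("tightening solver tolerances leaves observables unchanged below 0.1%", {
  setup <- load_scenario("lbg_h1022_batch")
  tr1 <- run_simulation(setup, atol = 1e-8, rtol = 1e-8)$trajectory
  tr2 <- run_simulation(setup, atol = 1e-9, rtol = 1e-9)$trajectory
  for (col in c("M_conc", "G_conc", "E_conc")) {
    rel <- max(abs(tr1[[col]] - tr2[[col]])) / max(tr2[[col]])
    expect_lt(rel, 1e-3)
  }
})

test_that("a fixed-step 4th-order integrator reproduces the stiff solution within 0.5%", {
  setup <- load_scenario("lbg_h1022_batch")
  ref <- run_simulation(setup, dt_report = 0.5)$trajectory
  rk4 <- run_simulation_rk4(setup, h = 1e-3, dt_report = 0.5)
  expect_equal(rk4$time_h, ref$time_h)
  for (col in c("M_conc", "G_conc", "E_conc")) {
    rel <- max(abs(rk4[[col]] - ref[[col]])) / max(ref[[col]])
    expect_lt(rel, 0.005)
  }
})

test_that("without inhibitor secretion the culture tracks the imposed SFR mid-feeding", {
  base <- load_scenario("cenpk113_7d_fedbatch_016")
  p <- base$params
  p$rho <- 0
  setup <- experiment_setup(base$initial_state, base$t0, base$t_END,
                            base$feeding, p)
  tr <- run_simulation(setup)$trajectory
  # realized specific growth rate of cell material, once the transient from
  # the batch-phase overshoot (C_M at t_F exceeds the feed design mass M_F)
  # has relaxed onto the feed-limited trajectory
  win <- tr$time_h >= 35 & tr$time_h <= 45
  fit <- stats::lm(log(CM_g) ~ time_h, data = tr[win, ])
  mu_real <- unname(coef(fit)[2])
  expect_lt(abs(mu_real - 0.16) / 0.16, 0.05)
})

test_that("the tabulated volume mode reproduces the printed closed-form volume", {
  base <- load_scenario("cenpk113_7d_fedbatch_016")
  setup <- experiment_setup(base$initial_state, base$t0, base$t_END,
                            base$feeding, base$params,
                            volume_mode = "tabulated")
  tr <- run_simulation(setup, dt_report = 1)$trajectory
  fb <- base$feeding
  expected <- ifelse(tr$time_h < fb$t_F, 1,
                     fb$M_F / (fb$c_F * fb$y_R) * exp(fb$mu * (tr$time_h - fb$t_F)))
  expect_equal(tr$V_l, expected, tolerance = 1e-10)
  expect_error(
    experiment_setup(base$initial_state, base$t0, base$t_END,
                     feeding_profile("none"), base$params,
                     volume_mode = "tabulated"),
    "exponential"
  )
})

test_that("trajectories export in the canonical column layout", {
  sim <- run_simulation(fix_batch_setup(t_END = 2))
  df <- as.data.frame(sim)
  expect_named(df, c("time_h", "G_g", "P_g", "E_g", "CM_g", "R_g", "I_g",
                     "D_g", "V_l", "M_conc", "G_conc", "E_conc", "I_conc",
                     "nonviable_frac"))
  path <- tempfile(fileext = ".csv")
  write_trajectory(sim, path)
  back <- utils::read.csv(path)
  expect_equal(back$M_conc, df$M_conc, tolerance = 1e-12)
})
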