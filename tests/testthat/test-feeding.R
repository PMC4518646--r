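# Feed-rate profiles and induced volume dynamics.

test_that("initial feed rate follows F0 = M_F mu / (c_F y_R)", {
  pr1 <- feeding_profile("exponential", t_F = 17, mu = 0.16, c_F = 500,
                         M_F = 3.66, y_R = 0.5)
  expect_equal(initial_feed_rate(pr1), 0.0023424, tolerance = 1e-10)
  pr2 <- feeding_profile("two_phase", t_F = 3.2, mu = 0.3, c_F = 100,
                         M_F = 3.66, y_R = 0.1)
  expect_equal(initial_feed_rate(pr2), 0.1098, tolerance = 1e-10)
  # nothing is delivered before feeding starts
  expect_equal(volumetric_feed_rate(c(0, 5, 16.99), pr1), rep(0, 3))
  expect_error(feeding_profile("exponential", t_F = 1, mu = 0.1, c_F = 0,
                               M_F = 1, y_R = 0.5), "c_F")
  expect_error(initial_feed_rate(feeding_profile("none")), "batch")
})

test_that("logistic mu* has its midpoint at t_F + m3 and decays to zero", {
  pr <- feeding_profile("logistic_mu", t_F = 15, m1 = 0.1863, m2 = 0.1628,
                        m3 = 14.1092, c_F = 500, M_F = 4.14, y_R = 0.5)
  expect_equal(mu_star(15 + 14.1092, pr), 0.1863 / 2, tolerance = 1e-12)
  expect_equal(mu_star(15 + 1e4, pr), 0, tolerance = 1e-12)
  expect_equal(mu_star(15, pr), 0.1693, tolerance = 5e-4)
  expect_equal(initial_feed_rate(pr), 4.14 * mu_star(15, pr) / (500 * 0.5),
               tolerance = 1e-12)
  # mu* is non-increasing in time
  expect_true(all(diff(mu_star(seq(15, 60, 0.5), pr)) < 0))
})

test_that("volumetric feed rates match their defining laws and closed-form integrals", {
  pr <- feeding_profile("exponential", t_F = 2, mu = 0.2, c_F = 100,
                        M_F = 1, y_R = 0.5)
  F0 <- initial_feed_rate(pr)
  expect_equal(volumetric_feed_rate(2, pr), F0)
  expect_equal(volumetric_feed_rate(5, pr), F0 * exp(0.2 * 3))
  expect_equal(glucose_feed_rate(5, pr), 100 * F0 * exp(0.2 * 3))
  # cumulative fed volume: analytic antiderivative vs adaptive quadrature
  for (t in c(3, 7, 12)) {
    quad <- integrate(function(s) volumetric_feed_rate(s, pr), 2, t,
                      rel.tol = 1e-12)$value
    expect_equal(cumulative_feed_volume(t, pr), quad, tolerance = 1e-8)
    expect_equal(cumulative_feed_volume(t, pr),
                 (F0 / 0.2) * (exp(0.2 * (t - 2)) - 1), tolerance = 1e-12)
  }

  two <- feeding_profile("two_phase", t_F = 1, mu = 0.3, t_switch = 3,
                         c_F = 100, M_F = 2, y_R = 0.5)
  const_rate <- initial_feed_rate(two) * exp(0.3 * 3)
  expect_equal(volumetric_feed_rate(c(4, 6, 30), two), rep(const_rate, 3))
  expect_equal(cumulative_feed_volume(10, two),
               integrate(function(s) volumetric_feed_rate(s, two), 1, 10,
                         rel.tol = 1e-12)$value, tolerance = 1e-8)

  lg <- feeding_profile("logistic_mu", t_F = 5, m1 = 0.15, m2 = 0.2, m3 = 8,
                        c_F = 200, M_F = 1, y_R = 0.4)
  # closed-form exponent of the mu* integral vs direct quadrature
  for (t in c(6, 15, 40)) {
    num <- integrate(function(s) mu_star(s, lg), 5, t, rel.tol = 1e-12)$value
    expect_equal(volumetric_feed_rate(t, lg),
                 initial_feed_rate(lg) * exp(num), tolerance = 1e-8)
  }
})

test_that("integrated reactor volume matches the analytic law for exponential feeding", {
  setup <- fix_fedbatch_setup(mu = 0.2, t_F = 2, t_END = 8)
  sim <- run_simulation(setup, atol = 1e-10, rtol = 1e-10)
  tr <- sim$trajectory
  F0 <- initial_feed_rate(setup$feeding)
  expected <- ifelse(tr$time_h < 2, 1, 1 + (F0 / 0.2) * (exp(0.2 * (tr$time_h - 2)) - 1))
  expect_equal(tr$V_l, expected, tolerance = 1e-8)
  # batch mode: volume constant
  sim_b <- run_simulation(fix_batch_setup(t_END = 3))
  expect_equal(sim_b$trajectory$V_l, rep(1, nrow(sim_b$trajectory)))
})
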