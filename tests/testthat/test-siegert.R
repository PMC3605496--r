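test_that("free-potential moments evaluate the printed formulas", {
  p <- neuron_params()
  m0 <- moments_conductance(0, 0, p)
  expect_equal(m0$mu, p$V_P)
  expect_equal(m0$tau, p$tau_P)
  # 1 kHz excitatory, gamma' = 1/4: 1/tau = 0.05 + 0.005 + 0.0275
  m1 <- moments_conductance(1, 0.25, p)
  expect_equal(1 / m1$tau, 0.0825)
  expect_equal(m1$tau, 12.121212, tolerance = 1e-6)
  # effective time constant: tau -> tau_P as rates -> 0, decreasing in rate
  taus <- vapply(c(0, 1, 5, 20, 80), function(l)
    moments_conductance(l, 0.25 * l, p)$tau, numeric(1))
  expect_true(all(diff(taus) < 0))
  expect_equal(taus[1], 20)
  # current model keeps the passive time constant
  pc <- neuron_params("current", a_E = 0.3125, a_I = -1)
  mc <- moments_current(10, 2.5, pc)
  expect_equal(mc$tau, 20)
  expect_equal(mc$mu, -70 + 20 * (10 * 0.3125 - 2.5))
  expect_equal(mc$sigma^2, 10 * (10 * 0.3125^2 + 2.5))
})

test_that("current-model moments match a threshold-free ensemble simulation", {
  pc <- neuron_params("current", a_E = 0.2, a_I = -0.8)
  lamE <- 20; lamI <- 5; dt <- 0.1
  set.seed(14)
  n <- 3000; V <- rep(-70, n)
  dec <- exp(-dt / 20)
  for (k in 1:4000) {  # 400 ms: ~20 time constants, stationary
    V <- -70 + (V + 70) * dec +
      0.2 * rpois(n, lamE * dt) - 0.8 * rpois(n, lamI * dt)
  }
  m <- moments_current(lamE, lamI, pc)
  expect_lt(abs(mean(V) - m$mu), 4 * sd(V) / sqrt(n))
  # grid variance carries an O(dt/tau) bias; allow MC + discretization slack
  expect_lt(abs(sd(V) - m$sigma) / m$sigma, 0.05)
})

test_that("Siegert rate is stable, monotone, and moments-only", {
  p <- neuron_params()
  # deeply subthreshold: threshold 30 sigma away -> essentially zero
  r0 <- siegert_rate(gaussian_moments(-70, 0.5, 20), p)
  expect_lt(r0, 1e-6)
  expect_gte(r0, 0)
  # monotone in mu
  mus <- seq(-75, -56, by = 1)
  rr <- vapply(mus, function(m)
    siegert_rate(gaussian_moments(m, 2, 10), p), numeric(1))
  expect_true(all(diff(rr) > 0))
  # monotone in sigma on the subthreshold side
  sig <- seq(0.5, 6, by = 0.5)
  rs <- vapply(sig, function(s)
    siegert_rate(gaussian_moments(-70, s, 10), p), numeric(1))
  expect_true(all(diff(rs) > 0))
  # the formula sees only (mu, sigma, tau): conductance and current
  # parameter sets with matched moments give identical rates
  pc <- neuron_params("current", a_E = 0.3, a_I = -1.2)
  m <- gaussian_moments(-62, 3, 7)
  expect_identical(siegert_rate(m, p), siegert_rate(m, pc))
  expect_error(siegert_rate(gaussian_moments(-62, 0, 7), p), "sigma")
})

test_that("Siegert rate matches Monte-Carlo in the weak-synapse regime", {
  # small current jumps, tau = 20 >> dt: diffusion limit applies
  pc <- neuron_params("current", a_E = 0.1, a_I = -0.4)
  lamE <- 100; lamI <- 25
  m <- moments_current(lamE, lamI, pc)
  pred <- siegert_rate(m, pc)
  n_sp <- 0; T_eff <- 0
  for (r in 1:12) {
    sp <- simulate_single_neuron(pc, lamE, lamI, 4000, dt = 0.1,
                                 seed = 860 + r)
    n_sp <- n_sp + sum(sp > 400)
    T_eff <- T_eff + 3.6
  }
  mc <- n_sp / T_eff
  expect_lt(abs(mc - pred) / pred, 0.15)
})

test_that("minimum pool size follows the 95% displacement rule", {
  p <- neuron_params()
  expect_equal(n_E_min_gaussian(gaussian_moments(-65, 2, 10), p,
                                a_E = 0.3125), 43)
  expect_equal(n_E_min_gaussian(gaussian_moments(p$V_Theta, 0, 10), p,
                                a_E = 0.3125), 0)
  # increasing with sigma at fixed mu
  ns <- vapply(c(0.5, 1, 2, 4), function(s)
    n_E_min_gaussian(gaussian_moments(-65, s, 10), p), numeric(1))
  expect_true(all(diff(ns) > 0))
  expect_error(n_E_min_gaussian(gaussian_moments(-65, 2, 10), p, a_E = 0),
               "jump")
})

test_that("moment-matched current fit reproduces the conductance target", {
  p <- neuron_params(g_I = 0.095)
  fit <- fit_current_to_conductance(p, 6000, 5, gamma = 0.25)
  tgt <- attr(fit, "moments")
  # balanced by construction at V_P = mu
  lamE <- 6000 * 5 / 1000; lamI <- 0.25 * lamE
  expect_equal(fit$a_E * lamE + fit$a_I * lamI, 0, tolerance = 1e-12)
  expect_equal(fit$V_P, tgt$mu)
  # fitted model reproduces (mu, sigma) exactly
  m2 <- moments_current(lamE, lamI, fit)
  expect_equal(m2$mu, tgt$mu, tolerance = 1e-9)
  expect_equal(m2$sigma, tgt$sigma, tolerance = 1e-9)
  expect_equal(m2$tau, tgt$tau)
  # raising V_P lowers the excitation/inhibition amplitude ratio
  ratios <- vapply(c(-76, -70, -64), function(vp) {
    f <- fit_current_to_conductance(p, 6000, 5, V_P = vp, gamma = 0.25)
    f$a_E / abs(f$a_I)
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("comparison sweeps reproduce the conductance/current contrast", {
  grid <- seq(100, 20000, by = 100)
  # reference current amplitude from the conductance jump at V_avg
  p <- neuron_params()
  a_E <- p$g_E * (p$V_E - (p$V_R + p$V_Theta) / 2)
  expect_equal(round(a_E, 3), 0.312)

  sw_c <- sweep_comparison("conductance", c(0.05, 0.085, 0.1), grid, nu = 5)
  sm_c <- attr(sw_c, "summary")
  # high inhibition: minimum pool size approaches an asymptote, so capacity
  # grows ~linearly in connectivity over the retained series
  hi <- sw_c[sw_c$varied == 0.1, ]
  expect_gt(nrow(hi), 5)
  expect_true(all(diff(hi$alpha_max) > 0))
  nmin_tail <- tail(hi$n_E_min, 5)
  expect_lt(diff(range(nmin_tail)), 2)
  # alpha ~ C_E at the tail: ratio alpha/C_E nearly constant
  tail_ratio <- tail(hi$alpha_max / hi$C_E, 5)
  expect_lt(diff(range(tail_ratio)) / mean(tail_ratio), 0.1)

  sw_i <- sweep_comparison("current", c(0.5, 0.875, 1.25), grid, nu = 5)
  sm_i <- attr(sw_i, "summary")
  # conventional current model: optimal capacity decreases with inhibition
  best_i <- vapply(split(sw_i, sw_i$varied), function(d)
    max(d$alpha_max, na.rm = TRUE), numeric(1))
  expect_true(all(diff(best_i[order(as.numeric(names(best_i)))]) < 0))
  # both truncation mechanisms appear across the families: the stochastic
  # fixed point destabilizes at weak inhibition and the wave-dominance
  # bound binds at strong inhibition
  conds <- c(sm_c$condition, sm_i$condition)
  expect_true(any(conds == "instability"))
  expect_true(any(conds == "nu_S_bound"))

  sw_f <- sweep_comparison("fitted", c(-80, -70, -60), grid, nu = 5,
                           ref_g_I = 0.095)
  expect_true(all(c("mu", "sigma", "nu_S_Hz", "n_E_min", "alpha_max")
                  %in% names(sw_f)))
  expect_gt(nrow(sw_f), 3)
})
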