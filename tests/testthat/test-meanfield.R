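test_that("self-consistency solver matches closed forms on synthetic tables", {
  syn <- synthetic_tables(beta = 1e-5, T_const = 3)
  # silent fixed point: h = 0 and f_S(0) = 0
  s0 <- solve_selfconsistent(8000, 200, 0, syn$rates, syn$prop)
  expect_equal(s0$lambda_E, 0)
  expect_equal(s0$nu, 0)
  # linear case: p_f = 1, T = 3 ms, f_S = beta*lambda, C_E*beta < 1
  # => lambda = C_E*(h/N_E)*n_E / (3 * (1 - C_E*beta))
  C_E <- 8000; n_E <- 200; h_NE <- 26 / 80000
  s <- solve_selfconsistent(C_E, n_E, h_NE, syn$rates, syn$prop,
                            N_E = 80000)
  lam_closed <- C_E * h_NE * n_E / (syn$T_const * (1 - C_E * syn$beta))
  expect_equal(s$lambda_E, lam_closed, tolerance = 1e-8)
  expect_equal(s$nu, s$nu_W + s$nu_S)
  expect_equal(s$lambda_I, 0.25 * s$lambda_E)
  expect_equal(s$h, 26)
  expect_lt(abs(s$residual) / s$lambda_E, 1e-6)
})

test_that("bisection root agrees with an exhaustive residual grid scan", {
  # curved stochastic response sampled onto a table (quadratic at knots)
  lam <- seq(0, 100, by = 2)
  rates <- rate_table(lam, 0.3 * lam + 0.004 * lam^2, gamma_prime = 0.25)
  prop <- prop_table(n_E = 100, lambda_E = lam,
                     P_S = matrix(pmax(0, pmin(1, 2 - lam / 30)), 1),
                     p_f = matrix(0.9, 1, length(lam)),
                     T = matrix(3, 1, length(lam)), n_pools = 100)
  C_E <- 600; h_NE <- 10 / 6000
  sol <- solve_selfconsistent(C_E, 100, h_NE, rates, prop, N_E = 6000)
  # oracle: brute-force scan of the residual on a fine grid
  fS <- function(l) approx(lam, rates$rate_Hz, l)$y / 1000
  resid <- function(l) C_E * (h_NE * 100 * 0.9 / 3 + fS(l)) - l
  fine <- seq(0.01, 100, length.out = 2e5)
  r <- resid(fine)
  cross <- which(r[-1] <= 0 & r[-length(r)] > 0)[1]
  expect_lt(abs(sol$lambda_E - fine[cross]), 1e-3)
  expect_lt(abs(sol$residual) / sol$lambda_E, 1e-6)
  # no-solution bracket reports residuals at both ends
  expect_error(solve_selfconsistent(60000, 100, 1e-3, rates, prop),
               "residual at")
})

test_that("propagation threshold interpolation and inversion are exact", {
  pt <- prop_table(n_E = c(80, 120, 160), lambda_E = c(10, 20, 30, 40, 50),
                   P_S = rbind(c(1, 1, 0.8, 0.2, 0),
                               c(1, 1, 1, 0.6, 0.1),
                               c(1, 1, 1, 1, 0.7)),
                   p_f = matrix(0.9, 3, 5), T = matrix(3, 3, 5),
                   n_pools = 100)
  lm <- lambda_E_max(80, pt)
  expect_equal(lm$value, 35)            # linear interpolation of the 0.5 cross
  expect_false(lm$out_of_range)
  expect_equal(lambda_E_max(120, pt)$value, 40 + 10 * 0.1 / 0.5)
  expect_true(lambda_E_max(160, pt)$out_of_range)
  # inversion: pool size needed at a given background rate
  nm <- n_E_min(35, pt)
  expect_equal(nm$value, 80)
  expect_false(nm$out_of_range)
  mid <- n_E_min(38.5, pt)   # halfway between the two thresholds
  expect_equal(mid$value, 100)
  expect_true(n_E_min(5, pt)$out_of_range)
})

test_that("wave lifetime relations evaluate exactly", {
  pt <- prop_table(n_E = 100, lambda_E = c(10, 20, 30),
                   P_S = matrix(c(0.9, exp(-1), 0.1), 1),
                   p_f = matrix(0.9, 1, 3), T = matrix(3, 1, 3),
                   n_pools = 100)
  ew <- equilibrium_waves(20, 100, pt, T_stim = 40)
  expect_equal(ew$T_S, 3 * 98)          # T * L / log(1/e^-1) = 294
  expect_equal(ew$h_eq, 294 / 40)       # 7.35
  expect_false(ew$degenerate)
  # h_eq grows monotonically as P_S -> 1
  h <- vapply(seq(10, 30, by = 0.5), function(l)
    equilibrium_waves(l, 100, pt)$h_eq, numeric(1))
  expect_true(all(diff(h) < 0))         # P_S falls with lambda, so h falls
  expect_true(equilibrium_waves(30, 100,
    prop_table(100, c(10, 20, 30), matrix(c(1, 1, 1), 1),
               matrix(0.9, 1, 3), matrix(3, 1, 3)))$degenerate)
})

test_that("capacity curve reproduces the alpha = C_E/n_min^2 algebra", {
  lam <- seq(0, 60, by = 5)
  rates <- rate_table(lam, 0.05 * lam, gamma_prime = 0.25)
  # n_E_min rises linearly from 50 (at lambda 10) to 100 (at lambda 40)
  pt <- prop_table(n_E = c(50, 100), lambda_E = lam,
                   P_S = rbind(ifelse(lam <= 10, 1, 0),
                               ifelse(lam <= 40, 1, 0)),
                   p_f = matrix(0.9, 2, length(lam)),
                   T = matrix(3, 2, length(lam)), n_pools = 100)
  # thresholds: rows cross 0.5 at 12.5 and 42.5 kHz respectively
  cc <- capacity_curve("nu_eq", 5, c(3000, 5000, 7000), rates, pt)
  lam_pts <- c(3000, 5000, 7000) * 0.005
  n_min <- approx(c(12.5, 42.5), c(50, 100), xout = lam_pts)$y
  expect_equal(cc$n_E_min, n_min, tolerance = 1e-6)
  expect_equal(cc$alpha_max, cc$C_E / cc$n_E_min^2)
  # scaling C_E at fixed n_E_min scales the embedding capacity linearly
  expect_equal(cc$alpha_max[2] / cc$alpha_max[1],
               (5000 / 3000) * (cc$n_E_min[1] / cc$n_E_min[2])^2)
})

test_that("mean-field solution on measured tables satisfies its residual bound", {
  tb <- agreement_tables()
  sol <- solve_selfconsistent(500, 100, 5 / 5000, tb$rates, tb$prop,
                              N_E = 5000)
  expect_lt(abs(sol$residual) / max(sol$lambda_E, 1e-9), 1e-6)
  expect_gt(sol$lambda_E, 0)
  expect_equal(sol$nu, sol$nu_W + sol$nu_S)
})

test_that("exact and threshold-approximated equilibria agree to grid spacing", {
  tb <- agreement_tables()
  eq <- equilibrium_state(500, 100, tb$rates, tb$prop, T_stim = 40,
                          N_E = 5000)
  dlam <- max(diff(tb$prop$lambda_E))
  expect_lt(abs(eq$exact$lambda_E - eq$approx$lambda_E), dlam)
})

test_that("neglected synchrony correction is small at cortical-scale geometry", {
  # n_E / (C_E (1 + nu_S/nu_W)) evaluated at driven equilibria
  tb <- ordering_tables(0.11)
  vals <- c()
  for (cfg in list(c(5000, 100), c(8000, 100), c(11000, 140))) {
    eq <- equilibrium_state(cfg[1], cfg[2], tb$rates, tb$prop,
                            N_E = 10 * cfg[1])
    vals <- c(vals, cfg[2] / (cfg[1] * (1 + eq$exact$nu_S_Hz /
                                          eq$exact$nu_W_Hz)))
  }
  expect_true(all(vals > 0.002 & vals < 0.05))
})

test_that("pool-size trade-off: bigger pools give higher rate, lower capacity", {
  tb <- ordering_tables(0.11)
  C_E <- 6000
  eqs <- lapply(c(100, 140), function(n)
    equilibrium_state(C_E, n, tb$rates, tb$prop, N_E = 10 * C_E))
  nu <- vapply(eqs, function(e) e$exact$nu_Hz, numeric(1))
  h <- vapply(eqs, function(e) e$exact$h_eq, numeric(1))
  expect_gt(nu[2], nu[1])               # rate rises with pool size
  expect_gt(h[2], h[1])                 # so does the number of waves
  alpha <- C_E / c(100, 140)^2
  expect_lt(alpha[2], alpha[1])         # while the embedding level falls
})
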