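# Diffusion-approximation analysis: Gaussian membrane-potential moments,
# the Siegert first-passage rate, and the conductance- vs current-based
# model comparison.

#' Gaussian moments of the free membrane potential
#'
#' Moments of the membrane-potential distribution without a spiking
#' threshold under stationary Poisson bombardment: mean `mu`, standard
#' deviation `sigma` (mV) and the effective membrane time constant `tau`
#' (ms). For conductance synapses `tau` shrinks with input rate (the
#' high-conductance state); for current synapses it equals the passive
#' `tau_P`.
#'
#' @param mu,sigma,tau Numeric scalars (mV, mV, ms).
#' @return An object of class `gaussian_moments`.
#' @export
gaussian_moments <- function(mu, sigma, tau) {
  if (sigma < 0) stop_invalid("sigma must be >= 0")
  if (tau <= 0) stop_invalid("tau must be > 0")
  structure(list(mu = mu, sigma = sigma, tau = tau),
            class = "gaussian_moments")
}

#' Free membrane-potential moments under Poisson input
#'
#' Effective-time-constant diffusion approximation. Conductance kind:
#' `1/tau = 1/tau_P + lambda_E g_E + lambda_I g_I`,
#' `mu = tau (V_P/tau_P + lambda_E g_E V_E + lambda_I g_I V_I)`,
#' `sigma^2 = (tau/2) (lambda_E g_E^2 (V_E - mu)^2 +
#'                     lambda_I g_I^2 (V_I - mu)^2)`.
#' Current kind: `tau = tau_P`,
#' `mu = V_P + tau_P (lambda_E a_E + lambda_I a_I)`,
#' `sigma^2 = (tau_P/2) (lambda_E a_E^2 + lambda_I a_I^2)`.
#'
#' @param lambda_E,lambda_I Input rates (kHz), >= 0.
#' @param params A [neuron_params()] of the matching kind.
#' @return A [gaussian_moments()].
#' @export
moments_conductance <- function(lambda_E, lambda_I, params) {
  if (lambda_E < 0 || lambda_I < 0) stop_invalid("rates must be >= 0")
  inv_tau <- 1 / params$tau_P + lambda_E * params$g_E + lambda_I * params$g_I
  tau <- 1 / inv_tau
  mu <- tau * (params$V_P / params$tau_P +
                 lambda_E * params$g_E * params$V_E +
                 lambda_I * params$g_I * params$V_I)
  s2 <- (tau / 2) * (lambda_E * params$g_E^2 * (params$V_E - mu)^2 +
                       lambda_I * params$g_I^2 * (params$V_I - mu)^2)
  gaussian_moments(mu, sqrt(s2), tau)
}

#' @rdname moments_conductance
#' @export
moments_current <- function(lambda_E, lambda_I, params) {
  if (lambda_E < 0 || lambda_I < 0) stop_invalid("rates must be >= 0")
  mu <- params$V_P + params$tau_P * (lambda_E * params$a_E +
                                       lambda_I * params$a_I)
  s2 <- (params$tau_P / 2) * (lambda_E * params$a_E^2 +
                                lambda_I * params$a_I^2)
  gaussian_moments(mu, sqrt(s2), params$tau_P)
}

# Stable evaluation of g(z) = sqrt(pi) * exp(z^2) * (1 + erf(z)).
# For z <= 0 this equals sqrt(pi) * erfcx(-z); far in the left tail the
# scaled complementary error function is replaced by its asymptotic series
# (erfcx overflows internally beyond |z| ~ 26).
siegert_integrand <- function(z) {
  out <- numeric(length(z))
  far <- z < -15
  if (any(far)) {
    x <- -z[far]
    out[far] <- (1 / x) * (1 - 0.5 / x^2 + 0.75 / x^4)
  }
  neg <- !far & z <= 0
  out[neg] <- sqrt(pi) * pracma::erfcx(-z[neg])
  pos <- z > 0
  if (any(pos)) {
    zp <- z[pos]
    out[pos] <- sqrt(pi) * (2 * exp(zp^2) - pracma::erfcx(zp))
  }
  out
}

#' Siegert first-passage spiking rate
#'
#' Mean firing rate of a leaky integrate-and-fire neuron in the diffusion
#' approximation:
#' `rate = 1 / (tau_ref + tau * I)` with
#' `I = integral from (V_R - mu)/(sqrt(2) sigma) to
#' (V_Theta - mu)/(sqrt(2) sigma) of sqrt(pi) e^{z^2} (1 + erf z) dz`.
#' The integral depends on the model only through the moments, so matched
#' `(mu, sigma, tau)` give identical rates for conductance and current
#' synapses. The upper tail is integrated after factoring out `e^{zu^2}`
#' (log-space) so deeply subthreshold operating points do not overflow.
#'
#' @param moments A [gaussian_moments()].
#' @param params A [neuron_params()] (supplies `V_R`, `V_Theta`, `tau_ref`).
#' @return Firing rate in Hz.
#' @export
siegert_rate <- function(moments, params) {
  if (moments$sigma <= 0) stop_invalid("sigma must be > 0")
  s <- sqrt(2) * moments$sigma
  zl <- (params$V_R - moments$mu) / s
  zu <- (params$V_Theta - moments$mu) / s
  if (zu <= 3) {
    I <- stats::integrate(siegert_integrand, zl, zu, rel.tol = 1e-10,
                          abs.tol = 1e-12)$value
    if (!is.finite(I)) stop_invalid("non-finite Siegert integrand")
    return(1000 / (params$tau_ref + moments$tau * I))
  }
  # split at a = max(zl, 0); direct part below, log-space tail above
  a <- max(zl, 0)
  I_low <- if (zl < a)
    stats::integrate(siegert_integrand, zl, a, rel.tol = 1e-10,
                     abs.tol = 1e-12)$value else 0
  # tail: substitute w = zu - z and factor out exp(zu^2); with z >= 0 on
  # this segment, exp(w^2 - 2*zu*w) <= 1 and 1 + erf(z) = 2*pnorm(sqrt(2)z)
  tail_fun <- function(w) {
    z <- zu - w
    exp(w^2 - 2 * zu * w) * sqrt(pi) * 2 * stats::pnorm(sqrt(2) * z)
  }
  # the integrand decays on the scale 1/(2*zu); truncate where it has
  # fallen below exp(-50) of its peak
  w_hi <- min(zu - a, if (zu > 7.2) 50 / zu else Inf)
  J <- stats::integrate(tail_fun, 0, w_hi, rel.tol = 1e-10,
                        abs.tol = 0)$value
  if (!is.finite(J)) stop_invalid("non-finite Siegert integrand")
  logI_high <- zu^2 + log(J)
  if (logI_high < 690) {
    I <- I_low + exp(logI_high)
    return(1000 / (params$tau_ref + moments$tau * I))
  }
  # astronomically long passage time: tau_ref and I_low are negligible
  1000 * exp(-logI_high - log(moments$tau))
}

#' Minimum pool size from the Gaussian membrane-potential approximation
#'
#' For stable propagation, a volley of `n` synchronous inputs of effective
#' amplitude `a_E` must shift 95 percent of the membrane-potential distribution
#' above threshold: `n * a_E >= V_Theta - (mu - 1.645 sigma)`, giving
#' `n_E_min = ceiling((V_Theta - mu + 1.645 sigma) / a_E)`. For conductance
#' synapses the effective amplitude is `g_E * (V_E - V_avg)` with
#' `V_avg = (V_R + V_Theta) / 2`.
#'
#' @param moments A [gaussian_moments()].
#' @param params A [neuron_params()].
#' @param a_E Effective excitatory jump (mV); default: derived from
#'   `params` as above.
#' @return Integer pool size (>= 0).
#' @export
n_E_min_gaussian <- function(moments, params, a_E = NULL) {
  if (is.null(a_E)) {
    a_E <- if (params$model_kind == "conductance")
      params$g_E * (params$V_E - (params$V_R + params$V_Theta) / 2)
    else params$a_E
  }
  if (!is.finite(a_E) || a_E <= 0)
    stop_invalid("effective excitatory jump must be > 0")
  max(0, ceiling((params$V_Theta - moments$mu + 1.645 * moments$sigma) / a_E))
}

#' Fit a current-based model to a conductance-based operating point
#'
#' At background rates `lambda_E = C_E_fit * nu`, `lambda_I = gamma *
#' lambda_E` the conductance model has moments `(mu, sigma, tau)`. The
#' fitted current model takes `tau_P = tau` and solves the two moment
#' equations for `(a_E, a_I)` given a chosen resting potential `V_P`
#' (default `V_P = mu`, which makes the fitted model exactly balanced:
#' `a_E lambda_E + a_I lambda_I = 0`).
#'
#' @param cond_params Conductance-kind [neuron_params()].
#' @param C_E_fit Connectivity at which to match.
#' @param nu Population firing rate (Hz).
#' @param V_P Resting potential of the fitted model (mV); default the
#'   conductance model's mean free potential.
#' @param gamma Inhibitory/excitatory rate ratio.
#' @return A current-kind [neuron_params()] with attribute `moments` (the
#'   matched target).
#' @export
fit_current_to_conductance <- function(cond_params, C_E_fit, nu,
                                       V_P = NULL, gamma = 0.25) {
  lambda_E <- C_E_fit * nu / 1000
  lambda_I <- gamma * lambda_E
  m <- moments_conductance(lambda_E, lambda_I, cond_params)
  if (is.null(V_P)) V_P <- m$mu
  S1 <- (m$mu - V_P) / m$tau
  S2 <- 2 * m$sigma^2 / m$tau
  A <- lambda_E * (lambda_I + lambda_E)
  B <- -2 * S1 * lambda_E
  C <- S1^2 - S2 * lambda_I
  disc <- B^2 - 4 * A * C
  if (disc < 0) stop_invalid("no real (a_E, a_I) fit for V_P = %g", V_P)
  a_E <- (-B + sqrt(disc)) / (2 * A)
  a_I <- (S1 - lambda_E * a_E) / lambda_I
  if (a_E <= 0 || a_I > 0)
    stop_invalid("infeasible fit for V_P = %g (a_E = %g, a_I = %g)",
                 V_P, a_E, a_I)
  out <- neuron_params("current", V_E = cond_params$V_E,
                       V_I = cond_params$V_I, V_P = V_P,
                       V_R = cond_params$V_R,
                       V_Theta = cond_params$V_Theta, tau_P = m$tau,
                       tau_ref = cond_params$tau_ref, a_E = a_E, a_I = a_I)
  attr(out, "moments") <- m
  out
}

#' Connectivity sweep comparing conductance- and current-based models
#'
#' For a family of models at a fixed mean firing rate `nu`, sweeps the
#' connectivity grid, setting `lambda_E = C_E * nu` and `lambda_I = gamma *
#' lambda_E`, and computes per point the Gaussian moments, the equilibrium
#' stochastic rate `nu_S` from the Siegert formula, its stability
#' (`|C_E * d nu_S / d lambda_E| < 1`, central difference over one grid
#' interval), the minimum pool size, and the capacity `alpha_max =
#' C_E / n_E_min^2`. Each series is truncated at `C_E_max`, the last grid
#' point before (a) the stochastic fixed point destabilizes, (b) stochastic
#' spikes exceed half of all spiking, or (c) the capacity stops increasing.
#'
#' Families: `"conductance"` varies `g_I`; `"current"` varies the
#' inhibitory amplitude magnitude `|a_I|` (mV) with `a_E = g_E * (V_E -
#' V_avg)`; `"fitted"` varies the resting potential `V_P` (mV) of
#' current-based models moment-matched (via
#' [fit_current_to_conductance()]) to a reference conductance model at its
#' own `C_E_max`.
#'
#' @param family `"conductance"`, `"current"` or `"fitted"`.
#' @param varied Grid of the varied parameter (see above).
#' @param C_E_grid Ascending connectivities.
#' @param nu Mean firing rate (Hz).
#' @param params Base conductance-kind [neuron_params()].
#' @param gamma Inhibitory/excitatory rate ratio.
#' @param ref_g_I Reference inhibitory conductance for the fitted family.
#' @return A `comparison_sweep` data frame (`family`, `varied`, `C_E`,
#'   `mu`, `sigma`, `tau`, `nu_S_Hz`, `n_E_min`, `alpha_max`) truncated at
#'   each series' `C_E_max`; attribute `summary` holds per-series `C_E_max`
#'   and the terminating condition.
#' @export
sweep_comparison <- function(family = c("conductance", "current", "fitted"),
                             varied, C_E_grid, nu = 5,
                             params = neuron_params(), gamma = 0.25,
                             ref_g_I = 0.095) {
  family <- match.arg(family)
  nu_k <- nu / 1000
  a_E_cond <- params$g_E * (params$V_E - (params$V_R + params$V_Theta) / 2)

  sweep_one <- function(mod, tag) {
    momf <- if (mod$model_kind == "conductance") moments_conductance
    else moments_current
    dlam <- diff(C_E_grid[1:2]) * nu_k
    rows <- lapply(C_E_grid, function(CE) {
      lam <- CE * nu_k
      m <- momf(lam, gamma * lam, mod)
      nuS <- siegert_rate(m, mod)
      f <- function(l) siegert_rate(momf(l, gamma * l, mod), mod) / 1000
      deriv <- (f(lam + dlam) - f(max(lam - dlam, 1e-9))) /
        (lam + dlam - max(lam - dlam, 1e-9))
      nmin <- n_E_min_gaussian(m, mod, a_E = if (mod$model_kind ==
                                                 "conductance") a_E_cond
                               else mod$a_E)
      data.frame(family = family, varied = tag, C_E = CE, mu = m$mu,
                 sigma = m$sigma, tau = m$tau, nu_S_Hz = nuS,
                 n_E_min = nmin,
                 alpha_max = if (nmin > 0) CE / nmin^2 else NA_real_,
                 stable = abs(CE * deriv) < 1,
                 wave_dominated = nuS < 0.5 * nu)
    })
    df <- do.call(rbind, rows)
    cond <- "grid_end"
    last <- nrow(df)
    for (k in seq_len(nrow(df))) {
      if (!df$stable[k]) { cond <- "instability"; last <- k - 1L; break }
      if (!df$wave_dominated[k]) { cond <- "nu_S_bound"; last <- k - 1L
        break }
      if (k > 1 && !is.na(df$alpha_max[k]) && !is.na(df$alpha_max[k - 1]) &&
          df$alpha_max[k] <= df$alpha_max[k - 1]) {
        cond <- "alpha_plateau"; last <- k - 1L; break
      }
    }
    if (last < 1) last <- 1L
    list(series = df[seq_len(last), ],
         summary = data.frame(family = family, varied = tag,
                              C_E_max = df$C_E[last], condition = cond))
  }

  models <- switch(family,
    conductance = lapply(varied, function(gI)
      neuron_params("conductance", V_E = params$V_E, V_I = params$V_I,
                    V_P = params$V_P, V_R = params$V_R,
                    V_Theta = params$V_Theta, tau_P = params$tau_P,
                    tau_ref = params$tau_ref, g_E = params$g_E, g_I = gI)),
    current = lapply(varied, function(aI)
      neuron_params("current", V_E = params$V_E, V_I = params$V_I,
                    V_P = params$V_P, V_R = params$V_R,
                    V_Theta = params$V_Theta, tau_P = params$tau_P,
                    tau_ref = params$tau_ref, a_E = a_E_cond, a_I = -aI)),
    fitted = {
      ref <- neuron_params("conductance", V_E = params$V_E,
                           V_I = params$V_I, V_P = params$V_P,
                           V_R = params$V_R, V_Theta = params$V_Theta,
                           tau_P = params$tau_P, tau_ref = params$tau_ref,
                           g_E = params$g_E, g_I = ref_g_I)
      ref_sweep <- sweep_comparison("conductance", ref_g_I, C_E_grid, nu,
                                    ref, gamma)
      C_E_fit <- attr(ref_sweep, "summary")$C_E_max[1]
      lapply(varied, function(vp)
        fit_current_to_conductance(ref, C_E_fit, nu, V_P = vp,
                                   gamma = gamma))
    })

  res <- Map(sweep_one, models, varied)
  out <- do.call(rbind, lapply(res, `[[`, "series"))
  structure(out, summary = do.call(rbind, lapply(res, `[[`, "summary")),
            class = c("comparison_sweep", "data.frame"))
}
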