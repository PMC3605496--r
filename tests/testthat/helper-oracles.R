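# Independent oracles used by the tests. These deliberately avoid the
# package's grid integrator and compiled engine.

# Exact event-driven integrate-and-fire: closed-form decay between input
# events, jumps applied at the exact event times, threshold tested per
# event. The reference the grid integrator must converge to as dt -> 0.
oracle_lif <- function(params, ev_time, ev_inh, T_end, V0 = params$V_P) {
  o <- order(ev_time)
  ev_time <- ev_time[o]; ev_inh <- ev_inh[o]
  keep <- ev_time >= 0 & ev_time <= T_end
  ev_time <- ev_time[keep]; ev_inh <- ev_inh[keep]
  tau <- params$tau_P; VP <- params$V_P
  V <- V0; t_prev <- 0; ref_until <- -Inf
  spikes <- numeric(10000); ns <- 0L
  for (i in seq_along(ev_time)) {
    t <- ev_time[i]
    if (t < ref_until) next
    if (t_prev < ref_until) { V <- params$V_R; t_prev <- ref_until }
    V <- VP + (V - VP) * exp(-(t - t_prev) / tau)
    t_prev <- t
    if (params$model_kind == "conductance") {
      V <- if (ev_inh[i]) params$V_I + (V - params$V_I) * (1 - params$g_I)
      else params$V_E + (V - params$V_E) * (1 - params$g_E)
    } else {
      V <- V + if (ev_inh[i]) params$a_I else params$a_E
    }
    if (V >= params$V_Theta) {
      ns <- ns + 1L
      if (ns > length(spikes)) spikes <- c(spikes, numeric(length(spikes)))
      spikes[ns] <- t
      V <- params$V_R
      ref_until <- t + params$tau_ref
    }
  }
  if (T_end < ref_until) {
    V <- params$V_R
  } else {
    if (t_prev < ref_until) { V <- params$V_R; t_prev <- ref_until }
    V <- VP + (V - VP) * exp(-(T_end - t_prev) / tau)
  }
  list(spikes = spikes[seq_len(ns)], V_end = V)
}

# Grid integration of a prescribed event train through step_membrane,
# returning the final membrane potential.
grid_lif_V <- function(params, ev_time, ev_inh, T_end, dt) {
  n_steps <- round(T_end / dt)
  stp <- pmax(1L, as.integer(ceiling(ev_time / dt - 1e-9)))
  ok <- stp <= n_steps
  cE <- tabulate(stp[ok & !ev_inh], nbins = n_steps)
  cI <- tabulate(stp[ok & ev_inh], nbins = n_steps)
  s <- neuron_state(params$V_P)
  for (k in seq_len(n_steps))
    s <- step_membrane(s, params, cE[k], cI[k], dt)
  s$V
}

# Poisson event train (exact continuous times) for the oracle.
poisson_events <- function(lambda_E, lambda_I, T_end) {
  nE <- rpois(1, lambda_E * T_end)
  nI <- rpois(1, lambda_I * T_end)
  list(time = c(runif(nE, 0, T_end), runif(nI, 0, T_end)),
       inh = c(rep(FALSE, nE), rep(TRUE, nI)))
}

# Mean absolute final-potential error of the grid integrator against the
# event-driven oracle, averaged over several random subthreshold trains so
# that sign cancellations of a single realization do not mask the
# convergence order.
grid_convergence_errors <- function(params, dts, n_trains = 6,
                                    n_events = 150, T_end = 60, seed = 7) {
  set.seed(seed)
  trains <- lapply(seq_len(n_trains), function(i)
    list(ev = sort(runif(n_events, 0, T_end)),
         inh = runif(n_events) < 0.4))
  refs <- vapply(trains, function(tr)
    oracle_lif(params, tr$ev, tr$inh, T_end)$V_end, numeric(1))
  vapply(dts, function(dt)
    mean(vapply(seq_len(n_trains), function(i)
      abs(grid_lif_V(params, trains[[i]]$ev, trains[[i]]$inh, T_end, dt) -
            refs[i]), numeric(1))), numeric(1))
}
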