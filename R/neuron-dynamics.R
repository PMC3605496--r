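#' Membrane state of a single neuron
#'
#' @param V Membrane potential (mV).
#' @param refractory_remaining Remaining refractory time (ms).
#' @return An object of class `neuron_state` with fields `V`,
#'   `refractory_remaining` and the logical `spiked`.
#' @export
neuron_state <- function(V, refractory_remaining = 0) {
  if (refractory_remaining < 0)
    stop_invalid("refractory_remaining must be >= 0")
  structure(list(V = V, refractory_remaining = refractory_remaining,
                 spiked = FALSE),
            class = "neuron_state")
}

#' Advance the membrane potential by one time step
#'
#' Applies, in order: exponential leak decay toward the resting potential
#' over `dt`, then `n_exc` excitatory jumps, then `n_inh` inhibitory jumps
#' (same-type jumps commute, so only the counts matter; the E-before-I order
#' is a fixed convention of the integrator). The threshold is tested once,
#' after all jumps: on a crossing the state is marked spiked, the potential
#' reset to `V_R`, and the refractory clock loaded with `tau_ref`. During
#' refractoriness the potential stays clamped at `V_R` and all inputs are
#' discarded.
#'
#' @param state A [neuron_state()].
#' @param params A [neuron_params()].
#' @param n_exc,n_inh Number of excitatory / inhibitory input spikes arriving
#'   in this step.
#' @param dt Step width (ms), > 0.
#' @return The updated `neuron_state`; `$spiked` is `TRUE` iff a spike was
#'   emitted in this step.
#' @export
#' @examples
#' p <- neuron_params()
#' s <- step_membrane(neuron_state(-55.5), p, n_exc = 10, dt = 0.1)
#' s$spiked
step_membrane <- function(state, params, n_exc = 0, n_inh = 0, dt) {
  if (dt <= 0) stop_invalid("dt must be > 0")
  if (n_exc < 0 || n_inh < 0) stop_invalid("input counts must be >= 0")
  state$spiked <- FALSE
  if (state$refractory_remaining > 0) {
    state$V <- params$V_R
    state$refractory_remaining <- max(0, state$refractory_remaining - dt)
    return(state)
  }
  v <- params$V_P + (state$V - params$V_P) * exp(-dt / params$tau_P)
  if (params$model_kind == "conductance") {
    if (n_exc > 0) v <- params$V_E + (v - params$V_E) * (1 - params$g_E)^n_exc
    if (n_inh > 0) v <- params$V_I + (v - params$V_I) * (1 - params$g_I)^n_inh
  } else {
    v <- v + n_exc * params$a_E + n_inh * params$a_I
  }
  if (v >= params$V_Theta) {
    state$spiked <- TRUE
    v <- params$V_R
    state$refractory_remaining <- params$tau_ref
  }
  state$V <- v
  state
}

#' Simulate a single neuron under Poisson bombardment
#'
#' Drives one neuron with independent excitatory and inhibitory Poisson input
#' streams, realized as per-step Poisson counts with means `lambda_E * dt`
#' and `lambda_I * dt`. Deterministic for a fixed seed.
#'
#' @param params A [neuron_params()].
#' @param lambda_E,lambda_I Input rates in kHz (spikes/ms).
#' @param duration Simulated time (ms).
#' @param dt Step width (ms); default 0.1.
#' @param seed Integer RNG seed.
#' @param return_V If `TRUE`, also return the membrane-potential trace.
#' @return Numeric vector of spike times (ms, step-end stamped); if
#'   `return_V`, a list with `spikes` and `V` (one value per step).
#' @export
simulate_single_neuron <- function(params, lambda_E, lambda_I, duration,
                                   dt = 0.1, seed = 1, return_V = FALSE) {
  if (lambda_E < 0 || lambda_I < 0) stop_invalid("rates must be >= 0")
  if (duration <= dt) stop_invalid("duration must exceed dt")
  n_steps <- as.integer(round(duration / dt))
  res <- local_seed(seed, engine_run(
    1L, c(0L, 0L), integer(0), integer(0), integer(0),
    n_steps, dt,
    rep(lambda_E * dt, n_steps), rep(lambda_I * dt, n_steps),
    integer(0), integer(0), integer(0),
    engine_par(params, dt), return_V, 0L))
  spikes <- (res$step + 1) * dt
  if (return_V) list(spikes = spikes, V = res$v_trace) else spikes
}

#' Stochastic-rate table: mean firing rate versus background input rate
#'
#' Estimates the stochastic spiking rate `f_S(lambda_E, gamma' * lambda_E)`
#' of a single neuron on a grid of excitatory background rates by repeated
#' Poisson-driven simulation, discarding an initial transient. The reference
#' protocol is 100 runs of 5000 ms per grid point with the first 1000 ms
#' discarded; smaller protocols can be configured.
#'
#' @param params A [neuron_params()].
#' @param lambda_E_grid Strictly ascending excitatory rates (kHz).
#' @param gamma_prime Ratio of inhibitory to excitatory input rate.
#' @param n_runs Runs per grid point.
#' @param run_duration,discard Run length and discarded transient (ms).
#' @param dt Step width (ms).
#' @param seed Integer RNG seed.
#' @return A `rate_table`: data frame with columns `lambda_E_kHz`, `rate_Hz`
#'   and attributes `gamma_prime`, `protocol`, `seed`.
#' @export
estimate_fS <- function(params, lambda_E_grid, gamma_prime = 0.25,
                        n_runs = 100, run_duration = 5000, discard = 1000,
                        dt = 0.1, seed = 1) {
  if (length(lambda_E_grid) == 0) stop_invalid("empty lambda_E grid")
  if (is.unsorted(lambda_E_grid, strictly = TRUE))
    stop_invalid("lambda_E grid must be strictly ascending")
  if (discard >= run_duration) stop_invalid("discard must be < run_duration")
  rate <- vapply(seq_along(lambda_E_grid), function(i) {
    lam <- lambda_E_grid[i]
    if (lam == 0 && params$model_kind == "conductance") return(0)
    n_sp <- 0
    for (r in seq_len(n_runs)) {
      sp <- simulate_single_neuron(params, lam, gamma_prime * lam,
                                   run_duration, dt,
                                   seed = derive_seed(seed, i, r))
      n_sp <- n_sp + sum(sp > discard)
    }
    1000 * n_sp / (n_runs * (run_duration - discard))
  }, numeric(1))
  rate_table(lambda_E_grid, rate, gamma_prime,
             protocol = list(n_runs = n_runs, run_duration = run_duration,
                             discard = discard, dt = dt),
             seed = seed)
}

#' Construct a stochastic-rate table
#'
#' @param lambda_E_kHz Ascending grid of excitatory background rates (kHz).
#' @param rate_Hz Mean stochastic spiking rate at each grid point (Hz).
#' @param gamma_prime Inhibitory/excitatory input-rate ratio of the protocol.
#' @param protocol,seed Optional metadata stored as attributes.
#' @return A `rate_table` data frame.
#' @export
rate_table <- function(lambda_E_kHz, rate_Hz, gamma_prime = 0.25,
                       protocol = NULL, seed = NULL) {
  if (is.unsorted(lambda_E_kHz, strictly = TRUE))
    stop_invalid("lambda_E grid must be strictly ascending")
  if (any(rate_Hz < 0)) stop_invalid("rates must be >= 0")
  structure(data.frame(lambda_E_kHz = lambda_E_kHz, rate_Hz = rate_Hz),
            gamma_prime = gamma_prime, protocol = protocol, seed = seed,
            class = c("rate_table", "data.frame"))
}

#' Evaluate a rate table by linear interpolation
#'
#' @param table A [rate_table()].
#' @param lambda_E Query rates (kHz); must lie within the grid range.
#' @return Interpolated rates (Hz).
#' @export
fS_lookup <- function(table, lambda_E) {
  rng <- range(table$lambda_E_kHz)
  if (any(lambda_E < rng[1] - 1e-12) || any(lambda_E > rng[2] + 1e-12))
    stop_invalid("lambda_E %g outside table range [%g, %g]",
                 lambda_E[which(lambda_E < rng[1] | lambda_E > rng[2])[1]],
                 rng[1], rng[2])
  if (nrow(table) == 1) return(rep(table$rate_Hz, length(lambda_E)))
  approx(table$lambda_E_kHz, table$rate_Hz, xout = lambda_E, rule = 2)$y
}

#' Write / read a rate table as two-column TSV
#'
#' Header comment lines record the protocol metadata.
#' @param table A [rate_table()].
#' @param path File path.
#' @return `read_rate_table` returns the `rate_table`.
#' @export
write_rate_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_table gamma_prime=%g seed=%s",
                     attr(table, "gamma_prime"),
                     attr(table, "seed") %||% "NA"), con)
  pr <- attr(table, "protocol")
  if (!is.null(pr))
    writeLines(sprintf("# protocol n_runs=%d run_duration=%g discard=%g dt=%g",
                       pr$n_runs, pr$run_duration, pr$discard, pr$dt), con)
  writeLines("lambda_E_kHz\trate_Hz", con)
  write.table(as.data.frame(table), con, sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  gp <- 0.25
  m <- regmatches(hdr, regexpr("gamma_prime=[0-9.eE+-]+", hdr))
  if (length(m)) gp <- as.numeric(sub("gamma_prime=", "", m[1]))
  df <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                   sep = "\t")
  rate_table(df$lambda_E_kHz, df$rate_Hz, gamma_prime = gp)
}
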