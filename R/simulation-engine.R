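#' Wave-initiation stimulus protocol
#'
#' External input consists of near-synchronous packets of excitatory spikes
#' delivered to one target E-pool (and its shadow I-pool, when present):
#' `packet_size` source spikes normally distributed around the nominal
#' stimulus time with standard deviation `packet_sigma`, each delivered to
#' each target neuron with an independent intra-link (`tau_B`) transmission
#' delay. Stimuli repeat every `period` ms from `start` onwards. An optional
#' balanced Poisson ramp (rates given in kHz, stepped to zero in four equal
#' decrements at the first four stimuli) can bring the network near its
#' operating point before the first packets arrive; it is off by default.
#'
#' @param target_pool Index of the stimulated pool.
#' @param period Inter-stimulus interval (ms).
#' @param start Time of the first stimulus (ms).
#' @param packet_size Number of stimulus spikes; default: the pool size.
#' @param packet_sigma Temporal spread of the packet (ms).
#' @param ramp `NULL` (off) or `c(lambda_E, lambda_I)` initial ramp rates in
#'   kHz.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(target_pool = 1, period = 40, start = 200,
                              packet_size = NULL, packet_sigma = 0.1,
                              ramp = NULL) {
  if (period <= 0) stop_invalid("period must be > 0")
  structure(list(target_pool = as.integer(target_pool), period = period,
                 start = start, packet_size = packet_size,
                 packet_sigma = packet_sigma, ramp = ramp),
            class = "stimulus_protocol")
}

#' Nominal stimulus times of a protocol within a run
#'
#' @param protocol A [stimulus_protocol()].
#' @param duration Run length (ms).
#' @return Times (ms) of all stimuli with `start <= t <= duration`.
#' @export
#' @examples
#' stimulus_times(stimulus_protocol(), 400)  # 200 240 280 320 360
stimulus_times <- function(protocol, duration) {
  if (protocol$start >= duration) return(numeric(0))
  tt <- seq(protocol$start, duration, by = protocol$period)
  tt[tt < duration]
}

#' Simulate a network realization
#'
#' Time-stepped simulation of any `network_spec` with optional external
#' Poisson background (same rate for every neuron) and optional
#' wave-initiating stimulus packets. Spike delivery respects per-synapse
#' delays; runs are bit-reproducible for a fixed seed.
#'
#' @param spec A `network_spec` from [build_embedding()] or
#'   [build_control_chain()].
#' @param params A [neuron_params()].
#' @param protocol A [stimulus_protocol()] or `NULL` for no stimulation.
#' @param background `NULL` or `list(lambda_E = , lambda_I = )` in kHz,
#'   applied to every neuron as independent Poisson streams.
#' @param duration Run length (ms); must be a multiple of `dt`.
#' @param dt Time step (ms); defaults to the network's grid.
#' @param seed Integer RNG seed.
#' @return A `spike_data` data frame with columns `neuron`, `time` (ms),
#'   sorted by time, and attributes `duration`, `dt`, `seed`, `n_neurons`.
#' @export
run_network <- function(spec, params, protocol = NULL, background = NULL,
                        duration, dt = spec$dt, seed = 1) {
  n_steps <- duration / dt
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop_invalid("duration must be a multiple of dt")
  n_steps <- as.integer(round(n_steps))
  if (length(spec$syn$delay_steps) && any(spec$syn$delay_steps < 1))
    stop_invalid("all delays must be at least one step")
  csr <- spec_csr(spec)

  mu_E <- rep(if (is.null(background)) 0 else background$lambda_E * dt,
              n_steps)
  mu_I <- rep(if (is.null(background)) 0 else background$lambda_I * dt,
              n_steps)

  res <- local_seed(seed, {
    ext <- list(step = integer(0), neuron = integer(0), inh = integer(0))
    if (!is.null(protocol)) {
      st <- stimulus_times(protocol, duration)
      st <- st[st < duration]
      if (!is.null(protocol$ramp) && length(st) >= 1) {
        # balanced Poisson transient, stepped down at the first four stimuli
        edges <- c(0, st[seq_len(min(4, length(st)))] , duration)
        level <- c(1, 1 - seq_len(min(4, length(st))) / 4)
        step_t <- (seq_len(n_steps) - 1) * dt
        fac <- level[findInterval(step_t, edges[-1]) + 1]
        fac[is.na(fac)] <- 0
        mu_E <- mu_E + protocol$ramp[1] * dt * fac
        mu_I <- mu_I + protocol$ramp[2] * dt * fac
      }
      ps <- protocol$packet_size %||% spec$n_E
      targets <- spec$pools_E[protocol$target_pool, ]
      if (!is.null(spec$pools_I))
        targets <- c(targets, spec$pools_I[protocol$target_pool, ])
      tb <- spec$delays$tau_B_range
      for (t0 in st) {
        src <- rnorm(ps, t0, protocol$packet_sigma)
        arr <- rep(src, times = length(targets)) +
          runif(ps * length(targets), tb[1], tb[2])
        stp <- time_to_step(arr, dt)
        keep <- stp >= 0 & stp < n_steps
        ext$step <- c(ext$step, stp[keep])
        ext$neuron <- c(ext$neuron, rep(targets, each = ps)[keep] - 1L)
      }
      ext$inh <- rep(0L, length(ext$step))
      ord <- order(ext$step)
      ext <- lapply(ext, `[`, ord)
    }
    engine_run(spec$n_neurons, csr$ptr, csr$post, csr$delay, csr$inh,
               n_steps, dt, mu_E, mu_I,
               ext$step, ext$neuron, ext$inh,
               engine_par(params, dt), FALSE, 0L)
  })
  structure(data.frame(neuron = res$neuron + 1L, time = (res$step + 1) * dt),
            duration = duration, dt = dt, seed = seed,
            n_neurons = spec$n_neurons, n_deliveries = res$n_deliveries,
            class = c("spike_data", "data.frame"))
}

#' Characterize pulse-packet propagation on a control chain
#'
#' Builds a feedforward control chain, bathes every neuron in balanced
#' Poisson background (`lambda_I = gamma * lambda_E`), lets the background
#' run for a 100 ms warm-up, then injects a wave-initiating packet into the
#' third pool and measures, over repeated trials:
#' survival probability `P_S` (a spike packet detected in the last pool),
#' participation probability `p_f` (packet size in the last pool divided by
#' `n_E`, averaged over surviving trials), and the mean pool-to-pool
#' propagation time `T` (time between the packets `measure_span` pools
#' before the end and at the end, divided by `measure_span`).
#'
#' @param n_E Pool size.
#' @param lambda_E Excitatory background rate (kHz).
#' @param gamma Inhibitory/excitatory background rate ratio.
#' @param params A [neuron_params()].
#' @param trials Number of trials.
#' @param delays A [delay_model()].
#' @param seed Integer seed (chain realization and trials derive from it).
#' @param n_pools Chain length in pools (reference protocol: 100, giving
#'   survival over `L = n_pools - 2` = 98 pools).
#' @param dt Time step (ms).
#' @param warmup Background-only period before the stimulus (ms).
#' @param detection A [detection_params()]; default uses `n_E`.
#' @param measure_span Pools spanned by the propagation-time measurement.
#' @return List with `P_S`, `p_f`, `T`, `trials`, `L`, and a per-trial
#'   data frame `detail`.
#' @export
characterize_propagation <- function(n_E, lambda_E, gamma = 0.25, params,
                                     trials = 100, delays = delay_model(),
                                     seed = 1, n_pools = 100, dt = 0.1,
                                     warmup = 100, detection = NULL,
                                     measure_span = 10) {
  if (trials < 1) stop_invalid("need at least one trial")
  if (is.null(detection)) detection <- detection_params(n_E)
  chain <- build_control_chain(n_E, n_pools, delays, dt,
                               seed = derive_seed(seed, 0))
  duration <- warmup + ceiling((n_pools - 3) * 6 + 20)
  proto <- stimulus_protocol(target_pool = 3, period = 2 * duration,
                             start = warmup, packet_size = n_E)
  k_last <- n_pools
  k_mid <- max(3L, n_pools - as.integer(measure_span))
  span <- k_last - k_mid
  pool_times <- function(spikes, k) {
    lo <- (k - 1L) * n_E
    sort(spikes$time[spikes$neuron > lo & spikes$neuron <= lo + n_E])
  }
  detail <- lapply(seq_len(trials), function(tr) {
    sp <- run_network(chain, params, proto,
                      background = list(lambda_E = lambda_E,
                                        lambda_I = gamma * lambda_E),
                      duration = duration, dt = dt,
                      seed = derive_seed(seed, tr))
    p_last <- detect_packets(pool_times(sp, k_last), detection)
    p_last <- p_last[p_last$time > warmup, , drop = FALSE]
    p_mid <- detect_packets(pool_times(sp, k_mid), detection)
    p_mid <- p_mid[p_mid$time > warmup, , drop = FALSE]
    data.frame(survived = nrow(p_last) > 0,
               size_last = if (nrow(p_last)) p_last$size[1] else NA_real_,
               t_last = if (nrow(p_last)) p_last$time[1] else NA_real_,
               t_mid = if (nrow(p_mid)) p_mid$time[1] else NA_real_)
  })
  detail <- do.call(rbind, detail)
  surv <- detail$survived
  ok_T <- surv & !is.na(detail$t_mid)
  list(P_S = mean(surv),
       p_f = if (any(surv)) mean(detail$size_last[surv]) / n_E else NA_real_,
       T = if (any(ok_T))
         mean((detail$t_last[ok_T] - detail$t_mid[ok_T]) / span)
       else NA_real_,
       trials = trials, L = as.integer(n_pools) - 2L,
       n_E = n_E, lambda_E = lambda_E,
       gamma = gamma, detail = detail)
}

#' Propagation table over a (pool size, background rate) grid
#'
#' Runs [characterize_propagation()] for every cell of the grid. The
#' reference protocol uses pool sizes 20, 24, ..., 220 and rates 1..300 kHz
#' with 100 trials over 100-pool chains; any coarser grid may be supplied.
#'
#' @param n_E_grid,lambda_E_grid Ascending grids.
#' @param gamma Background rate ratio.
#' @param params A [neuron_params()].
#' @param trials Trials per cell.
#' @param delays A [delay_model()].
#' @param seed Master seed; each cell derives its own stream.
#' @param n_pools Chain length per cell.
#' @param dt Time step (ms).
#' @return A `prop_table`: matrices `P_S`, `p_f`, `T` with rows indexed by
#'   `n_E` and columns by `lambda_E`; `p_f` and `T` are `NA` where no trial
#'   survived.
#' @export
build_propagation_table <- function(n_E_grid, lambda_E_grid, gamma = 0.25,
                                    params = neuron_params(), trials = 100,
                                    delays = delay_model(), seed = 1,
                                    n_pools = 100, dt = 0.1) {
  if (is.unsorted(n_E_grid, strictly = TRUE) ||
      is.unsorted(lambda_E_grid, strictly = TRUE))
    stop_invalid("grids must be strictly ascending")
  dims <- c(length(n_E_grid), length(lambda_E_grid))
  P_S <- p_f <- TT <- matrix(NA_real_, dims[1], dims[2])
  for (i in seq_len(dims[1])) {
    for (j in seq_len(dims[2])) {
      r <- characterize_propagation(n_E_grid[i], lambda_E_grid[j], gamma,
                                    params, trials, delays,
                                    seed = derive_seed(seed, i, j),
                                    n_pools = n_pools, dt = dt)
      P_S[i, j] <- r$P_S; p_f[i, j] <- r$p_f; TT[i, j] <- r$T
    }
  }
  prop_table(n_E_grid, lambda_E_grid, P_S, p_f, TT, trials = trials,
             gamma = gamma, n_pools = n_pools)
}

#' Construct a propagation table from matrices
#'
#' @param n_E,lambda_E Ascending axis grids.
#' @param P_S,p_f,T Matrices (`length(n_E)` x `length(lambda_E)`): survival
#'   probability, participation probability, pool-to-pool time (ms).
#' @param trials Trials per cell.
#' @param gamma Background rate ratio.
#' @param n_pools Chain length used; survival span is `L = n_pools - 2`.
#' @return An object of class `prop_table`.
#' @export
prop_table <- function(n_E, lambda_E, P_S, p_f, T, trials = NA,
                       gamma = 0.25, n_pools = 100) {
  stopifnot(all(dim(P_S) == c(length(n_E), length(lambda_E))),
            all(dim(p_f) == dim(P_S)), all(dim(T) == dim(P_S)))
  if (any(P_S < 0 | P_S > 1, na.rm = TRUE))
    stop_invalid("P_S must lie in [0, 1]")
  if (any(T <= 0, na.rm = TRUE)) stop_invalid("T must be positive")
  structure(list(n_E = n_E, lambda_E = lambda_E, P_S = P_S, p_f = p_f,
                 T = T, trials = trials, gamma = gamma,
                 n_pools = n_pools, L = n_pools - 2L),
            class = "prop_table")
}

#' @export
print.prop_table <- function(x, ...) {
  cat(sprintf("<prop_table: %d pool sizes x %d rates, %s trials/cell, L=%d>\n",
              length(x$n_E), length(x$lambda_E),
              paste(unique(x$trials), collapse = "/"), x$L))
  invisible(x)
}

# Row interpolators (piecewise linear in lambda_E) for a pool size present
# in the table grid.
prop_row <- function(table, n_E, what = c("P_S", "p_f", "T")) {
  what <- match.arg(what)
  i <- match(n_E, table$n_E)
  if (is.na(i)) stop_invalid("n_E = %g not a row of the table", n_E)
  y <- table[[what]][i, ]
  ok <- !is.na(y)
  if (sum(ok) < 1) stop_invalid("row n_E = %g has no defined values", n_E)
  x <- table$lambda_E[ok]; y <- y[ok]
  function(lambda) {
    if (length(x) == 1) return(rep(y, length(lambda)))
    approx(x, y, xout = pmin(pmax(lambda, min(x)), max(x)), rule = 2)$y
  }
}

#' Write / read a propagation table (long-format TSV)
#'
#' @param table A [prop_table()].
#' @param path File path.
#' @return `read_prop_table` returns the `prop_table`.
#' @export
write_prop_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# prop_table gamma=%g n_pools=%d trials=%s",
                     table$gamma, table$n_pools,
                     paste(unique(table$trials), collapse = ",")), con)
  df <- expand.grid(n_E = table$n_E, lambda_E = table$lambda_E)
  df$P_S <- as.vector(table$P_S)
  df$p_f <- as.vector(table$p_f)
  df$T <- as.vector(table$T)
  writeLines(paste(names(df), collapse = "\t"), con)
  write.table(df, con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_prop_table
#' @export
read_prop_table <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")][1]
  getv <- function(key, default) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[0-9.eE+-]+"), hdr))
    if (length(m)) as.numeric(sub(paste0(key, "="), "", m)) else default
  }
  df <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                   sep = "\t")
  n_E <- sort(unique(df$n_E)); lam <- sort(unique(df$lambda_E))
  shape <- function(col) {
    m <- matrix(NA_real_, length(n_E), length(lam))
    m[cbind(match(df$n_E, n_E), match(df$lambda_E, lam))] <- col
    m
  }
  prop_table(n_E, lam, shape(df$P_S), shape(df$p_f), shape(df$T),
             trials = getv("trials", NA), gamma = getv("gamma", 0.25),
             n_pools = as.integer(getv("n_pools", 100)))
}

#' Write / read spike data as whitespace-separated text
#'
#' One spike per line (`neuron_id time_ms`), ascending in time, with a JSON
#' metadata sidecar (`<path>.meta.json`).
#'
#' @param spikes A `spike_data` from [run_network()].
#' @param path File path.
#' @return `read_spikes` returns the `spike_data`.
#' @export
write_spikes <- function(spikes, path) {
  write.table(data.frame(spikes$neuron, spikes$time), path,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  meta <- list(duration = attr(spikes, "duration"), dt = attr(spikes, "dt"),
               seed = attr(spikes, "seed"),
               n_neurons = attr(spikes, "n_neurons"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  df <- read.table(path, col.names = c("neuron", "time"))
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  structure(df, duration = meta$duration, dt = meta$dt, seed = meta$seed,
            n_neurons = meta$n_neurons,
            class = c("spike_data", "data.frame"))
}
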