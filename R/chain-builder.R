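#' Embedding geometry configuration
#'
#' Describes one combinatorial-capacity embedding: every excitatory synapse
#' belongs to a pool-to-pool link, so the number of pools is fixed by the
#' connectivity and pool size, `p = round(N_E * C_E / n_E^2)`, and the
#' embedding level is `alpha = p / N_E = C_E / n_E^2`.
#'
#' @param C_E Excitatory inputs per neuron.
#' @param n_E Excitatory pool size.
#' @param gamma Ratio `N_I / N_E = n_I / n_E` (inhibitory fractions).
#' @param gamma_prime Ratio of inhibitory to excitatory in-degree per neuron.
#' @param N_E Excitatory population size; default `10 * C_E`, which gives a
#'   10 percent pairwise connection probability.
#' @param seed Integer seed used for the network realization.
#' @return An object of class `embedding_config`.
#' @export
#' @examples
#' derive_counts(embedding_config(C_E = 8000, n_E = 72))
embedding_config <- function(C_E, n_E, gamma = 0.25, gamma_prime = 0.25,
                             N_E = 10 * C_E, seed = 1) {
  structure(list(C_E = C_E, n_E = as.integer(n_E), gamma = gamma,
                 gamma_prime = gamma_prime, N_E = as.integer(N_E),
                 seed = as.integer(seed)),
            class = "embedding_config")
}

#' Two-component transmission-delay model
#'
#' Each excitatory synapse's delay is the sum of an inter-link component
#' `tau_A`, drawn once per pool-to-pool link (default uniform on
#' \[0.5, 4.5) ms), and an intra-link component `tau_B`, drawn per synapse
#' (default uniform on \[0, 0.5) ms). Inhibitory synapses draw both
#' components independently per synapse. The narrow intra-link spread is what
#' creates the integration window that lets background input modulate wave
#' propagation.
#'
#' @param tau_A_range,tau_B_range Numeric length-2 half-open intervals (ms).
#' @return An object of class `delay_model`.
#' @export
delay_model <- function(tau_A_range = c(0.5, 4.5),
                        tau_B_range = c(0, 0.5)) {
  stopifnot(length(tau_A_range) == 2, length(tau_B_range) == 2,
            tau_A_range[1] >= 0, tau_B_range[1] >= 0,
            diff(tau_A_range) >= 0, diff(tau_B_range) >= 0)
  structure(list(tau_A_range = tau_A_range, tau_B_range = tau_B_range),
            class = "delay_model")
}

#' Derived combinatorial counts of an embedding
#'
#' @param config An [embedding_config()].
#' @return List with `p` (number of pools), `alpha` (embedding level,
#'   pools per excitatory neuron), `N_I`, `n_I`, `C_I`.
#' @export
#' @examples
#' derive_counts(embedding_config(8000, 72))$p   # 123457
derive_counts <- function(config) {
  if (config$n_E < 1) stop_invalid("n_E must be >= 1")
  if (config$C_E < config$n_E) stop_invalid("need C_E >= n_E")
  p <- as.integer(round(config$N_E * config$C_E / config$n_E^2))
  if (p < 1) stop_invalid("embedding has p < 1 pool")
  n_I <- config$gamma * config$n_E
  if (abs(n_I - round(n_I)) > 1e-9)
    stop_invalid("gamma * n_E = %g is not an integer pool size", n_I)
  N_I <- config$gamma * config$N_E
  if (abs(N_I - round(N_I)) > 1e-9)
    stop_invalid("gamma * N_E = %g is not an integer population size", N_I)
  list(p = p, alpha = config$C_E / config$n_E^2,
       N_I = as.integer(round(N_I)), n_I = as.integer(round(n_I)),
       C_I = config$gamma_prime * config$C_E)
}

# Balanced random pool assignment: p pools of n members from N ids, every id
# used floor(p*n/N) or ceil(p*n/N) times, members distinct within each pool.
# Realized by shuffling the replicated id multiset and repairing within-pool
# duplicates by swaps across pools.
assign_pools <- function(N, p, n) {
  total <- p * n
  base <- total %/% N
  extra <- total %% N
  counts <- rep(base, N)
  if (extra > 0) counts[sample.int(N, extra)] <- base + 1L
  ids <- sample(rep.int(seq_len(N), counts))
  pools <- matrix(ids, nrow = p, ncol = n, byrow = TRUE)
  bad <- which(apply(pools, 1L, anyDuplicated) > 0)
  guard <- 0L
  while (length(bad) > 0) {
    guard <- guard + 1L
    if (guard > 1000L) stop_invalid("pool assignment repair did not converge")
    for (r in bad) {
      row <- pools[r, ]
      for (j in which(duplicated(row))) {
        repeat {
          r2 <- sample.int(p, 1L)
          if (r2 == r) next
          j2 <- sample.int(n, 1L)
          v <- pools[r2, j2]
          if (!(v %in% pools[r, ]) && !(pools[r, j] %in% pools[r2, -j2])) {
            pools[r2, j2] <- pools[r, j]
            pools[r, j] <- v
            row <- pools[r, ]
            break
          }
        }
      }
    }
    bad <- which(apply(pools, 1L, anyDuplicated) > 0)
  }
  pools
}

#' Build one realization of the combinatorial embedding
#'
#' Assigns excitatory and inhibitory (shadow) pools with balanced membership
#' counts, orders all E-pools into a single cyclic chain (ring), wires each
#' E-pool all-to-all to the next E-pool and next I-pool with two-component
#' delays, and gives every neuron a random inhibitory in-degree equal to
#' `round(gamma_prime * excitatory in-degree)`. Excitatory neurons are ids
#' `1..N_E`, inhibitory `N_E+1..N_E+N_I`. Deterministic for a fixed config
#' seed.
#'
#' @param config An [embedding_config()].
#' @param delays A [delay_model()].
#' @param dt Time step (ms) to whose grid delays are rounded (half-up,
#'   minimum one step).
#' @return A `network_spec`: pool tables, synapse arrays (`pre`, `post`,
#'   `inh`, `delay_steps`) and in-degree bookkeeping.
#' @export
build_embedding <- function(config, delays = delay_model(), dt = 0.1) {
  cts <- derive_counts(config)
  if (config$n_E > config$N_E) stop_invalid("n_E exceeds N_E")
  N_E <- config$N_E; N_I <- cts$N_I; p <- cts$p
  n_E <- config$n_E; n_I <- cts$n_I
  n_neurons <- N_E + N_I
  local_seed(config$seed, {
    pools_E <- assign_pools(N_E, p, n_E)
    pools_I <- assign_pools(N_I, p, n_I) + N_E

    m <- n_E * (n_E + n_I)          # synapses per link
    nxt <- c(seq_len(p)[-1], 1L)    # ring successor
    pre <- integer(p * m); post <- integer(p * m); dl <- numeric(p * m)
    tau_A <- runif(p, delays$tau_A_range[1], delays$tau_A_range[2])
    for (mu in seq_len(p)) {
      idx <- ((mu - 1L) * m + 1L):(mu * m)
      targets <- c(pools_E[nxt[mu], ], pools_I[nxt[mu], ])
      pre[idx] <- rep.int(pools_E[mu, ], n_E + n_I)
      post[idx] <- rep(targets, each = n_E)
      dl[idx] <- tau_A[mu] +
        runif(m, delays$tau_B_range[1], delays$tau_B_range[2])
    }

    exc_indeg <- tabulate(post, nbins = n_neurons)
    inh_indeg <- as.integer(round(config$gamma_prime * exc_indeg))
    tot_inh <- sum(inh_indeg)
    ipre <- integer(tot_inh); ipost <- integer(tot_inh)
    off <- 0L
    for (i in seq_len(n_neurons)) {
      k <- inh_indeg[i]
      if (k > 0L) {
        ipre[(off + 1L):(off + k)] <- N_E + sample.int(N_I, k)
        ipost[(off + 1L):(off + k)] <- i
        off <- off + k
      }
    }
    idl <- runif(tot_inh, delays$tau_A_range[1], delays$tau_A_range[2]) +
      runif(tot_inh, delays$tau_B_range[1], delays$tau_B_range[2])

    syn <- list(pre = c(pre, ipre), post = c(post, ipost),
                inh = c(rep(0L, length(pre)), rep(1L, tot_inh)),
                delay_steps = delay_to_steps(c(dl, idl), dt))
    structure(list(kind = "embedding", N_E = N_E, N_I = N_I,
                   n_neurons = n_neurons, p = p, n_E = n_E, n_I = n_I,
                   pools_E = pools_E, pools_I = pools_I, syn = syn,
                   exc_indeg = exc_indeg, inh_indeg = inh_indeg,
                   dt = dt, config = config, delays = delays,
                   seed = config$seed),
              class = "network_spec")
  })
}

#' Build a non-embedded control chain
#'
#' A feedforward chain of disjoint pools used to characterize pulse-packet
#' propagation under external Poisson background: no neuron appears in two
#' pools, pool k projects all-to-all to pool k+1, and there are no inhibitory
#' neurons (background inhibition is supplied externally). Delays use the
#' same two-component model as the embedding (per-link `tau_A` plus
#' per-synapse `tau_B`), so the measured pool-to-pool propagation time
#' includes the full transmission delay.
#'
#' @param n_E Pool size.
#' @param n_pools Number of pools (>= 2).
#' @param delays A [delay_model()].
#' @param dt Time step (ms).
#' @param seed Integer seed.
#' @return A `network_spec` with `kind = "control"`.
#' @export
build_control_chain <- function(n_E, n_pools, delays = delay_model(),
                                dt = 0.1, seed = 1) {
  if (n_pools < 2) stop_invalid("need n_pools >= 2")
  n_E <- as.integer(n_E)
  n_pools <- as.integer(n_pools)
  n_neurons <- n_pools * n_E
  pools_E <- matrix(seq_len(n_neurons), nrow = n_pools, ncol = n_E,
                    byrow = TRUE)
  m <- n_E * n_E
  local_seed(seed, {
    tau_A <- runif(n_pools - 1L, delays$tau_A_range[1], delays$tau_A_range[2])
    pre <- integer((n_pools - 1L) * m)
    post <- integer((n_pools - 1L) * m)
    dl <- numeric((n_pools - 1L) * m)
    for (k in seq_len(n_pools - 1L)) {
      idx <- ((k - 1L) * m + 1L):(k * m)
      pre[idx] <- rep.int(pools_E[k, ], n_E)
      post[idx] <- rep(pools_E[k + 1L, ], each = n_E)
      dl[idx] <- tau_A[k] +
        runif(m, delays$tau_B_range[1], delays$tau_B_range[2])
    }
    syn <- list(pre = pre, post = post, inh = rep(0L, length(pre)),
                delay_steps = delay_to_steps(dl, dt))
    structure(list(kind = "control", N_E = n_neurons, N_I = 0L,
                   n_neurons = n_neurons, p = n_pools, n_E = n_E, n_I = 0L,
                   pools_E = pools_E, pools_I = NULL, syn = syn,
                   exc_indeg = tabulate(post, nbins = n_neurons),
                   inh_indeg = rep(0L, n_neurons),
                   dt = dt, config = NULL, delays = delays, seed = seed),
              class = "network_spec")
  })
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec: %s>\n", x$kind))
  cat(sprintf("  %d neurons (%d E + %d I), %d pools of n_E=%d (n_I=%d)\n",
              x$n_neurons, x$N_E, x$N_I, x$p, x$n_E, x$n_I))
  cat(sprintf("  %d synapses (%d inhibitory), dt=%g ms, seed=%d\n",
              length(x$syn$pre), sum(x$syn$inh), x$dt, x$seed))
  invisible(x)
}

# CSR grouping of synapses by presynaptic neuron for O(out-degree) delivery.
spec_csr <- function(spec) {
  ord <- order(spec$syn$pre)
  deg <- tabulate(spec$syn$pre, nbins = spec$n_neurons)
  list(ptr = c(0L, cumsum(deg)),
       post = spec$syn$post[ord] - 1L,
       delay = spec$syn$delay_steps[ord],
       inh = spec$syn$inh[ord])
}

#' Serialize a network spec to a directory of text tables
#'
#' Writes `synapses.tsv` (pre, post, inh, delay_steps), `pools_E.tsv`,
#' optionally `pools_I.tsv`, and `meta.json` (geometry, dt, seed, config).
#' The round trip through [read_network_spec()] is lossless.
#'
#' @param spec A `network_spec`.
#' @param dir Output directory (created if missing).
#' @return `read_network_spec` returns the `network_spec`.
#' @export
write_network_spec <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(as.data.frame(spec$syn), file.path(dir, "synapses.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(spec$pools_E, file.path(dir, "pools_E.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (!is.null(spec$pools_I))
    write.table(spec$pools_I, file.path(dir, "pools_I.tsv"), sep = "\t",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  meta <- spec[c("kind", "N_E", "N_I", "n_neurons", "p", "n_E", "n_I",
                 "dt", "seed")]
  meta$config <- if (!is.null(spec$config)) unclass(spec$config)
  meta$delays <- unclass(spec$delays)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  syn <- read.table(file.path(dir, "synapses.tsv"), header = TRUE, sep = "\t")
  pe <- as.matrix(read.table(file.path(dir, "pools_E.tsv"), sep = "\t"))
  dimnames(pe) <- NULL
  pi_path <- file.path(dir, "pools_I.tsv")
  pi_ <- if (file.exists(pi_path)) {
    x <- as.matrix(read.table(pi_path, sep = "\t")); dimnames(x) <- NULL; x
  }
  syn <- list(pre = as.integer(syn$pre), post = as.integer(syn$post),
              inh = as.integer(syn$inh),
              delay_steps = as.integer(syn$delay_steps))
  cfg <- if (!is.null(meta$config))
    do.call(embedding_config, meta$config[c("C_E", "n_E", "gamma",
                                            "gamma_prime", "N_E", "seed")])
  structure(list(kind = meta$kind, N_E = as.integer(meta$N_E),
                 N_I = as.integer(meta$N_I),
                 n_neurons = as.integer(meta$n_neurons),
                 p = as.integer(meta$p), n_E = as.integer(meta$n_E),
                 n_I = as.integer(meta$n_I),
                 pools_E = pe, pools_I = pi_, syn = syn,
                 exc_indeg = tabulate(syn$post[syn$inh == 0L],
                                      nbins = meta$n_neurons),
                 inh_indeg = tabulate(syn$post[syn$inh == 1L],
                                      nbins = meta$n_neurons),
                 dt = meta$dt, config = cfg,
                 delays = delay_model(unlist(meta$delays$tau_A_range),
                                      unlist(meta$delays$tau_B_range)),
                 seed = as.integer(meta$seed)),
            class = "network_spec")
}
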