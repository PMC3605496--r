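#' Spike-packet detection parameters
#'
#' Detection slides a window of width `T_w` anchored at every spike of the
#' pooled raster, classifies windows with more than `n_theta` spikes as
#' suprathreshold, keeps maximal runs of at least `min_run` consecutive
#' suprathreshold windows, and reduces each run to a single packet. The
#' method assumes the spike rate outside packets is low, so the default
#' count threshold sits at about 40 percent of the pool size. Packets in
#' consecutive pools are linked into waves when their time gap falls inside
#' `link_window`.
#'
#' @param n_E Pool size; sets the default count threshold.
#' @param T_w Window width (ms).
#' @param n_theta Count threshold; default `round(0.4 * n_E)`.
#' @param min_run Minimal suprathreshold run length.
#' @param link_window Allowed packet-to-packet gap (ms) for wave linking.
#' @param rate_bin Bin width (ms) for the time-resolved wave-spike rate.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(n_E, T_w = 3, n_theta = round(0.4 * n_E),
                             min_run = 6, link_window = c(0.5, 6),
                             rate_bin = 20) {
  if (T_w <= 0) stop_invalid("T_w must be > 0")
  if (n_theta <= 0 || n_theta >= n_E)
    stop_invalid("need 0 < n_theta < n_E")
  if (min_run < 1) stop_invalid("min_run must be >= 1")
  structure(list(n_E = as.integer(n_E), T_w = T_w,
                 n_theta = as.integer(n_theta),
                 min_run = as.integer(min_run), link_window = link_window,
                 rate_bin = rate_bin),
            class = "detection_params")
}

#' Detect spike packets in one pool's pooled spike train
#'
#' To every spike time `t_k` a window `[t_k, t_k + T_w)` is applied; its
#' spike count classifies the window as suprathreshold (`count > n_theta`).
#' Each maximal run of at least `min_run` consecutive suprathreshold windows
#' yields one packet: among the run's windows with maximal count, the
#' `floor(m/2)`'th (0-based) is selected, and the packet time is the median
#' of its spike times (even-sized lists take the lower middle element).
#'
#' @param times Sorted spike times (ms) of all neurons in the pool.
#' @param params A [detection_params()].
#' @return Data frame with one row per packet: `time` (median, ms), `size`
#'   (spike count), `t_lo`, `t_hi` (window bounds of the selected sublist).
#'   Empty input gives zero rows.
#' @export
detect_packets <- function(times, params) {
  empty <- data.frame(time = numeric(0), size = numeric(0),
                      t_lo = numeric(0), t_hi = numeric(0))
  n <- length(times)
  if (n == 0) return(empty)
  if (is.unsorted(times)) stop_invalid("spike times must be sorted")
  # count of spikes in [t_k, t_k + T_w) for each anchor spike k
  n_lt <- function(x) findInterval(x, times, left.open = TRUE)
  cnt <- n_lt(times + params$T_w) - n_lt(times)
  supra <- cnt > params$n_theta
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= params$min_run
  if (!any(keep)) return(empty)
  out <- lapply(which(keep), function(i) {
    idx <- starts[i]:ends[i]
    lmax <- idx[cnt[idx] == max(cnt[idx])]
    sel <- lmax[floor(length(lmax) / 2) + 1L]
    c(lo = times[sel], hi = times[sel] + params$T_w)
  })
  out <- do.call(rbind, out)
  # selected windows of consecutive runs can overlap when two packets pass
  # the pool less than T_w apart; boundary spikes go to the earlier packet
  if (nrow(out) > 1)
    out[-1, "lo"] <- pmax(out[-1, "lo"], out[-nrow(out), "hi"])
  res <- lapply(seq_len(nrow(out)), function(i) {
    members <- times[times >= out[i, "lo"] & times < out[i, "hi"]]
    m <- length(members)
    if (m == 0) return(NULL)
    data.frame(time = sort(members)[(m + 1L) %/% 2L], size = m,
               t_lo = out[i, "lo"], t_hi = out[i, "hi"])
  })
  res <- do.call(rbind, res)
  if (is.null(res)) empty else res
}

#' Detect packets in every pool of a network's raster
#'
#' @param spikes A `spike_data` from [run_network()].
#' @param spec The `network_spec` that produced it (supplies the pool
#'   membership; a neuron appearing in several pools contributes its spikes
#'   to each of them).
#' @param params A [detection_params()].
#' @return Data frame with columns `pool`, `time`, `size`, `t_lo`, `t_hi`.
#' @export
detect_packets_by_pool <- function(spikes, spec, params) {
  p <- nrow(spec$pools_E)
  # map each spike to every pool its neuron belongs to (vectorized CSR walk)
  memb_pool <- rep(seq_len(p), each = ncol(spec$pools_E))
  memb_id <- as.vector(t(spec$pools_E))
  ord <- order(memb_id)
  memb_pool <- memb_pool[ord]
  ptr <- c(0L, cumsum(tabulate(memb_id[ord], nbins = spec$n_neurons)))
  reps <- diff(ptr)[spikes$neuron]
  idx <- rep.int(ptr[spikes$neuron], reps) + sequence(reps)
  pool_of <- memb_pool[idx]
  time_rep <- rep.int(spikes$time, reps)
  o2 <- order(pool_of, time_rep)
  out <- split(time_rep[o2], pool_of[o2])
  pools <- as.integer(names(out))
  res <- lapply(seq_along(out), function(i) {
    pk <- detect_packets(unname(out[[i]]), params)
    if (nrow(pk)) pk$pool <- pools[i]
    pk
  })
  res <- do.call(rbind, res[vapply(res, nrow, 1L) > 0])
  if (is.null(res))
    return(data.frame(pool = integer(0), time = numeric(0),
                      size = numeric(0), t_lo = numeric(0),
                      t_hi = numeric(0)))
  res[order(res$time), c("pool", "time", "size", "t_lo", "t_hi")]
}

#' Link packets on consecutive pools into synfire waves
#'
#' Greedy chaining: packets are visited in time order; an unassigned packet
#' opens a new wave, which is extended by repeatedly taking, in the
#' successor pool, the earliest unassigned packet whose time gap lies in
#' `link_window` (taking the earlier candidate resolves wave lapping). Each
#' packet belongs to at most one wave.
#'
#' @param packets Data frame with columns `pool`, `time`, `size` (e.g. from
#'   [detect_packets_by_pool()]).
#' @param params A [detection_params()].
#' @param n_pools Number of pools in the chain.
#' @param ring If `TRUE` the successor of the last pool is pool 1.
#' @return A `wave_set`: `packets` (input plus a `wave` id column) and
#'   `waves` (per-wave `n_packets`, `t_first`, `t_last`, `mean_gap`).
#' @export
link_waves <- function(packets, params, n_pools, ring = FALSE) {
  np <- nrow(packets)
  wave <- rep(NA_integer_, np)
  if (np > 0) {
    ord <- order(packets$time)
    by_pool <- split(ord, packets$pool[ord])  # time-sorted indices per pool
    lw <- params$link_window
    succ <- function(k) if (ring) (k %% n_pools) + 1L else k + 1L
    wid <- 0L
    for (i in ord) {
      if (!is.na(wave[i])) next
      wid <- wid + 1L
      wave[i] <- wid
      cur <- i
      repeat {
        nxt_pool <- succ(packets$pool[cur])
        cand <- by_pool[[as.character(nxt_pool)]]
        if (is.null(cand)) break
        gaps <- packets$time[cand] - packets$time[cur]
        ok <- which(is.na(wave[cand]) & gaps >= lw[1] & gaps <= lw[2])
        if (length(ok) == 0) break
        cur <- cand[ok[1]]
        wave[cur] <- wid
      }
    }
  }
  packets$wave <- wave
  waves <- if (np > 0 && any(!is.na(wave))) {
    sp <- split(seq_len(np), wave)
    do.call(rbind, lapply(names(sp), function(w) {
      idx <- sp[[w]]
      tt <- sort(packets$time[idx])
      data.frame(wave = as.integer(w), n_packets = length(idx),
                 t_first = tt[1], t_last = tt[length(tt)],
                 mean_gap = if (length(tt) > 1) mean(diff(tt)) else NA_real_)
    }))
  } else {
    data.frame(wave = integer(0), n_packets = integer(0),
               t_first = numeric(0), t_last = numeric(0),
               mean_gap = numeric(0))
  }
  structure(list(packets = packets, waves = waves), class = "wave_set")
}

#' Equilibrium statistics of a driven embedding run
#'
#' Computes the time-resolved wave count `h(t)` (a wave counts as alive from
#' its first packet time until its last packet time plus one link interval),
#' finds the equilibration time `t_start = max(1000 ms, t_mean)` where
#' `t_mean` is when `h(t)` first exceeds its mean over \[1000 ms, end\], and
#' reports means over \[`t_start`, end\]: the overall rate `nu`, the rate of
#' spikes belonging to packets `nu_W`, and the mean and maximum wave count.
#'
#' @param spikes A `spike_data`.
#' @param waves A `wave_set` from [link_waves()].
#' @param total_duration Run length (ms); >= 2000.
#' @param params A [detection_params()] (supplies `rate_bin`).
#' @param dt Grid step for `h(t)` (ms).
#' @return List with `nu_Hz`, `nu_W_Hz`, `mean_h`, `max_h`, `t_start`, and a
#'   `series` data frame (`t`, `h`) plus `rates` (`t`, `nu_W_Hz`) binned at
#'   `rate_bin`.
#' @export
equilibrium_statistics <- function(spikes, waves,
                                   total_duration = attr(spikes, "duration"),
                                   params, dt = attr(spikes, "dt")) {
  if (is.null(total_duration) || total_duration < 2000)
    stop_invalid("need a run of at least 2000 ms")
  N <- attr(spikes, "n_neurons")
  grid <- seq(dt, total_duration, by = dt)
  wv <- waves$waves
  if (nrow(wv) == 0) {
    h <- rep(0, length(grid))
    t_start <- 1000
  } else {
    gap <- ifelse(is.na(wv$mean_gap), 3, wv$mean_gap)
    t_on <- wv$t_first
    t_off <- pmin(wv$t_last + gap, total_duration)
    h <- findInterval(grid, sort(t_on)) - findInterval(grid, sort(t_off))
    base <- grid >= 1000
    h_mean_ref <- mean(h[base])
    above <- which(h > h_mean_ref)
    t_mean <- if (length(above)) grid[above[1]] else 1000
    t_start <- max(1000, t_mean)
  }
  win <- grid > t_start
  win_len <- (total_duration - t_start) / 1000  # s
  nu <- sum(spikes$time > t_start) / (N * win_len)
  pk <- waves$packets
  in_win <- !is.na(pk$wave) & pk$time > t_start
  nu_W <- sum(pk$size[in_win]) / (N * win_len)
  bins <- seq(0, total_duration, by = params$rate_bin)
  bi <- findInterval(pk$time[!is.na(pk$wave)], bins, left.open = TRUE)
  nuW_t <- vapply(seq_len(length(bins) - 1), function(b)
    sum(pk$size[!is.na(pk$wave)][bi == b]), numeric(1)) /
    (N * params$rate_bin / 1000)
  list(nu_Hz = nu, nu_W_Hz = nu_W,
       mean_h = if (any(win)) mean(h[win]) else 0,
       max_h = if (any(win)) max(h[win]) else 0,
       t_start = t_start,
       series = data.frame(t = grid, h = h),
       rates = data.frame(t = bins[-1], nu_W_Hz = nuW_t))
}
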