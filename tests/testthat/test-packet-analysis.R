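test_that("packet detection follows the windowed-run definition", {
  det <- detection_params(100, n_theta = 40)
  expect_identical(nrow(detect_packets(numeric(0), det)), 0L)
  # planted packet: 80 spikes uniform in [50, 51] ms, sparse background
  set.seed(2)
  times <- sort(c(runif(80, 50, 51), 10, 400))
  pk <- detect_packets(times, det)
  expect_identical(nrow(pk), 1L)
  expect_gte(pk$time, 50)
  expect_lte(pk$time, 51)
  expect_gte(pk$size, 80)
  # constant subthreshold rate: every window below n_theta -> nothing
  sub <- sort(runif(300, 0, 1000))  # ~0.9 spikes per 3 ms window
  expect_identical(nrow(detect_packets(sub, det)), 0L)
  # a suprathreshold run shorter than min_run is rejected
  burst <- sort(c(runif(45, 70, 70.05), runif(3, 0, 1000)))
  det_strict <- detection_params(100, n_theta = 40, min_run = 60)
  expect_identical(nrow(detect_packets(burst, det_strict)), 0L)
  expect_error(detect_packets(c(3, 1), det), "sorted")
})

test_that("hand-executed window bookkeeping matches detect_packets", {
  # fixture small enough to trace by hand: windows anchored per spike,
  # counts over [t_k, t_k+3), threshold 4, runs >= 3
  times <- c(0, 10, 10.2, 10.4, 10.6, 10.8, 11.0, 11.2, 30)
  det <- detection_params(10, T_w = 3, n_theta = 4, min_run = 3)
  # anchors 2..5 have counts 7,6,5,... : counts via direct enumeration
  cnt <- vapply(times, function(t) sum(times >= t & times < t + 3),
                numeric(1))
  expect_equal(cnt, c(1, 7, 6, 5, 4, 3, 2, 1, 1))
  # suprathreshold anchors: counts > 4 -> anchors 2,3,4 (run length 3)
  pk <- detect_packets(times, det)
  expect_identical(nrow(pk), 1L)
  # L_max = the single anchor with count 7 -> packet is its window,
  # median of 7 spikes in [10, 13) is 10.6
  expect_equal(pk$size, 7)
  expect_equal(pk$time, 10.6)
})

test_that("even-sized packets take the lower-middle median", {
  det <- detection_params(10, T_w = 3, n_theta = 3, min_run = 3)
  times <- c(20.0, 20.2, 20.4, 20.6, 20.8, 21.0)
  pk <- detect_packets(times, det)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$size, 6)
  expect_equal(pk$time, 20.4)  # lower middle of an even-sized list
})

test_that("detection is invariant to time translation and neuron relabeling", {
  det <- detection_params(100, n_theta = 40)
  for (seed in 1:4) {
    fx <- make_fixture("raster_with_packets", seed = seed)
    pk <- detect_packets(fx$times, det)
    sh <- detect_packets(fx$times + 137.5, det)
    expect_equal(sh$time, pk$time + 137.5)
    expect_equal(sh$size, pk$size)
  }
})

test_that("recall and precision are 1 on planted-packet fixtures", {
  det <- detection_params(100, n_theta = 40)
  for (seed in 1:5) {
    fx <- make_fixture("raster_with_packets", seed = seed)
    pk <- detect_packets(fx$times, det)
    # recall: every planted packet recovered within the window width
    expect_true(all(vapply(fx$truth, function(t0)
      any(abs(pk$time - t0) <= det$T_w), logical(1))))
    # precision: every detection near a planted packet
    expect_true(all(vapply(pk$time, function(t0)
      any(abs(fx$truth - t0) <= det$T_w), logical(1))))
  }
})

test_that("wave linking chains packets within the gap window only", {
  det <- detection_params(100)
  pk <- data.frame(pool = 1:10, time = 100 + 2.5 * (0:9),
                   size = 80)
  wv <- link_waves(pk, det, n_pools = 10)
  expect_identical(nrow(wv$waves), 1L)
  expect_identical(wv$waves$n_packets, 10L)
  expect_equal(wv$waves$mean_gap, 2.5)
  # a 7 ms gap breaks the chain in two
  pk2 <- pk
  pk2$time[6:10] <- pk2$time[6:10] + 4.5   # gap 5->6 becomes 7 ms
  wv2 <- link_waves(pk2, det, n_pools = 10)
  expect_identical(nrow(wv2$waves), 2L)
  expect_equal(sort(wv2$waves$n_packets), c(5L, 5L))
  # lapping: two candidates in the successor pool -> the earlier one wins
  pk3 <- data.frame(pool = c(1, 2, 2), time = c(100, 102, 104),
                    size = 80)
  wv3 <- link_waves(pk3, det, n_pools = 3)
  expect_identical(wv3$packets$wave[2], wv3$packets$wave[1])
  expect_false(identical(wv3$packets$wave[3], wv3$packets$wave[1]))
})

test_that("equilibrium statistics handle empty and persistent wave sets", {
  det <- detection_params(100)
  sp <- structure(data.frame(neuron = integer(0), time = numeric(0)),
                  duration = 3000, dt = 0.1, n_neurons = 1000L,
                  class = c("spike_data", "data.frame"))
  empty <- link_waves(data.frame(pool = integer(0), time = numeric(0),
                                 size = numeric(0)), det, n_pools = 10)
  st <- equilibrium_statistics(sp, empty, params = det)
  expect_equal(st$mean_h, 0)
  expect_equal(st$max_h, 0)
  expect_equal(st$t_start, 1000)
  # one uninterrupted wave spanning the whole run
  pk <- data.frame(pool = rep(1:10, 100), time = sort(rep(1:1000, 1) * 3),
                   size = 50)[1:1000, ]
  pk$time <- seq(3, 3000, by = 3)
  pk$pool <- rep(1:10, 100)
  wv <- link_waves(pk, det, n_pools = 10, ring = TRUE)
  expect_identical(nrow(wv$waves), 1L)
  sp2 <- structure(data.frame(neuron = rep(1L, 1000),
                              time = pk$time),
                   duration = 3000, dt = 0.1, n_neurons = 1000L,
                   class = c("spike_data", "data.frame"))
  st2 <- equilibrium_statistics(sp2, wv, params = det)
  expect_equal(st2$max_h, 1)
  expect_gt(st2$mean_h, 0.95)
  expect_error(equilibrium_statistics(sp, empty, total_duration = 500,
                                      params = det), "2000")
})

test_that("every spike counted into the wave rate belongs to one packet", {
  run <- embedding_run()
  pk <- run$packets
  # packet windows within one pool never overlap, so membership is unique
  by_pool <- split(pk, pk$pool)
  overlaps <- vapply(by_pool, function(d) {
    if (nrow(d) < 2) return(FALSE)
    d <- d[order(d$t_lo), ]
    any(d$t_lo[-1] < d$t_hi[-nrow(d)])
  }, logical(1))
  expect_false(any(overlaps))
  # wave-spike rate is a subset of the total rate
  expect_lte(run$stats$nu_W_Hz, run$stats$nu_Hz)
  expect_gt(run$stats$nu_W_Hz, 0)
})
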