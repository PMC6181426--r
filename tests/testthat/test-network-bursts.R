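test_that("binned smoothing produces a standardized kernel bump", {
  # empty train -> all zeros
  z <- smooth_spike_signal(numeric(0), 0, 1)
  expect_equal(z, rep(0, 500))
  # single spike -> kernel-shaped bump with max exactly 1
  s <- smooth_spike_signal(0.5, 0, 1, window_ms = 10)
  expect_equal(max(s), 1)
  expect_equal(which.max(s), 251)  # bump centered on the spike's bin
  # two spikes one bin apart under a wide kernel: unimodal, matches the
  # direct convolution oracle after rescaling
  tt <- c(0.500, 0.502)
  s2 <- smooth_spike_signal(tt, 0, 1, window_ms = 50)
  k <- gaussian_kernel(50, 0.002)
  x <- rep(0, 500); x[c(251, 252)] <- 1
  half <- (length(k) - 1) / 2
  oracle <- as.numeric(stats::filter(c(rep(0, half), x, rep(0, half)), k, sides = 2))
  oracle <- oracle[(half + 1):(half + 500)]
  oracle <- oracle / max(oracle)
  expect_equal(s2, oracle, tolerance = 1e-9)
  # interior local maxima only at the plateau: unimodal up to ties
  d <- sign(diff(round(s2, 12)))
  expect_lte(sum(diff(d[d != 0]) < 0), 1)
  # duplicate spikes in one bin collapse with a warning
  expect_warning(smooth_spike_signal(c(0.5001, 0.5002), 0, 1), "collapsed")
})

test_that("well synchrony signal rewards coincidence", {
  mk <- function(times) smooth_spike_signal(times, 0, 2, window_ms = 20)
  # identical electrodes: combined signal still peaks at 1 at the same spot
  sigs <- replicate(4, mk(1), simplify = FALSE)
  w <- well_synchrony_signal(sigs, window_ms = 20)
  expect_equal(max(w), 1)
  expect_equal(which.max(w), which.max(sigs[[1]]))
  # coincident bumps on 8 electrodes beat two disjoint single-electrode bumps
  # in pre-standardization mean amplitude
  co <- rowMeans(do.call(cbind, replicate(8, mk(1), simplify = FALSE)))
  dis <- rowMeans(do.call(cbind, c(list(mk(0.5), mk(1.5)),
                                   replicate(6, mk(numeric(0)), simplify = FALSE))))
  expect_gt(max(co), max(dis))
  expect_error(well_synchrony_signal(list()), "no electrode")
})

test_that("otsu threshold maximizes between-class variance", {
  # two-level signal: threshold strictly between the levels
  v <- c(rep(0, 50), rep(1, 50))
  thr <- otsu_threshold(v)
  expect_gt(thr, 0); expect_lt(thr, 1)
  # constant signal is degenerate
  expect_true(is.na(otsu_threshold(rep(0.3, 100))))
  # two tight clusters: classes exactly recovered, matches exhaustive search
  set.seed(8)
  v2 <- c(rnorm(200, 0.1, 0.01), rnorm(200, 0.9, 0.01))
  thr2 <- otsu_threshold(v2)
  expect_gt(thr2, 0.2); expect_lt(thr2, 0.8)
  expect_equal(v2 > thr2, v2 > 0.5)
  # exhaustive oracle over the same 256-level histogram
  edges <- seq(min(v2), max(v2), length.out = 257)
  idx <- pmin(pmax(findInterval(v2, edges, rightmost.closed = TRUE), 1), 256)
  bcv <- vapply(1:255, function(t) {
    lo <- v2[idx <= t]; hi <- v2[idx > t]
    if (!length(lo) || !length(hi)) return(-Inf)
    length(lo) / length(v2) * length(hi) / length(v2) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  top <- which(bcv >= max(bcv) - 1e-9 * abs(max(bcv)))
  expect_equal(thr2, edges[top[ceiling(length(top) / 2)] + 1], tolerance = 1e-12)
})

test_that("injected synchronized bursts are detected at about the injected count", {
  cfg <- sim_config(n_wells = 1, duration = 120, background_rate = 1,
                    burst_rate = 0, nb_rate = 5, nb_fraction = 0.9,
                    nb_count_mode = "fixed", seed = 404)
  sim <- simulate_recording(cfg)
  nb <- detect_network_bursts(sim$recording, recording_wells(sim$recording)[1])
  truth <- sim$truth$nb_events
  for (w in c(10, 20, 50)) {
    ev <- nb$events[nb$events$window == w, ]
    hit <- vapply(seq_len(nrow(truth)), function(i) {
      any(ev$start_time <= truth$end_time[i] & ev$end_time >= truth$start_time[i])
    }, logical(1))
    expect_gte(mean(hit), 0.9)
    expect_lte(abs(nrow(ev) - nrow(truth)) / nrow(truth), 0.35)
  }
  # events disjoint, ordered, spikes inside intervals, features consistent
  ev10 <- nb$events[nb$events$window == 10, ]
  if (nrow(ev10) > 1) expect_true(all(ev10$start_time[-1] >= ev10$end_time[-nrow(ev10)]))
  expect_equal(nb$features$nb_count_w10, nrow(ev10))
})

test_that("an asynchronous sparse well yields no network bursts", {
  set.seed(55)
  trains <- lapply(make_well_trains(16, numeric(0)), function(x) sort(runif(15, 0, 60)))
  rec <- make_recording(trains, end_time = 60)
  nb <- detect_network_bursts(rec, "A1", windows = 10)
  expect_lte(nrow(nb$events), 1)
})

test_that("33 network burst features, 11 per window", {
  rec <- make_recording(make_well_trains(8, c(1, 1.01, 1.02, 1.03, 1.04, 1.05),
                                         shift = 0.002), end_time = 10)
  nb <- detect_network_bursts(rec, "A1")
  expect_setequal(setdiff(names(nb$features), "well"), nb_feature_names())
  expect_length(nb_feature_names(), 33)
  expect_length(nb_feature_names(10), 11)
  # all spikes fall inside the single NB -> 100% participation
  expect_equal(nb$features$pct_spikes_in_nb_w10, 100)
})
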