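test_that("max interval detector reproduces hand-traced examples", {
  # six spikes at 50 ms ISI -> one burst spanning 0.25 s
  b <- detect_bursts_max_interval(seq(0, 0.25, by = 0.05))
  expect_equal(nrow(b), 1)
  expect_equal(b$n_spikes, 6L)
  expect_equal(b$duration, 0.25)
  # ISIs of 0.3 s never start a burst
  expect_equal(nrow(detect_bursts_max_interval(seq(0, 3, by = 0.3))), 0)
  # two 6-spike clusters 0.5 s apart (< min_ibi 0.8) merge into one burst
  clu <- seq(0, 0.25, by = 0.05)
  b2 <- detect_bursts_max_interval(c(clu, 0.75 + clu))
  expect_equal(nrow(b2), 1)
  expect_equal(b2$n_spikes, 12L)
  # clusters 1 s apart stay separate
  b3 <- detect_bursts_max_interval(c(clu, 1.5 + clu))
  expect_equal(nrow(b3), 2)
  expect_equal(nrow(detect_bursts_max_interval(numeric(0))), 0)
})

test_that("max interval matches the brute-force rule oracle on random trains", {
  set.seed(71)
  for (i in 1:40) {
    # mixture of background and dense clusters
    tt <- sort(c(runif(30, 0, 60),
                 unlist(lapply(runif(sample(0:4, 1), 0, 55), function(o) {
                   o + cumsum(runif(sample(4:12, 1), 0.01, 0.12))
                 }))))
    got <- detect_bursts_max_interval(tt)
    want <- max_interval_oracle(tt)
    expect_equal(got$start_index, want$start)
    expect_equal(got$end_index, want$end)
  }
})

test_that("raising min_spikes never increases the burst count", {
  set.seed(19)
  for (i in 1:10) {
    tt <- sort(c(runif(40, 0, 60),
                 unlist(lapply(runif(3, 0, 55), function(o) o + (0:9) * 0.05))))
    counts <- vapply(c(3, 6, 9, 12), function(ms) {
      nrow(detect_bursts_max_interval(tt, max_interval_params(min_spikes = ms)))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("poisson surprise statistic matches the Poisson tail", {
  expect_equal(poisson_surprise(10, 1, 1),
               -stats::ppois(9, 1, lower.tail = FALSE, log.p = TRUE) / log(10))
  # 10 spikes packed into 1 s on a 1 Hz electrode is a > 5 surprise
  expect_gt(poisson_surprise(10, 1, 1), 5)
})

test_that("poisson surprise finds an injected dense cluster and nothing in regular firing", {
  set.seed(23)
  bg <- sort(runif(100, 0, 100))
  cluster <- 50 + seq(0, 1, length.out = 10)
  tt <- sort(c(bg, cluster))
  b <- detect_bursts_poisson_surprise(tt, s_min = 5, t_total = 100)
  expect_gte(nrow(b), 1)
  # the detected burst covers the injected cluster and beats the threshold
  hit <- b$start_time <= min(cluster) + 0.5 & b$end_time >= max(cluster) - 0.5
  expect_true(any(hit))
  expect_true(all(b$surprise >= 5))
  # perfectly regular 1 Hz train: exhaustive scan finds no S >= 5 run
  reg <- 0:59
  expect_null(ps_oracle(reg, s_min = 5, rate = 1))
  expect_equal(nrow(detect_bursts_poisson_surprise(reg, s_min = 5, t_total = 60)), 0)
  expect_equal(nrow(detect_bursts_poisson_surprise(numeric(0))), 0)
  expect_equal(nrow(detect_bursts_poisson_surprise(c(1, 2))), 0)  # < 3 spikes
})

test_that("detected bursts are non-overlapping, ordered and inside the window", {
  set.seed(37)
  tt <- sort(c(runif(60, 0, 120),
               unlist(lapply(runif(5, 0, 115), function(o) o + (0:11) * 0.03))))
  for (m in c("mi", "ps")) {
    b <- if (m == "mi") detect_bursts_max_interval(tt)
         else detect_bursts_poisson_surprise(tt, t_total = 120)
    if (nrow(b) > 1) {
      expect_true(all(b$start_time[-1] > b$end_time[-nrow(b)]))
    }
    expect_true(all(b$start_time >= 0 & b$end_time <= 120))
    expect_true(all(b$n_spikes >= 2))
    expect_equal(b$duration, b$end_time - b$start_time)
  }
})

test_that("burst feature summaries compute the documented ratios", {
  # one burst of 6 spikes lasting 0.25 s -> in-burst spike rate 24 Hz;
  # another burst 5 s after the first ends -> IBI 5 s
  clu <- seq(0, 0.25, by = 0.05)
  trains <- list(A1_11 = c(clu, 5.25 + clu), A1_12 = sort(runif(10, 0, 30)))
  rec <- make_recording(trains, end_time = 30)
  bursts <- detect_bursts(rec, "mi")
  expect_equal(nrow(bursts$A1_11), 2)
  ft <- summarize_burst_features(bursts, rec)
  expect_equal(ft$spike_rate_in_burst_mean, 24)
  expect_equal(ft$ibi_mean, 5)
  expect_equal(ft$n_bursting_electrodes, 1L)
  expect_equal(ft$total_bursts, 2)
  # well with no bursts: all 19 features missing or zero-count
  rec2 <- make_recording(list(B1_11 = sort(runif(10, 0, 30))), end_time = 30)
  ft2 <- summarize_burst_features(detect_bursts(rec2, "mi"), rec2)
  expect_equal(ft2$n_bursting_electrodes, 0L)
  expect_true(all(is.na(unlist(ft2[setdiff(burst_feature_names(),
                                           "n_bursting_electrodes")]))))
})

test_that("exactly 19 burst features are emitted", {
  rec <- make_recording(make_well_trains(4, seq(0, 0.25, by = 0.05), shift = 0.002),
                        end_time = 10)
  ft <- summarize_burst_features(detect_bursts(rec, "mi"), rec)
  expect_setequal(setdiff(names(ft), "well"), burst_feature_names())
  expect_length(burst_feature_names(), 19)
})
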