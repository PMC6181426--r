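test_that("STTC reproduces hand-computed and degenerate cases", {
  # identical trains are perfectly correlated whatever dt
  a <- c(1, 2.5, 4, 7)
  expect_equal(sttc(a, a, dt = 0.05, t_start = 0, t_end = 10), 1.0)
  expect_equal(sttc(a, a, dt = 0.3, t_start = 0, t_end = 10), 1.0)
  # hand-computed: no coincidences, tiles cover 3% of the recording each
  expect_equal(sttc(c(1, 2, 3), c(1.2, 2.2, 3.2), dt = 0.05, t_start = 0, t_end = 10),
               -0.03)
  expect_error(sttc(a, numeric(0), dt = 0.05, t_start = 0, t_end = 10), "empty")
})

test_that("STTC matches the brute-force oracle on random train pairs", {
  set.seed(101)
  for (i in 1:100) {
    t_end <- runif(1, 5, 20)
    a <- sort(runif(sample(2:15, 1), 0, t_end))
    b <- sort(runif(sample(2:15, 1), 0, t_end))
    dt <- runif(1, 0.01, 0.5)
    expect_equal(sttc(a, b, dt, 0, t_end), sttc_oracle(a, b, dt, 0, t_end),
                 tolerance = 1e-12)
  }
})

test_that("STTC is symmetric and shift invariant for interior spikes", {
  set.seed(7)
  for (i in 1:20) {
    a <- sort(runif(8, 2, 8)); b <- sort(runif(8, 2, 8))
    expect_equal(sttc(a, b, 0.1, 0, 10), sttc(b, a, 0.1, 0, 10))
    s <- runif(1, -1, 1)
    expect_equal(sttc(a + s, b + s, 0.1, 0 + s, 10 + s),
                 sttc(a, b, 0.1, 0, 10), tolerance = 1e-12)
  }
})

test_that("well mean STTC averages all active pairs", {
  trains <- make_well_trains(3, c(1, 2, 3, 4), shift = 0)  # identical trains
  rec <- make_recording(trains, end_time = 10)
  expect_equal(mean_sttc_by_well(rec, "A1", dt = 0.05), 1.0)
  # N = 5 -> exactly 10 pairs, equal to a brute-force double loop
  set.seed(5)
  trains5 <- lapply(make_well_trains(5, numeric(0)), function(x) sort(runif(10, 0, 30)))
  rec5 <- make_recording(trains5, end_time = 30)
  tr <- spike_trains(rec5)
  pairs <- utils::combn(5, 2)
  expect_equal(ncol(pairs), 10)
  brute <- mean(apply(pairs, 2, function(ij) {
    sttc_oracle(tr[[ij[1]]], tr[[ij[2]]], 0.05, 0, 30)
  }))
  expect_equal(mean_sttc_by_well(rec5, "A1", dt = 0.05), brute, tolerance = 1e-12)
  # fewer than two (active) electrodes: missing value
  rec1 <- make_recording(list(A1_11 = c(1, 2)), end_time = 10)
  expect_true(is.na(mean_sttc_by_well(rec1, "A1")))
})

test_that("entropy matches closed forms", {
  # one spike per bin over n bins: H = log2 n, normalized 1
  n <- 20
  times <- seq(0.05, 1.95, by = 0.1)  # exactly one per 0.1 s bin over [0, 2]
  expect_equal(spike_entropy(times, bin = 0.1, t_start = 0, t_end = 2,
                             normalize = FALSE), log2(n))
  expect_equal(spike_entropy(times, bin = 0.1, t_start = 0, t_end = 2), 1)
  # all spikes in one bin: H = 0
  expect_equal(spike_entropy(rep(0.05, 7), bin = 0.1, t_start = 0, t_end = 2,
                             normalize = FALSE), 0)
  # mass (1/2, 1/2, 0, 0) over 4 bins: H = 1 bit, normalized 0.5
  times2 <- c(0.01, 0.02, 0.11, 0.12)
  expect_equal(spike_entropy(times2, bin = 0.1, t_start = 0, t_end = 0.4,
                             normalize = FALSE), 1)
  expect_equal(spike_entropy(times2, bin = 0.1, t_start = 0, t_end = 0.4), 0.5)
  expect_true(is.na(spike_entropy(numeric(0), bin = 0.1, t_start = 0, t_end = 1)))
})

test_that("entropy is bounded by log2(n) and normalized entropy by 1", {
  set.seed(3)
  for (i in 1:20) {
    tt <- sort(runif(rpois(1, 30) + 1, 0, 10))
    h <- spike_entropy(tt, 0.1, 0, 10, normalize = FALSE)
    expect_lte(h, log2(100) + 1e-12)
    hn <- spike_entropy(tt, 0.1, 0, 10)
    expect_gte(hn, 0); expect_lte(hn, 1)
  }
})

test_that("75th-percentile binarization uses a strict inequality", {
  counts <- c(0L, 0L, 0L, 4L)  # quantile(type 7) = 1, only the 4 passes
  expect_equal(binarize_counts(counts), c(0L, 0L, 0L, 1L))
  expect_equal(binarize_counts(rep(2L, 8)), rep(0L, 8))  # ties at the percentile -> 0
})

test_that("mutual information reproduces identities", {
  # identical binarized vectors: I(X,X) = H(X)
  a <- c(0.05, 0.15, 1.05, 1.06, 1.07, 1.08)  # one bin clearly above the 75th pct
  x <- binarize_counts(bin_spike_counts(a, 0.1, 0, 2))
  px <- mean(x)
  h <- -px * log2(px) - (1 - px) * log2(1 - px)
  expect_equal(pairwise_mutual_information(a, a, 0.1, 0, 2), h)
  # constant binary vector: I = 0 without error
  b <- seq(0.05, 1.95, by = 0.1)  # uniform counts -> all zeros after binarization
  expect_equal(pairwise_mutual_information(b, b, 0.1, 0, 2), 0)
  # symmetry and non-negativity on random pairs; joint mass conserved
  set.seed(13)
  for (i in 1:25) {
    u <- sort(runif(30, 0, 10)); v <- sort(runif(30, 0, 10))
    m1 <- pairwise_mutual_information(u, v, 0.1, 0, 10)
    expect_equal(m1, pairwise_mutual_information(v, u, 0.1, 0, 10))
    expect_gte(m1, 0)
  }
})

test_that("independent Poisson trains carry near-zero mutual information", {
  set.seed(29)
  vals <- replicate(100, {
    u <- sort(runif(rpois(1, 500), 0, 500))
    v <- sort(runif(rpois(1, 500), 0, 500))
    pairwise_mutual_information(u, v, 0.1, 0, 500)
  })
  expect_lt(mean(vals), 0.01)
})
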