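test_that("normalized histograms clip, normalize and respect the grid", {
  g <- seq(0, 3, length.out = 31)
  # constant values land in a single bin with frequency 1
  h <- normalized_histogram(rep(0.2, 30), g)
  expect_equal(sum(h$freq), 1)
  expect_equal(max(h$freq), 1)
  # values above the maximum are clipped into the last bin
  h2 <- normalized_histogram(c(rep(0.2, 5), 5), g)
  expect_equal(h2$freq[30], 1 / 6)
  # an even split across two bins gives (0.5, 0.5)
  h3 <- normalized_histogram(c(rep(0.05, 5), rep(0.15, 5)), seq(0, 0.3, by = 0.1))
  expect_equal(h3$freq, c(0.5, 0.5, 0))
  # no data -> histogram omitted, not zeros
  expect_null(normalized_histogram(numeric(0), g))
})

test_that("electrode histograms honour the minimum-burst filter", {
  clu <- seq(0, 0.25, by = 0.05)
  trains <- list(A1_11 = c(outer(clu, seq(0, 50, by = 5), "+")),  # 11 bursts
                 A1_12 = clu)                                      # 1 burst
  rec <- make_recording(trains, end_time = 60)
  bursts <- detect_bursts(rec, "mi")
  ed <- electrode_distributions(bursts, rec, "duration")
  expect_equal(ed$electrode, "A1_11")  # A1_12 fails min_bursts = 5
  expect_equal(sum(ed$hist[[1]]$freq), 1)
})

test_that("aggregation averages member histograms and renormalizes", {
  g <- seq(0, 4, by = 1)
  d1 <- hist_from_freq(c(1, 0, 0, 0))
  d3 <- hist_from_freq(c(0, 0, 1, 0))
  tab <- tibble::tibble(well = c("A1", "A2"), electrode = c("A1_11", "A2_11"),
                        hist = list(d1, d3))
  agg <- aggregate_distributions(tab, c(A1 = "g", A2 = "g"))
  expect_equal(agg$g$freq, c(0.5, 0, 0.5, 0))
  # two identical histograms average to themselves
  tab2 <- tibble::tibble(well = c("A1", "A2"), electrode = c("a", "b"),
                         hist = list(d1, d1))
  expect_equal(aggregate_distributions(tab2, c(A1 = "g", A2 = "g"))$g$freq, d1$freq)
  # by-well equals direct by-treatment when each well has one electrode
  agg_w <- aggregate_distributions(tab, c(A1 = "g", A2 = "g"), by_well = TRUE)
  agg_e <- aggregate_distributions(tab, c(A1 = "g", A2 = "g"), by_well = FALSE)
  expect_equal(agg_w$g$freq, agg_e$g$freq)
})

test_that("EMD and MD reproduce the area-between-CDFs oracle", {
  d1 <- hist_from_freq(c(1, 0, 0, 0))
  d3 <- hist_from_freq(c(0, 0, 1, 0))
  dd <- distribution_distances(d1, d3)
  expect_equal(unname(dd["emd"]), 2)
  expect_equal(unname(dd["md"]), 1)
  a <- hist_from_freq(c(0.5, 0.5, 0))
  b <- hist_from_freq(c(0, 0.5, 0.5))
  dd2 <- distribution_distances(a, b)
  expect_equal(unname(dd2["emd"]), 1)
  expect_equal(unname(dd2["md"]), 0.5)
  # identical histograms are at distance zero
  expect_equal(unname(distribution_distances(d1, d1)), c(0, 0))
  # grid mismatch is an error
  expect_error(distribution_distances(d1, hist_from_freq(c(1, 0, 0))), "grid")
})

test_that("EMD and MD behave as metrics on random histogram triples", {
  set.seed(31)
  rhist <- function() {
    f <- runif(8); hist_from_freq(f / sum(f))
  }
  for (i in 1:30) {
    x <- rhist(); y <- rhist(); z <- rhist()
    for (stat in c("emd", "md")) {
      dxy <- distribution_distances(x, y)[stat]
      dyx <- distribution_distances(y, x)[stat]
      dxz <- distribution_distances(x, z)[stat]
      dzy <- distribution_distances(z, y)[stat]
      expect_equal(unname(dxy), unname(dyx))
      expect_lte(unname(dxy), unname(dxz) + unname(dzy) + 1e-12)
      expect_equal(unname(distribution_distances(x, x)[stat]), 0)
    }
  }
})

test_that("label permutation keeps well histogram sets intact and finds a strong shift", {
  x <- make_hist_tab(10, shift = 2, seed = 42)
  res <- permute_distribution_test(x$tab, x$layout, c("WT", "KO"),
                                   n_perm = 100, seed = 7)
  expect_lte(res$p_emd, 0.05)
  expect_lte(res$p_md, 0.05)
  expect_length(res$perm_emd, 100)
  expect_true(all(res$perm_emd >= 0))
  g <- glance(res)
  expect_equal(g$emd, res$emd)
  # identical groups, degenerate statistic: every permutation ties -> p = 1
  g31 <- seq(0, 3, length.out = 31)
  same <- normalized_histogram(rep(0.2, 20), g31)
  tab <- tibble::tibble(well = well_labels(6),
                        electrode = paste0(well_labels(6), "_1"),
                        hist = replicate(6, same, simplify = FALSE))
  lay <- tibble::tibble(well = well_labels(6),
                        treatment = rep(c("A", "B"), each = 3))
  res0 <- permute_distribution_test(tab, lay, c("A", "B"), n_perm = 50, seed = 3)
  expect_equal(res0$p_emd, 1)
  # n_perm = 0: observed distances only
  resn <- permute_distribution_test(x$tab, x$layout, c("WT", "KO"), n_perm = 0)
  expect_true(is.na(resn$p_emd))
  expect_gt(resn$emd, 0)
})

test_that("ks mode compares pooled raw values", {
  set.seed(9)
  res <- permute_distribution_test(mode = "ks", treatments = c("A", "B"),
                                   values_a = rgamma(200, 2, 8),
                                   values_b = rgamma(200, 2, 4))
  expect_lt(res$ks_p, 0.01)
  expect_gt(res$ks_statistic, 0)
  expect_equal(names(glance(res)), c("ks_statistic", "ks_p"))
})
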