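#' Default histogram grids for burst-feature distributions
#'
#' Five burst features have empirical distributions: inter-burst interval
#' (`"ibi"`, s), ISI within bursts (`"isi_in_burst"`, s), number of spikes
#' in bursts (`"spikes_per_burst"`), burst duration (`"duration"`, s) and
#' spike frequency within bursts (`"spike_freq"`, Hz). The duration maximum
#' (3 s) and spike-frequency maximum (300 Hz) are user-facing caps; values
#' above the maximum are clipped into the last bin.
#'
#' @param feature one of `"ibi"`, `"isi_in_burst"`, `"spikes_per_burst"`,
#'   `"duration"`, `"spike_freq"`
#' @param bins number of bins, default 30
#' @return numeric vector of bin edges (length `bins + 1`)
#' @export
distribution_grid <- function(feature = distribution_feature_names(), bins = 30) {
  feature <- match.arg(feature)
  max_val <- switch(feature, ibi = 20, isi_in_burst = 0.5,
                    spikes_per_burst = 200, duration = 3, spike_freq = 300)
  seq(0, max_val, length.out = bins + 1)
}

#' Names of the five burst-distribution features
#' @return character vector of length 5
#' @export
distribution_feature_names <- function() {
  c("ibi", "isi_in_burst", "spikes_per_burst", "duration", "spike_freq")
}

#' Extract one burst feature's raw values from an electrode's bursts
#'
#' @param times the electrode's spike times (needed for within-burst ISIs)
#' @param bursts burst tibble from a detector
#' @param feature see [distribution_grid()]
#' @return numeric vector of feature values (possibly empty)
#' @export
burst_feature_values <- function(times, bursts, feature = distribution_feature_names()) {
  feature <- match.arg(feature)
  nb <- nrow(bursts)
  if (nb == 0) return(numeric(0))
  switch(feature,
    ibi = if (nb >= 2) bursts$start_time[-1] - bursts$end_time[-nb] else numeric(0),
    isi_in_burst = unlist(lapply(seq_len(nb), function(k) {
      diff(times[bursts$start_index[k]:bursts$end_index[k]])
    })),
    spikes_per_burst = as.numeric(bursts$n_spikes),
    duration = bursts$duration,
    spike_freq = bursts$n_spikes / pmax(bursts$duration, 1e-9)
  )
}

#' Normalized histogram of a burst feature
#'
#' Values are counted on a fixed bin grid shared by all electrodes for that
#' feature; values above the last edge are clipped into the last bin;
#' frequencies are normalized to sum to 1.
#'
#' @param values numeric vector of feature values
#' @param breaks bin edges, e.g. from [distribution_grid()]
#' @return object of class `mea_histogram`: list with `breaks`, `freq`
#'   (sums to 1), `n` (number of values). `NULL` when `values` is empty
#'   (empty histograms are omitted, not zero-filled).
#' @export
normalized_histogram <- function(values, breaks) {
  values <- values[!is.na(values)]
  if (length(values) == 0) return(NULL)
  nb <- length(breaks) - 1L
  idx <- findInterval(pmin(values, breaks[nb + 1L]), breaks, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nb)
  counts <- tabulate(idx, nb)
  structure(list(breaks = breaks, freq = counts / sum(counts), n = length(values)),
            class = "mea_histogram")
}

#' Per-electrode normalized burst-feature histograms
#'
#' Electrodes with fewer than `min_bursts` bursts (default 5) are excluded;
#' their histogram would be too noisy to represent the electrode.
#'
#' @param bursts named list of burst tibbles from [detect_bursts()]
#' @param rec the [mea_recording()]
#' @param feature see [distribution_grid()]
#' @param breaks bin edges; default [distribution_grid()] for the feature
#' @param min_bursts minimum bursts per electrode, default 5
#' @return tibble with `well`, `electrode`, `hist` (list column of
#'   `mea_histogram`); electrodes without a histogram are omitted
#' @export
electrode_distributions <- function(bursts, rec, feature, breaks = NULL,
                                    min_bursts = 5) {
  if (is.null(breaks)) breaks <- distribution_grid(feature)
  trains <- spike_trains(rec)
  el_tab <- rec$electrodes
  rows <- lapply(el_tab$electrode, function(e) {
    b <- bursts[[e]]
    if (is.null(b) || nrow(b) < min_bursts) return(NULL)
    h <- normalized_histogram(burst_feature_values(trains[[e]], b, feature), breaks)
    if (is.null(h)) return(NULL)
    tibble(well = el_tab$well[el_tab$electrode == e], electrode = e, hist = list(h))
  })
  dplyr::bind_rows(rows)
}

#' Average normalized histograms within groups
#'
#' Member frequencies (sharing one bin grid) are averaged unweighted and
#' renormalized to sum to 1. With `by_well = TRUE` electrode histograms are
#' first averaged within wells, then well histograms within groups.
#'
#' @param hist_tab tibble from [electrode_distributions()]
#' @param groups named character vector or tibble (`well`, `group`) mapping
#'   wells to group labels (e.g. treatments); wells with `NA` are dropped
#' @param by_well average by well first (default `TRUE`)
#' @return named list of `mea_histogram`, one per group (empty groups
#'   omitted)
#' @export
aggregate_distributions <- function(hist_tab, groups, by_well = TRUE) {
  if (is.data.frame(groups)) groups <- stats::setNames(groups$group, groups$well)
  hist_tab <- hist_tab[!is.na(groups[hist_tab$well]), ]
  if (nrow(hist_tab) == 0) return(list())
  mean_hists <- function(hs) {
    freq <- rowMeans(vapply(hs, `[[`, numeric(length(hs[[1]]$freq)), "freq"))
    structure(list(breaks = hs[[1]]$breaks, freq = freq / sum(freq),
                   n = sum(vapply(hs, `[[`, numeric(1), "n"))),
              class = "mea_histogram")
  }
  if (by_well) {
    well_h <- lapply(split(hist_tab$hist, hist_tab$well), mean_hists)
    grp <- split(well_h, unname(groups[names(well_h)]))
  } else {
    grp <- split(hist_tab$hist, unname(groups[hist_tab$well]))
  }
  lapply(grp, mean_hists)
}

#' Earth mover's and maximum CDF distances between two histograms
#'
#' On a shared 1-D grid the earth mover's distance (EMD) is the area between
#' the cumulative distributions (in units of bin width times probability)
#' and the maximum distance (MD) is the largest absolute difference between
#' the CDFs, in `[0, 1]`.
#'
#' @param a,b `mea_histogram` objects on identical grids
#' @return named numeric vector `c(emd = , md = )`
#' @export
distribution_distances <- function(a, b) {
  if (length(a$breaks) != length(b$breaks) || any(abs(a$breaks - b$breaks) > 1e-12)) {
    abort("histograms must share the same bin grid")
  }
  ca <- cumsum(a$freq); cb <- cumsum(b$freq)
  bw <- diff(a$breaks)[1]
  c(emd = sum(abs(ca - cb)) * bw, md = max(abs(ca - cb)))
}

#' Permutation test for burst-feature distribution differences
#'
#' The observed EMD and MD between the two treatments' aggregated
#' histograms are compared with the distribution obtained by shuffling the
#' treatment labels of the wells (`n_perm` times, default 100) while each
#' well's electrode histograms are kept intact. The permutation p-value is
#' the proportion of permuted distances greater than or equal to the
#' observed one (no smoothing, so p may be 0). With `mode = "ks"` a
#' two-sample Kolmogorov-Smirnov test on the pooled raw feature values is
#' returned instead (the single-recording comparison).
#'
#' @param hist_tab tibble from [electrode_distributions()] (for
#'   `mode = "perm"`)
#' @param layout plate layout tibble (`well`, `treatment`)
#' @param treatments character vector of the two treatment labels to compare
#' @param n_perm number of label shuffles, default 100; 0 gives observed
#'   distances only with `NA` p-values
#' @param seed RNG seed (required for reproducibility)
#' @param by_well see [aggregate_distributions()]
#' @param mode `"perm"` (EMD/MD permutation, default) or `"ks"`
#' @param values_a,values_b pooled raw feature values per treatment
#'   (required for `mode = "ks"`)
#' @return object of class `mea_dist_test`: list with `emd`, `md`,
#'   `p_emd`, `p_md`, `perm_emd`, `perm_md`, `n_perm`, `treatments` (or
#'   `ks_statistic`, `ks_p` in ks mode). Has [tidy()]/[glance()] methods.
#' @export
permute_distribution_test <- function(hist_tab = NULL, layout = NULL,
                                      treatments = NULL, n_perm = 100,
                                      seed = NULL, by_well = TRUE,
                                      mode = c("perm", "ks"),
                                      values_a = NULL, values_b = NULL) {
  mode <- match.arg(mode)
  if (mode == "ks") {
    stopifnot(!is.null(values_a), !is.null(values_b))
    kt <- suppressWarnings(stats::ks.test(values_a, values_b))
    return(structure(list(ks_statistic = unname(kt$statistic), ks_p = kt$p.value,
                          treatments = treatments, mode = "ks"),
                     class = "mea_dist_test"))
  }
  stopifnot(!is.null(hist_tab), !is.null(layout), length(treatments) == 2)
  if (!is.null(seed)) set.seed(seed)
  trt <- stats::setNames(layout$treatment, layout$well)
  wells <- unique(hist_tab$well)
  wells <- wells[trt[wells] %in% treatments]
  labels <- trt[wells]
  if (min(table(factor(labels, levels = treatments))) < 2) {
    abort("need at least 2 wells per treatment")
  }
  observed_dist <- function(lab) {
    groups <- stats::setNames(lab, wells)
    agg <- aggregate_distributions(hist_tab[hist_tab$well %in% wells, ],
                                   tibble(well = wells, group = unname(groups[wells])),
                                   by_well = by_well)
    if (length(agg) < 2) return(c(emd = NA_real_, md = NA_real_))
    distribution_distances(agg[[treatments[1]]], agg[[treatments[2]]])
  }
  obs <- observed_dist(labels)
  res <- list(emd = unname(obs["emd"]), md = unname(obs["md"]),
              n_perm = n_perm, treatments = treatments, mode = "perm")
  if (n_perm > 0) {
    n_distinct <- choose(length(wells), sum(labels == treatments[1]))
    perm <- vapply(seq_len(n_perm), function(i) observed_dist(sample(labels)),
                   numeric(2))
    res$perm_emd <- perm["emd", ]
    res$perm_md <- perm["md", ]
    res$p_emd <- mean(res$perm_emd >= res$emd, na.rm = TRUE)
    res$p_md <- mean(res$perm_md >= res$md, na.rm = TRUE)
    if (n_distinct < 2) {
      warn("too few wells for any distinct permutation; p = 1")
      res$p_emd <- 1; res$p_md <- 1
    }
  } else {
    res$p_emd <- NA_real_; res$p_md <- NA_real_
  }
  structure(res, class = "mea_dist_test")
}

#' @export
print.mea_dist_test <- function(x, ...) {
  if (x$mode == "ks") {
    cat(sprintf("<mea_dist_test ks>  D = %.4f, p = %.4g\n", x$ks_statistic, x$ks_p))
  } else {
    cat(sprintf("<mea_dist_test %s vs %s>  EMD = %.4f (p = %s), MD = %.4f (p = %s), %d permutations\n",
                x$treatments[1], x$treatments[2], x$emd, format(x$p_emd),
                x$md, format(x$p_md), x$n_perm))
  }
  invisible(x)
}
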