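#' Detect network spikes in one well
#'
#' A network spike (NS) is a brief volley of near-coincident firing: spike
#' times of all electrodes in the well are binned into tumbling windows
#' (default 10 ms) and the number of *distinct* electrodes firing in each
#' bin is counted. A contiguous run of bins at or above `min_electrodes`
#' (default 4, or 25% of the well's electrodes, whichever is larger) is one
#' NS; its peak is the maximum-count bin (earliest on ties) and consecutive
#' events are separated by at least one sub-threshold bin.
#'
#' @param rec an [mea_recording()]
#' @param well well id
#' @param bin detection bin width (s), default 0.010
#' @param min_electrodes detection threshold; default
#'   `max(4, ceiling(0.25 * n_electrodes))`
#' @return tibble, one row per NS: `well`, `start_time`, `end_time`,
#'   `peak_time` (center of the peak bin), `peak_electrode_count`,
#'   `n_spikes` (spikes of the well inside the event run), `duration`
#' @export
detect_network_spikes <- function(rec, well, bin = 0.010, min_electrodes = NULL) {
  stopifnot(bin > 0)
  ids <- rec$electrodes$electrode[rec$electrodes$well == well]
  if (is.null(min_electrodes)) min_electrodes <- max(4, ceiling(0.25 * length(ids)))
  stopifnot(min_electrodes >= 1)
  empty <- tibble(well = character(), start_time = numeric(), end_time = numeric(),
                  peak_time = numeric(), peak_electrode_count = integer(),
                  n_spikes = integer(), duration = numeric())
  sp <- rec$spikes[rec$spikes$electrode %in% ids, ]
  if (nrow(sp) == 0) return(empty)

  n_bins <- max(1L, as.integer(ceiling((rec$end_time - rec$start_time) / bin - 1e-9)))
  bin_idx <- pmin(pmax(floor((sp$time - rec$start_time) / bin) + 1L, 1L), n_bins)
  # distinct electrodes per bin
  key <- !duplicated(paste(bin_idx, sp$electrode))
  counts <- tabulate(bin_idx[key], n_bins)

  above <- counts >= min_electrodes
  if (!any(above)) return(empty)
  r <- rle(above)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  sel <- which(r$values)
  rows <- lapply(sel, function(k) {
    b0 <- run_start[k]; b1 <- run_end[k]
    peak_bin <- b0 + which.max(counts[b0:b1]) - 1L
    t0 <- rec$start_time + (b0 - 1L) * bin
    t1 <- rec$start_time + b1 * bin
    tibble(well = well, start_time = t0, end_time = t1,
           peak_time = rec$start_time + (peak_bin - 0.5) * bin,
           peak_electrode_count = counts[peak_bin],
           n_spikes = sum(sp$time >= t0 & sp$time < t1),
           duration = t1 - t0)
  })
  dplyr::bind_rows(rows)
}

#' Detect network spikes on every well
#'
#' @inheritParams detect_network_spikes
#' @return tibble of events across wells (see [detect_network_spikes()])
#' @export
detect_network_spikes_all <- function(rec, bin = 0.010, min_electrodes = NULL) {
  dplyr::bind_rows(lapply(recording_wells(rec), function(w) {
    detect_network_spikes(rec, w, bin = bin, min_electrodes = min_electrodes)
  }))
}

ns_profile <- function(rec, events, ids, profile_bin = 0.1, span = 1) {
  k <- as.integer(round(span / profile_bin))
  offsets <- (-k):k
  sp <- rec$spikes[rec$spikes$electrode %in% ids, ]
  prof <- matrix(0, nrow = nrow(events), ncol = length(offsets))
  for (i in seq_len(nrow(events))) {
    lo <- events$peak_time[i] + (offsets - 0.5) * profile_bin
    hi <- lo + profile_bin
    prof[i, ] <- vapply(seq_along(offsets), function(j) {
      inside <- sp$time >= lo[j] & sp$time < hi[j]
      length(unique(sp$electrode[inside]))
    }, numeric(1))
  }
  colMeans(prof)
}

#' Well-level network spike features
#'
#' Summarizes NS events into this package's canonical ten well-level NS
#' features (a documented reconstruction): `ns_count`, `ns_rate` (/min),
#' `peak_electrodes_mean`, `peak_electrodes_sd`, `spikes_per_ns_mean`,
#' `spikes_per_ns_sd`, `pct_spikes_in_ns`, `isi_in_ns_mean` (s),
#' `inter_ns_interval_mean` (s, peak to peak), `ns_duration_mean` (s).
#' Wells with no NS report `NA` features. The around-peak profile (mean
#' number of distinct electrodes firing in 100 ms bins spanning +/- 1 s of
#' each peak) is attached as attribute `"profile"`, a tibble with one row
#' per well.
#'
#' @param events tibble from [detect_network_spikes_all()]
#' @param rec the [mea_recording()]
#' @param profile_bin around-peak profile bin width (s), default 0.1
#' @param profile_span half-width of the profile (s), default 1
#' @return tibble, one row per well, 10 feature columns
#' @export
summarize_network_spikes <- function(events, rec, profile_bin = 0.1, profile_span = 1) {
  td <- recording_duration(rec)
  wells <- recording_wells(rec)
  el_tab <- rec$electrodes
  prof_rows <- list()
  rows <- lapply(wells, function(w) {
    ev <- events[events$well == w, ]
    ids <- el_tab$electrode[el_tab$well == w]
    total_spikes <- sum(rec$spikes$electrode %in% ids)
    if (nrow(ev) == 0) {
      return(tibble(well = w, ns_count = 0L, ns_rate = NA_real_,
                    peak_electrodes_mean = NA_real_, peak_electrodes_sd = NA_real_,
                    spikes_per_ns_mean = NA_real_, spikes_per_ns_sd = NA_real_,
                    pct_spikes_in_ns = NA_real_, isi_in_ns_mean = NA_real_,
                    inter_ns_interval_mean = NA_real_, ns_duration_mean = NA_real_))
    }
    sp <- rec$spikes[rec$spikes$electrode %in% ids, ]
    isi_in <- unlist(lapply(seq_len(nrow(ev)), function(i) {
      tt <- sort(sp$time[sp$time >= ev$start_time[i] & sp$time < ev$end_time[i]])
      diff(tt)
    }))
    prof <- ns_profile(rec, ev, ids, profile_bin, profile_span)
    prof_rows[[w]] <<- tibble(well = w,
                              offset = seq(-profile_span, profile_span, by = profile_bin),
                              mean_electrodes = prof)
    tibble(
      well = w,
      ns_count = nrow(ev),
      ns_rate = nrow(ev) / td * 60,
      peak_electrodes_mean = mean(ev$peak_electrode_count),
      peak_electrodes_sd = if (nrow(ev) > 1) stats::sd(ev$peak_electrode_count) else NA_real_,
      spikes_per_ns_mean = mean(ev$n_spikes),
      spikes_per_ns_sd = if (nrow(ev) > 1) stats::sd(ev$n_spikes) else NA_real_,
      pct_spikes_in_ns = if (total_spikes > 0) 100 * sum(ev$n_spikes) / total_spikes else NA_real_,
      isi_in_ns_mean = if (length(isi_in) > 0) mean(isi_in) else NA_real_,
      inter_ns_interval_mean = if (nrow(ev) > 1) mean(diff(ev$peak_time)) else NA_real_,
      ns_duration_mean = mean(ev$duration)
    )
  })
  res <- dplyr::bind_rows(rows)
  attr(res, "profile") <- dplyr::bind_rows(prof_rows)
  res
}

#' Names of the 10 well-level network spike features
#' @return character vector of length 10
#' @export
ns_feature_names <- function() {
  c("ns_count", "ns_rate", "peak_electrodes_mean", "peak_electrodes_sd",
    "spikes_per_ns_mean", "spikes_per_ns_sd", "pct_spikes_in_ns",
    "isi_in_ns_mean", "inter_ns_interval_mean", "ns_duration_mean")
}
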