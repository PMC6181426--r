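#' Identify active electrodes
#'
#' An electrode is active when its mean firing rate reaches `min_rate`
#' (default 5 spikes/min, a common MEA convention; the activity criterion is
#' configurable). Activity gates all downstream well-level analyses.
#'
#' @param rec an [mea_recording()]
#' @param min_rate minimum firing rate in Hz (default `5/60`)
#' @return tibble with `electrode`, `well`, `n_spikes`, `mfr`, `active`
#' @export
active_electrodes <- function(rec, min_rate = 5 / 60) {
  stopifnot(min_rate >= 0)
  er <- electrode_rates(rec)
  er$active <- if (min_rate > 0) er$mfr >= min_rate else er$n_spikes >= 1L
  er
}

isi_stats <- function(times) {
  if (length(times) < 2) return(c(mean = NA_real_, cv = NA_real_))
  d <- diff(times)
  m <- mean(d)
  c(mean = m, cv = if (m > 0) stats::sd(d) / m else 0)
}

#' Well-level spiking statistics
#'
#' Computes this package's canonical set of eleven well-level spiking
#' statistics over the active electrodes of each well (the exact
#' composition is a documented reconstruction, see the methods vignette):
#' `n_active_electrodes`, `n_spikes`, `spikes_per_ae_mean`,
#' `spike_count_cv`, `well_mfr` (mean of active electrodes' MFR, Hz),
#' `mfr_sd`, `isi_mean` (s), `isi_cv`, and the three synchrony means
#' `mean_sttc`, `mean_mi`, `mean_entropy` (normalized). Wells with no
#' active electrodes report `NA`, not zero.
#'
#' @param rec an [mea_recording()]
#' @param active activity table from [active_electrodes()]; computed with
#'   defaults when `NULL`
#' @param sttc_dt STTC coincidence half-window (s)
#' @param entropy_bin bin width (s) for entropy and mutual information
#' @param synchrony include the STTC/MI/entropy columns (default `TRUE`;
#'   they are the costliest statistics)
#' @return tibble, one row per well, 11 statistic columns
#' @export
compute_spike_statistics <- function(rec, active = NULL, sttc_dt = 0.05,
                                     entropy_bin = 0.1, synchrony = TRUE) {
  if (is.null(active)) active <- active_electrodes(rec)
  td <- recording_duration(rec)
  wells <- recording_wells(rec)
  trains_all <- spike_trains(rec)

  rows <- lapply(wells, function(w) {
    act <- active[active$well == w & active$active, ]
    n_ae <- nrow(act)
    if (n_ae == 0) {
      out <- tibble(well = w, n_active_electrodes = 0L, n_spikes = NA_real_,
                    spikes_per_ae_mean = NA_real_, spike_count_cv = NA_real_,
                    well_mfr = NA_real_, mfr_sd = NA_real_,
                    isi_mean = NA_real_, isi_cv = NA_real_)
      if (synchrony) {
        out$mean_sttc <- NA_real_; out$mean_mi <- NA_real_; out$mean_entropy <- NA_real_
      }
      return(out)
    }
    trains <- trains_all[act$electrode]
    isis <- vapply(trains, isi_stats, numeric(2))
    cnt_sd <- if (n_ae > 1) stats::sd(act$n_spikes) else NA_real_
    out <- tibble(
      well = w,
      n_active_electrodes = n_ae,
      n_spikes = sum(act$n_spikes),
      spikes_per_ae_mean = mean(act$n_spikes),
      spike_count_cv = if (mean(act$n_spikes) > 0) cnt_sd / mean(act$n_spikes) else NA_real_,
      well_mfr = mean(act$mfr),
      mfr_sd = if (n_ae > 1) stats::sd(act$mfr) else NA_real_,
      isi_mean = mean(isis["mean", ], na.rm = TRUE),
      isi_cv = mean(isis["cv", ], na.rm = TRUE)
    )
    out$isi_mean[is.nan(out$isi_mean)] <- NA_real_
    out$isi_cv[is.nan(out$isi_cv)] <- NA_real_
    if (synchrony) {
      out$mean_sttc <- mean_sttc_by_well(rec, w, dt = sttc_dt, active = active)
      mi <- well_mutual_information(rec, w, bin = entropy_bin, active = active)
      out$mean_mi <- if (nrow(mi) > 0) mean(mi$mi) else NA_real_
      ent <- vapply(trains, spike_entropy, numeric(1), bin = entropy_bin,
                    t_start = rec$start_time, t_end = rec$end_time, normalize = TRUE)
      out$mean_entropy <- mean(ent, na.rm = TRUE)
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Names of the aggregated spike features
#'
#' The eight spike features that enter the aggregated cross-recording
#' tables: the eleven spiking statistics of [compute_spike_statistics()]
#' minus the three synchrony means (which are reported as statistics but
#' not aggregated, keeping the feature inventory at 8 spike + 19 burst +
#' 10 network-spike + 33 network-burst = 70).
#' @return character vector of length 8
#' @export
spike_feature_names <- function() {
  c("n_active_electrodes", "n_spikes", "spikes_per_ae_mean", "spike_count_cv",
    "well_mfr", "mfr_sd", "isi_mean", "isi_cv")
}

#' Names of the eleven well-level spiking statistics
#' @return character vector of length 11
#' @export
spike_statistic_names <- function() {
  c(spike_feature_names(), "mean_sttc", "mean_mi", "mean_entropy")
}
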