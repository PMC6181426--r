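#' Maximum Interval burst detection parameters
#'
#' The five NeuroExplorer-style rules: a burst begins at an inter-spike
#' interval (ISI) no longer than `max_begin_isi` and extends while ISIs stay
#' within `max_end_isi`; bursts separated by less than `min_ibi` are merged;
#' bursts shorter than `min_duration` or with fewer than `min_spikes` spikes
#' are discarded.
#'
#' @param max_begin_isi s, default 0.1
#' @param max_end_isi s, default 0.25 (must be `>= max_begin_isi`)
#' @param min_ibi s, default 0.8
#' @param min_duration s, default 0.05
#' @param min_spikes count, default 6
#' @return list of class `max_interval_params`
#' @export
max_interval_params <- function(max_begin_isi = 0.1, max_end_isi = 0.25,
                                min_ibi = 0.8, min_duration = 0.05,
                                min_spikes = 6) {
  stopifnot(max_begin_isi > 0, max_end_isi >= max_begin_isi,
            min_ibi > 0, min_duration > 0, min_spikes >= 2)
  structure(list(max_begin_isi = max_begin_isi, max_end_isi = max_end_isi,
                 min_ibi = min_ibi, min_duration = min_duration,
                 min_spikes = min_spikes),
            class = "max_interval_params")
}

empty_bursts <- function() {
  tibble(start_index = integer(), end_index = integer(),
         start_time = numeric(), end_time = numeric(),
         n_spikes = integer(), duration = numeric(), surprise = numeric())
}

#' Detect bursts with the Maximum Interval algorithm
#'
#' @param times sorted spike times of one electrode (s)
#' @param params a [max_interval_params()] object
#' @return tibble of non-overlapping, time-ordered bursts with columns
#'   `start_index`, `end_index` (1-based into `times`), `start_time`,
#'   `end_time`, `n_spikes`, `duration`, `surprise` (NA for this detector)
#' @export
detect_bursts_max_interval <- function(times, params = max_interval_params()) {
  n <- length(times)
  if (n < 2) return(empty_bursts())
  isi <- diff(times)
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n - 1L) {
    if (isi[i] <= params$max_begin_isi) {
      j <- i + 1L
      while (j <= n - 1L && isi[j] <= params$max_end_isi) j <- j + 1L
      starts <- c(starts, i); ends <- c(ends, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(starts) == 0) return(empty_bursts())
  # merge bursts separated by less than min_ibi
  k <- 1L
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(0); out_e <- integer(0)
  if (length(starts) > 1) {
    for (b in 2:length(starts)) {
      if (times[starts[b]] - times[me] < params$min_ibi) {
        me <- ends[b]
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- starts[b]; me <- ends[b]
      }
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  dur <- times[out_e] - times[out_s]
  nsp <- out_e - out_s + 1L
  keep <- dur >= params$min_duration & nsp >= params$min_spikes
  tibble(start_index = out_s[keep], end_index = out_e[keep],
         start_time = times[out_s[keep]], end_time = times[out_e[keep]],
         n_spikes = nsp[keep], duration = dur[keep], surprise = NA_real_)
}

#' Poisson surprise of a spike run
#'
#' `S = -log10 P(X >= n | X ~ Poisson(rate * d))`: how surprising it is to
#' see `n` spikes packed into a span of `d` seconds if the electrode fired
#' as a homogeneous Poisson process at its mean rate.
#'
#' @param n spike count in the run
#' @param d run duration (s)
#' @param rate mean firing rate (Hz)
#' @return surprise in -log10 units
#' @export
poisson_surprise <- function(n, d, rate) {
  lambda <- rate * pmax(d, 1e-9)
  -stats::ppois(n - 1, lambda, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Detect bursts with the Poisson Surprise algorithm
#'
#' Candidate runs are seeded by stretches of short ISIs (below half the mean
#' ISI), greedily extended at the tail and trimmed at the head while the
#' surprise statistic increases, and kept when the final surprise reaches
#' `s_min`. Overlapping candidates are resolved in favour of higher
#' surprise, ties toward the longer burst.
#'
#' @param times sorted spike times of one electrode (s)
#' @param s_min surprise threshold in -log10 units (default 5)
#' @param rate Poisson rate (Hz); defaults to the electrode's mean firing
#'   rate `length(times) / t_total`
#' @param t_total recording duration (s), used for the default rate
#' @param lookahead how many spikes past the current tail to examine when
#'   extending (default 10)
#' @return tibble of bursts as in [detect_bursts_max_interval()], with
#'   `surprise` filled in
#' @export
detect_bursts_poisson_surprise <- function(times, s_min = 5, rate = NULL,
                                           t_total = NULL, lookahead = 10L) {
  n <- length(times)
  if (n < 3) return(empty_bursts())
  if (is.null(rate)) {
    if (is.null(t_total)) t_total <- max(times) - min(times)
    if (t_total <= 0) return(empty_bursts())
    rate <- n / t_total
  }
  if (rate <= 0) return(empty_bursts())
  isi <- diff(times)
  mean_isi <- 1 / rate
  short <- isi < mean_isi / 2
  if (!any(short)) return(empty_bursts())

  s_of <- function(i, j) poisson_surprise(j - i + 1L, times[j] - times[i], rate)

  # maximal runs of short ISIs -> seed [i, j] spans
  r <- rle(short)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  seeds <- cbind(starts_idx[r$values], ends_idx[r$values] + 1L)

  cand <- list()
  for (k in seq_len(nrow(seeds))) {
    i <- seeds[k, 1]; j <- seeds[k, 2]
    repeat {
      changed <- FALSE
      # extend tail: jump to the best of the next `lookahead` spikes if it helps
      if (j < n) {
        js <- (j + 1L):min(n, j + lookahead)
        sv <- s_of(i, js)
        best <- which.max(sv)
        if (sv[best] > s_of(i, j)) { j <- js[best]; changed <- TRUE }
      }
      # trim head while surprise increases (keep at least 3 spikes)
      while (j - i + 1L > 3L && s_of(i + 1L, j) > s_of(i, j)) { i <- i + 1L; changed <- TRUE }
      if (!changed) break
    }
    s <- s_of(i, j)
    if (is.finite(s) && s >= s_min && j - i + 1L >= 2L) {
      cand[[length(cand) + 1L]] <- c(i, j, s)
    }
  }
  if (length(cand) == 0) return(empty_bursts())
  cm <- do.call(rbind, cand)
  cm <- cm[!duplicated(cm[, 1:2, drop = FALSE]), , drop = FALSE]
  # higher surprise wins overlaps; ties toward the longer burst
  len <- cm[, 2] - cm[, 1]
  ord <- order(-cm[, 3], -len, cm[, 1])
  cm <- cm[ord, , drop = FALSE]
  taken <- logical(n)
  keep <- logical(nrow(cm))
  for (k in seq_len(nrow(cm))) {
    span <- cm[k, 1]:cm[k, 2]
    if (!any(taken[span])) { keep[k] <- TRUE; taken[span] <- TRUE }
  }
  cm <- cm[keep, , drop = FALSE]
  cm <- cm[order(cm[, 1]), , drop = FALSE]
  tibble(start_index = as.integer(cm[, 1]), end_index = as.integer(cm[, 2]),
         start_time = times[cm[, 1]], end_time = times[cm[, 2]],
         n_spikes = as.integer(cm[, 2] - cm[, 1] + 1L),
         duration = times[cm[, 2]] - times[cm[, 1]],
         surprise = cm[, 3])
}

#' Detect bursts on every electrode of a recording
#'
#' @param rec an [mea_recording()]
#' @param method `"mi"` (Maximum Interval, default) or `"ps"` (Poisson
#'   Surprise)
#' @param ... passed to the chosen detector
#' @return named list (by electrode id) of burst tibbles
#' @export
detect_bursts <- function(rec, method = c("mi", "ps"), ...) {
  method <- match.arg(method)
  trains <- spike_trains(rec)
  if (method == "mi") {
    lapply(trains, detect_bursts_max_interval, ...)
  } else {
    lapply(trains, detect_bursts_poisson_surprise,
           t_total = recording_duration(rec), ...)
  }
}

burst_electrode_summary <- function(times, bursts, t_total) {
  nb <- nrow(bursts)
  in_burst <- sum(bursts$n_spikes)
  isi_in <- unlist(lapply(seq_len(nb), function(k) {
    diff(times[bursts$start_index[k]:bursts$end_index[k]])
  }))
  tibble(
    n_bursts = nb,
    burst_duration = mean(bursts$duration),
    burst_rate = nb / t_total * 60,
    spikes_per_burst = mean(bursts$n_spikes),
    spike_rate_in_burst = mean(bursts$n_spikes / pmax(bursts$duration, 1e-9)),
    ibi = if (nb >= 2) mean(bursts$start_time[-1] - bursts$end_time[-nb]) else NA_real_,
    isi_in_burst = if (length(isi_in) > 0) mean(isi_in) else NA_real_,
    pct_spikes_in_bursts = 100 * in_burst / length(times),
    spikes_in_bursts = in_burst,
    n_spikes = length(times)
  )
}

#' Well-level burst features
#'
#' Summarizes electrode-level bursts into this package's canonical 19
#' well-level burst features (a documented reconstruction): per-well mean
#' and SD over *bursting* electrodes of \{bursts per electrode, burst
#' duration (s), burst rate (/min), spikes per burst, spike rate in burst
#' (Hz), inter-burst interval (s), ISI within burst (s), % spikes in
#' bursts\}, plus `n_bursting_electrodes`, `total_bursts` and
#' `well_pct_spikes_in_bursts`. Wells (or statistics) without data report
#' `NA`, not zero.
#'
#' @param bursts named list of burst tibbles from [detect_bursts()]
#' @param rec the [mea_recording()] the bursts came from
#' @param active optional activity table from [active_electrodes()]; when
#'   given, only active electrodes are summarized
#' @return tibble, one row per well, 19 feature columns
#' @export
summarize_burst_features <- function(bursts, rec, active = NULL) {
  td <- recording_duration(rec)
  trains <- spike_trains(rec)
  wells <- recording_wells(rec)
  el_tab <- rec$electrodes
  rows <- lapply(wells, function(w) {
    ids <- el_tab$electrode[el_tab$well == w]
    if (!is.null(active)) ids <- intersect(ids, active$electrode[active$active])
    per_el <- dplyr::bind_rows(lapply(ids, function(e) {
      b <- bursts[[e]]
      if (is.null(b) || nrow(b) == 0) return(NULL)
      burst_electrode_summary(trains[[e]], b, td)
    }))
    base <- c("n_bursts", "burst_duration", "burst_rate", "spikes_per_burst",
              "spike_rate_in_burst", "ibi", "isi_in_burst", "pct_spikes_in_bursts")
    out <- tibble(well = w)
    if (nrow(per_el) == 0) {
      for (f in base) {
        out[[paste0(f, "_mean")]] <- NA_real_
        out[[paste0(f, "_sd")]] <- NA_real_
      }
      out$n_bursting_electrodes <- 0L
      out$total_bursts <- NA_real_
      out$well_pct_spikes_in_bursts <- NA_real_
      return(out)
    }
    for (f in base) {
      v <- per_el[[f]]
      out[[paste0(f, "_mean")]] <- mean(v, na.rm = TRUE)
      out[[paste0(f, "_sd")]] <- if (sum(!is.na(v)) > 1) stats::sd(v, na.rm = TRUE) else NA_real_
    }
    out[[paste0("n_bursts", "_mean")]] <- mean(per_el$n_bursts)
    out$n_bursting_electrodes <- nrow(per_el)
    out$total_bursts <- sum(per_el$n_bursts)
    well_total_spikes <- sum(vapply(trains[ids], length, integer(1)))
    out$well_pct_spikes_in_bursts <-
      if (well_total_spikes > 0) 100 * sum(per_el$spikes_in_bursts) / well_total_spikes else NA_real_
    out
  })
  res <- dplyr::bind_rows(rows)
  nm <- names(res)
  nm[nm == "n_bursts_mean"] <- "bursts_per_electrode_mean"
  nm[nm == "n_bursts_sd"] <- "bursts_per_electrode_sd"
  names(res) <- nm
  res
}

#' Names of the 19 well-level burst features
#' @return character vector of length 19
#' @export
burst_feature_names <- function() {
  base <- c("bursts_per_electrode", "burst_duration", "burst_rate",
            "spikes_per_burst", "spike_rate_in_burst", "ibi", "isi_in_burst",
            "pct_spikes_in_bursts")
  c(paste0(rep(base, each = 2), c("_mean", "_sd")),
    "n_bursting_electrodes", "total_bursts", "well_pct_spikes_in_bursts")
}
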