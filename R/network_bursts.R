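#' Gaussian smoothing kernel for binned spike trains
#'
#' The kernel's standard deviation is the smoothing window converted to
#' bins (`window_ms / 1000 / bin`), truncated at +/- 3 sigma and normalized
#' to unit sum.
#'
#' @param window_ms smoothing window (ms)
#' @param bin bin width (s)
#' @return numeric kernel of odd length summing to 1
#' @export
gaussian_kernel <- function(window_ms, bin) {
  sigma <- (window_ms / 1000) / bin
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm((-half):half, sd = sigma)
  k / sum(k)
}

# same-length convolution via FFT (kernel must have odd length)
conv_same <- function(x, k) {
  n <- length(x); m <- length(k)
  half <- (m - 1L) %/% 2L
  full <- stats::convolve(x, rev(k), type = "open")
  full[(half + 1L):(half + n)]
}

#' Bin and smooth one electrode's spike train
#'
#' Spike times are binned at `bin` seconds (default 2 ms, chosen so that at
#' most one spike falls in a bin; bins receiving several spikes are
#' collapsed to one with a warning), convolved with a normalized Gaussian
#' kernel ([gaussian_kernel()]) and rescaled so the maximum is exactly 1
#' (an all-zero signal stays zero).
#'
#' @param times sorted spike times (s)
#' @param t_start,t_end recording window (s)
#' @param bin bin width (s), default 0.002
#' @param window_ms Gaussian smoothing window (ms)
#' @param warn_duplicates warn when a bin holds more than one spike
#' @return numeric signal of length `ceiling(T / bin)`, values in `[0, 1]`
#' @export
smooth_spike_signal <- function(times, t_start, t_end, bin = 0.002,
                                window_ms = 10, warn_duplicates = TRUE) {
  counts <- bin_spike_counts(times, bin, t_start, t_end)
  if (warn_duplicates && any(counts > 1L)) {
    warn("multiple spikes collapsed within a single bin")
  }
  x <- as.numeric(counts > 0L)
  if (!any(x > 0)) return(x)
  sm <- conv_same(x, gaussian_kernel(window_ms, bin))
  sm[sm < 0] <- 0  # FFT round-off
  sm / max(sm)
}

#' Combine electrode signals into a well synchronization signal
#'
#' The standardized electrode-level signals are averaged, smoothed again
#' with the same Gaussian kernel, and re-standardized to a maximum of 1.
#' Larger values indicate stronger synchronized bursting across the well.
#'
#' @param signals list (or matrix columns) of equal-length electrode signals
#' @param bin bin width (s) the signals were built with
#' @param window_ms Gaussian smoothing window (ms)
#' @return numeric well-level signal, max 1 (all-zero stays zero)
#' @export
well_synchrony_signal <- function(signals, bin = 0.002, window_ms = 10) {
  if (length(signals) == 0) abort("no electrode signals to combine")
  mat <- do.call(cbind, signals)
  avg <- rowMeans(mat)
  if (!any(avg > 0)) return(avg)
  sm <- conv_same(avg, gaussian_kernel(window_ms, bin))
  sm[sm < 0] <- 0
  sm / max(sm)
}

#' Otsu's global threshold
#'
#' The values are histogrammed into `n_levels` equal-width bins over their
#' range and the threshold maximizing the between-class variance
#' `w0 w1 (mu0 - mu1)^2` is returned (the edge between the two classes).
#' A constant input is degenerate and returns `NA`.
#'
#' @param values numeric vector
#' @param n_levels histogram resolution, default 256
#' @return threshold value, or `NA_real_` for a constant input
#' @export
otsu_threshold <- function(values, n_levels = 256) {
  rng <- range(values)
  if (!is.finite(diff(rng)) || diff(rng) == 0) return(NA_real_)
  edges <- seq(rng[1], rng[2], length.out = n_levels + 1)
  idx <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L), n_levels)
  p <- tabulate(idx, n_levels) / length(values)
  mids <- (edges[-1] + edges[-(n_levels + 1)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_levels]
  t_idx <- seq_len(n_levels - 1)
  w1 <- 1 - w0[t_idx]
  valid <- w0[t_idx] > 0 & w1 > 0
  bcv <- rep(-Inf, n_levels - 1)
  bcv[valid] <- (mu_t * w0[t_idx][valid] - mu0[t_idx][valid])^2 /
    (w0[t_idx][valid] * w1[valid])
  if (!any(is.finite(bcv))) return(NA_real_)
  # ties (e.g. an empty gap between two clusters) break toward the middle
  # of the maximal plateau, centering the threshold in the gap
  top <- which(bcv >= max(bcv) - 1e-12 * abs(max(bcv)))
  best <- top[ceiling(length(top) / 2)]
  edges[best + 1]
}

#' Detect synchronized network bursts in one well
#'
#' Network bursts (NBs) are long synchronized bursting intervals across a
#' well. Each electrode's train is binned (2 ms) and Gaussian-smoothed at
#' each window size; the standardized electrode signals are averaged,
#' re-smoothed and re-standardized into a well synchronization signal; Otsu
#' thresholding of that signal marks contiguous above-threshold intervals as
#' NB candidates. Candidates with fewer than `min_electrodes` participating
#' electrodes are discarded (isolated single-electrode bumps otherwise pass
#' a global threshold on sparse wells).
#'
#' @param rec an [mea_recording()]
#' @param well well id
#' @param windows Gaussian window sizes in ms (defaults 10, 20, 50)
#' @param bin bin width (s), default 0.002
#' @param min_electrodes minimum distinct electrodes firing inside an NB,
#'   default `max(4, ceiling(0.25 * n_electrodes))`
#' @param warn_duplicates see [smooth_spike_signal()]
#' @return list with `events` (tibble: `well`, `window`, `start_time`,
#'   `end_time`, `duration`, `n_spikes`, `spike_intensity` spikes/s,
#'   `n_electrodes`) and `features` (one-row tibble of 11 features per
#'   window, 33 columns, suffixed `_w<window>`)
#' @export
detect_network_bursts <- function(rec, well, windows = c(10, 20, 50),
                                  bin = 0.002, min_electrodes = NULL,
                                  warn_duplicates = FALSE) {
  ids <- rec$electrodes$electrode[rec$electrodes$well == well]
  if (is.null(min_electrodes)) min_electrodes <- max(4, ceiling(0.25 * length(ids)))
  trains <- spike_trains(rec, electrodes = ids)
  sp <- rec$spikes[rec$spikes$electrode %in% ids, ]
  td <- recording_duration(rec)
  total_spikes <- nrow(sp)

  events <- list()
  feats <- tibble(well = well)
  for (w_ms in windows) {
    ev <- tibble(well = character(), window = numeric(), start_time = numeric(),
                 end_time = numeric(), duration = numeric(), n_spikes = integer(),
                 spike_intensity = numeric(), n_electrodes = integer())
    if (total_spikes > 0) {
      sigs <- lapply(trains, smooth_spike_signal, t_start = rec$start_time,
                     t_end = rec$end_time, bin = bin, window_ms = w_ms,
                     warn_duplicates = warn_duplicates)
      sig <- well_synchrony_signal(sigs, bin = bin, window_ms = w_ms)
      thr <- otsu_threshold(sig)
      if (!is.na(thr)) {
        above <- sig > thr
        if (any(above)) {
          r <- rle(above)
          run_end <- cumsum(r$lengths)
          run_start <- run_end - r$lengths + 1L
          sel <- which(r$values)
          rows <- lapply(sel, function(k) {
            t0 <- rec$start_time + (run_start[k] - 1L) * bin
            t1 <- rec$start_time + run_end[k] * bin
            inside <- sp$time >= t0 & sp$time < t1
            n_el <- length(unique(sp$electrode[inside]))
            tibble(well = well, window = w_ms, start_time = t0, end_time = t1,
                   duration = t1 - t0, n_spikes = sum(inside),
                   spike_intensity = sum(inside) / (t1 - t0), n_electrodes = n_el)
          })
          ev <- dplyr::bind_rows(rows)
          ev <- ev[ev$n_electrodes >= min_electrodes, ]
        }
      }
    }
    events[[as.character(w_ms)]] <- ev
    nb <- nrow(ev)
    f <- tibble(
      nb_count = nb,
      nb_rate = if (nb > 0) nb / td * 60 else NA_real_,
      nb_duration_mean = if (nb > 0) mean(ev$duration) else NA_real_,
      nb_duration_sd = if (nb > 1) stats::sd(ev$duration) else NA_real_,
      spikes_in_nb_total = if (nb > 0) sum(ev$n_spikes) else NA_real_,
      pct_spikes_in_nb = if (nb > 0 && total_spikes > 0) 100 * sum(ev$n_spikes) / total_spikes else NA_real_,
      spikes_per_nb_mean = if (nb > 0) mean(ev$n_spikes) else NA_real_,
      spike_intensity_mean = if (nb > 0) mean(ev$spike_intensity) else NA_real_,
      spike_intensity_sd = if (nb > 1) stats::sd(ev$spike_intensity) else NA_real_,
      inter_nb_interval_mean = if (nb > 1) mean(ev$start_time[-1] - ev$end_time[-nb]) else NA_real_,
      electrodes_per_nb_mean = if (nb > 0) mean(ev$n_electrodes) else NA_real_
    )
    names(f) <- paste0(names(f), "_w", w_ms)
    feats <- dplyr::bind_cols(feats, f)
  }
  list(events = dplyr::bind_rows(events), features = feats)
}

#' Network burst features for every well
#'
#' @inheritParams detect_network_bursts
#' @return list with `events` (tibble across wells) and `features` (tibble,
#'   one row per well, 33 feature columns)
#' @export
detect_network_bursts_all <- function(rec, windows = c(10, 20, 50), bin = 0.002,
                                      min_electrodes = NULL, warn_duplicates = FALSE) {
  res <- lapply(recording_wells(rec), function(w) {
    detect_network_bursts(rec, w, windows = windows, bin = bin,
                          min_electrodes = min_electrodes,
                          warn_duplicates = warn_duplicates)
  })
  list(events = dplyr::bind_rows(lapply(res, `[[`, "events")),
       features = dplyr::bind_rows(lapply(res, `[[`, "features")))
}

#' Names of the network burst features
#' @param windows window sizes in ms
#' @return character vector (11 per window)
#' @export
nb_feature_names <- function(windows = c(10, 20, 50)) {
  base <- c("nb_count", "nb_rate", "nb_duration_mean", "nb_duration_sd",
            "spikes_in_nb_total", "pct_spikes_in_nb", "spikes_per_nb_mean",
            "spike_intensity_mean", "spike_intensity_sd",
            "inter_nb_interval_mean", "electrodes_per_nb_mean")
  as.vector(vapply(windows, function(w) paste0(base, "_w", w),
                   character(length(base))))
}
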