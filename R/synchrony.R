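#' Spike time tiling coefficient for one electrode pair
#'
#' Firing-rate-insensitive pairwise correlation between two spike trains in
#' `[-1, 1]`. For trains A and B with coincidence half-window `dt`:
#' `P_A` is the proportion of A's spikes falling within `dt` of any spike of
#' B, `T_A` the proportion of the recording tiled by `+/- dt` windows around
#' A's spikes (overlapping windows merged, clipped to the recording), and
#'
#'   STTC = 1/2 \[ (P_A - T_B)/(1 - P_A T_B) + (P_B - T_A)/(1 - P_B T_A) \]
#'
#' @param a,b sorted numeric vectors of spike times (s); both non-empty
#' @param dt coincidence half-window (s), default 0.05
#' @param t_start,t_end recording window (s)
#' @return STTC value in `[-1, 1]`
#' @export
sttc <- function(a, b, dt = 0.05, t_start = 0, t_end) {
  if (length(a) == 0 || length(b) == 0) abort("sttc is undefined for empty trains")
  if (dt <= 0) abort("dt must be positive")
  ta <- tiling_fraction(a, dt, t_start, t_end)
  tb <- tiling_fraction(b, dt, t_start, t_end)
  pa <- coincident_fraction(a, b, dt)
  pb <- coincident_fraction(b, a, dt)
  term <- function(p, t) {
    d <- 1 - p * t
    if (d == 0) 0 else (p - t) / d
  }
  0.5 * (term(pa, tb) + term(pb, ta))
}

# fraction of [t_start, t_end] covered by the union of [s - dt, s + dt]
tiling_fraction <- function(s, dt, t_start, t_end) {
  lo <- pmax(s - dt, t_start)
  hi <- pmin(s + dt, t_end)
  # union of sorted, possibly overlapping intervals
  n <- length(s)
  total <- 0
  cur_lo <- lo[1]; cur_hi <- hi[1]
  if (n > 1) {
    for (i in 2:n) {
      if (lo[i] <= cur_hi) {
        cur_hi <- max(cur_hi, hi[i])
      } else {
        total <- total + (cur_hi - cur_lo)
        cur_lo <- lo[i]; cur_hi <- hi[i]
      }
    }
  }
  total <- total + (cur_hi - cur_lo)
  total / (t_end - t_start)
}

# proportion of spikes in a lying within dt of any spike in b
coincident_fraction <- function(a, b, dt) {
  idx <- findInterval(a, b)
  d_prev <- ifelse(idx >= 1, a - b[pmax(idx, 1)], Inf)
  d_next <- ifelse(idx < length(b), b[pmin(idx + 1, length(b))] - a, Inf)
  mean(pmin(d_prev, d_next) <= dt)
}

#' Mean pairwise STTC across the active electrodes of a well
#'
#' Any dependence of correlation on electrode distance is ignored: the
#' unweighted mean over all N(N-1)/2 active-electrode pairs is returned.
#'
#' @param rec an [mea_recording()]
#' @param well well id
#' @param dt coincidence half-window (s)
#' @param active optional activity table from [active_electrodes()]; when
#'   given, only active electrodes enter the mean
#' @return mean STTC, or `NA` when fewer than 2 (active) electrodes have
#'   spikes
#' @export
mean_sttc_by_well <- function(rec, well, dt = 0.05, active = NULL) {
  trains <- well_active_trains(rec, well, active)
  if (length(trains) < 2) return(NA_real_)
  pairs <- utils::combn(length(trains), 2)
  vals <- apply(pairs, 2, function(ij) {
    sttc(trains[[ij[1]]], trains[[ij[2]]], dt = dt,
         t_start = rec$start_time, t_end = rec$end_time)
  })
  mean(vals)
}

well_active_trains <- function(rec, well, active = NULL) {
  ids <- rec$electrodes$electrode[rec$electrodes$well == well]
  if (!is.null(active)) ids <- intersect(ids, active$electrode[active$active])
  trains <- spike_trains(rec, electrodes = ids)
  trains[lengths(trains) > 0]
}

#' Bin a spike train into equal time intervals
#'
#' @param times sorted spike times (s)
#' @param bin bin width (s), default 0.1
#' @param t_start,t_end recording window (s)
#' @return integer vector of per-bin spike counts, length `ceiling(T/bin)`
#' @export
bin_spike_counts <- function(times, bin = 0.1, t_start = 0, t_end) {
  n_bins <- max(1L, as.integer(ceiling((t_end - t_start) / bin - 1e-9)))
  if (length(times) == 0) return(integer(n_bins))
  idx <- pmin(pmax(floor((times - t_start) / bin) + 1L, 1L), n_bins)
  tabulate(idx, n_bins)
}

#' Shannon entropy of a binned spike train
#'
#' Spike counts in equal time bins are turned into a probability mass
#' function (count divided by the electrode's total spikes); the entropy
#' `H(X) = -sum p(x_i) log2 p(x_i)` measures the disorder of the firing
#' pattern. The normalized variant divides by `log2(n_bins)` so a perfectly
#' uniform train scores 1 and a train firing in a single bin scores 0.
#'
#' @param times sorted spike times (s); empty trains give `NA`
#' @param bin bin width (s), default 0.1
#' @param t_start,t_end recording window (s)
#' @param normalize divide by `log2(n_bins)` (default `TRUE`)
#' @return entropy in bits (or the unitless normalized value)
#' @export
spike_entropy <- function(times, bin = 0.1, t_start = 0, t_end, normalize = TRUE) {
  if (length(times) == 0) return(NA_real_)
  counts <- bin_spike_counts(times, bin, t_start, t_end)
  p <- counts[counts > 0] / sum(counts)
  h <- -sum(p * log2(p))
  if (normalize) h / log2(length(counts)) else h
}

#' Binarize binned spike counts at the 75th percentile
#'
#' Each time bin is classified as burst member (1) or non-member (0): a bin
#' scores 1 iff its spike count is strictly greater than the 75th percentile
#' of counts across all bins of that electrode (linear-interpolation
#' quantile; ties at the percentile map to 0).
#'
#' @param counts integer vector of per-bin spike counts
#' @return integer 0/1 vector of the same length
#' @export
binarize_counts <- function(counts) {
  thr <- stats::quantile(counts, 0.75, names = FALSE, type = 7)
  as.integer(counts > thr)
}

#' Mutual information between two electrodes' binarized bin vectors
#'
#' Both trains are binned on a common grid, binarized with
#' [binarize_counts()], and the mutual information of the resulting 2x2
#' joint distribution is computed in bits:
#' `I(X,Y) = sum_{x,y in {0,1}} p(x,y) log2 p(x,y) / (p(x) p(y))`,
#' with `0 log 0 = 0`. A constant binary vector gives `I = 0`.
#'
#' @param a,b sorted spike-time vectors (s); both non-empty
#' @param bin bin width (s), default 0.1
#' @param t_start,t_end recording window (s)
#' @return mutual information in bits, `>= 0`
#' @export
pairwise_mutual_information <- function(a, b, bin = 0.1, t_start = 0, t_end) {
  if (length(a) == 0 || length(b) == 0) abort("mutual information needs non-empty trains")
  x <- binarize_counts(bin_spike_counts(a, bin, t_start, t_end))
  y <- binarize_counts(bin_spike_counts(b, bin, t_start, t_end))
  binary_mi(x, y)
}

binary_mi <- function(x, y) {
  n <- length(x)
  joint <- tabulate(1L + x + 2L * y, 4L) / n  # cells: 00, 10, 01, 11
  px <- c(joint[1] + joint[3], joint[2] + joint[4])  # P(X=0), P(X=1)
  py <- c(joint[1] + joint[2], joint[3] + joint[4])
  px_cell <- px[c(1, 2, 1, 2)]
  py_cell <- py[c(1, 1, 2, 2)]
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / (px_cell[nz] * py_cell[nz])))
}

#' Pairwise mutual information across a well
#'
#' @param rec an [mea_recording()]
#' @param well well id
#' @param bin bin width (s)
#' @param active optional activity table from [active_electrodes()]
#' @return tibble with one row per active-electrode pair: `electrode_a`,
#'   `electrode_b`, `mi` (bits). The well-level summary feature is the mean
#'   of `mi`; the full distribution is retained for treatment-level tests.
#' @export
well_mutual_information <- function(rec, well, bin = 0.1, active = NULL) {
  trains <- well_active_trains(rec, well, active)
  if (length(trains) < 2) {
    return(tibble(electrode_a = character(), electrode_b = character(), mi = numeric()))
  }
  bins <- lapply(trains, function(tt) {
    binarize_counts(bin_spike_counts(tt, bin, rec$start_time, rec$end_time))
  })
  pairs <- utils::combn(length(trains), 2)
  tibble(
    electrode_a = names(trains)[pairs[1, ]],
    electrode_b = names(trains)[pairs[2, ]],
    mi = apply(pairs, 2, function(ij) binary_mi(bins[[ij[1]]], bins[[ij[2]]]))
  )
}
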