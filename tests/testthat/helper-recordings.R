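# builders for small in-code fixtures

well_labels <- function(n) {
  rows <- LETTERS[1:ceiling(n / 8)]
  paste0(rep(rows, each = 8), rep(1:8, length(rows)))[seq_len(n)]
}

# recording from a named list of spike-time vectors (electrode names carry
# well membership, e.g. "A1_11")
make_recording <- function(trains, end_time = NULL, start_time = 0, label = "rec") {
  sp <- dplyr::bind_rows(purrr::imap(trains, function(tt, e) {
    tibble::tibble(time = tt, electrode = e)
  }))
  el <- meaplate:::parse_electrode_names(names(trains))
  mea_recording(sp, electrodes = el, start_time = start_time,
                end_time = end_time, label = label)
}

# n electrodes in one well, each firing the same times shifted by `shift`
make_well_trains <- function(n, times, well = "A1", shift = 0) {
  els <- paste0(well, "_", rep(1:4, each = 4), rep(1:4, 4))[seq_len(n)]
  stats::setNames(lapply(seq_len(n), function(i) times + (i - 1) * shift), els)
}

# brute-force STTC oracle: explicit double loops and interval union
sttc_oracle <- function(a, b, dt, t_start, t_end) {
  prop_near <- function(x, y) {
    mean(vapply(x, function(xi) any(abs(xi - y) <= dt), logical(1)))
  }
  tiling <- function(s) {
    grid_cov <- function() {
      iv <- cbind(pmax(s - dt, t_start), pmin(s + dt, t_end))
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      tot <- 0; cur <- iv[1, ]
      for (i in seq_len(nrow(iv))[-1]) {
        if (iv[i, 1] <= cur[2]) cur[2] <- max(cur[2], iv[i, 2])
        else { tot <- tot + diff(cur); cur <- iv[i, ] }
      }
      (tot + diff(cur)) / (t_end - t_start)
    }
    grid_cov()
  }
  pa <- prop_near(a, b); pb <- prop_near(b, a)
  ta <- tiling(a); tb <- tiling(b)
  term <- function(p, t) if (1 - p * t == 0) 0 else (p - t) / (1 - p * t)
  0.5 * (term(pa, tb) + term(pb, ta))
}

# brute-force Max Interval oracle: the five rules, written independently
max_interval_oracle <- function(times, p = max_interval_params()) {
  n <- length(times)
  if (n < 2) return(data.frame(start = integer(), end = integer()))
  isi <- diff(times)
  raw <- list(); i <- 1
  while (i <= n - 1) {
    if (isi[i] <= p$max_begin_isi) {
      j <- i
      while (j <= n - 1 && isi[j] <= p$max_end_isi) j <- j + 1
      raw[[length(raw) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(raw) == 0) return(data.frame(start = integer(), end = integer()))
  merged <- list(raw[[1]])
  for (b in raw[-1]) {
    last <- merged[[length(merged)]]
    if (times[b[1]] - times[last[2]] < p$min_ibi) {
      merged[[length(merged)]] <- c(last[1], b[2])
    } else merged[[length(merged) + 1]] <- b
  }
  m <- do.call(rbind, merged)
  keep <- (times[m[, 2]] - times[m[, 1]]) >= p$min_duration &
    (m[, 2] - m[, 1] + 1) >= p$min_spikes
  data.frame(start = m[keep, 1], end = m[keep, 2])
}

# exhaustive Poisson Surprise oracle: scan all spans, best non-overlapping
ps_oracle <- function(times, s_min, rate) {
  n <- length(times)
  best <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- poisson_surprise(j - i + 1, times[j] - times[i], rate)
    if (s >= s_min) best <- rbind(best, c(i, j, s))
  }
  best
}

# area-between-CDFs oracle for EMD / max CDF distance
emd_md_oracle <- function(fa, fb, bw = 1) {
  ca <- cumsum(fa); cb <- cumsum(fb)
  c(emd = sum(abs(ca - cb)) * bw, md = max(abs(ca - cb)))
}

hist_from_freq <- function(freq, bw = 1) {
  structure(list(breaks = seq(0, length(freq) * bw, by = bw),
                 freq = freq, n = 100L), class = "mea_histogram")
}

make_hist_tab <- function(n_wells_per_grp, shift = 0, seed = 1, n_el = 3) {
  set.seed(seed)
  g <- seq(0, 3, length.out = 31)
  wells <- well_labels(2 * n_wells_per_grp)
  rows <- list()
  for (i in seq_along(wells)) {
    mult <- if (i > n_wells_per_grp) 1 + shift else 1
    for (e in 1:n_el) {
      vals <- rgamma(30, shape = 2, rate = 8) * mult
      rows[[length(rows) + 1]] <- tibble::tibble(
        well = wells[i], electrode = paste0(wells[i], "_", e),
        hist = list(normalized_histogram(vals, g)))
    }
  }
  layout <- tibble::tibble(well = wells,
                           treatment = rep(c("WT", "KO"), each = n_wells_per_grp))
  list(tab = dplyr::bind_rows(rows), layout = layout)
}
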