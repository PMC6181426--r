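#' Simulation configuration for synthetic MEA plates
#'
#' Defines the generative model behind every synthetic recording: per
#' electrode, homogeneous Poisson background firing plus injected
#' electrode-level bursts (fixed-ISI spike packets), and well-level network
#' burst (NB) events that place near-coincident burst packets on a sampled
#' subset of the well's electrodes (onsets jittered by up to `nb_jitter` to
#' exercise the smoothing windows). Treatment effects multiply rates per
#' well.
#'
#' Defaults emulate a 48-well plate with 16 electrodes per well recorded
#' for 900 s, 1 Hz background firing, 3 bursts/min per electrode with 6-20
#' spikes at 10 ms intra-burst ISI (100 Hz, far above background), and 2
#' NBs/min with 80% electrode participation.
#'
#' @param n_wells number of wells (default 48; labels A1..F8)
#' @param electrodes_per_well electrodes per well (default 16, positions
#'   11..44)
#' @param duration recording length (s), default 900
#' @param background_rate background Poisson rate (Hz), default 1
#' @param burst_rate electrode burst rate (/min), default 3
#' @param burst_spikes integer range (min, max) of spikes per burst packet,
#'   default `c(6, 20)`
#' @param burst_isi intra-burst ISI (s), default 0.01
#' @param nb_rate NB rate (/min), default 2
#' @param nb_fraction fraction of electrodes participating in each NB,
#'   default 0.8
#' @param nb_jitter max onset jitter per participating electrode (s),
#'   default 0.02
#' @param nb_count_mode `"poisson"` (event count ~ Poisson, default) or
#'   `"fixed"` (exactly `nb_rate * duration / 60` events)
#' @param treatments named list: treatment label -> list of multipliers
#'   (`rate`, `burst_rate`, `nb_rate`, all default 1); wells are assigned to
#'   treatments round-robin. `NULL` gives a single `"control"` treatment.
#' @param seed RNG seed (mandatory)
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_wells = 48, electrodes_per_well = 16, duration = 900,
                       background_rate = 1, burst_rate = 3,
                       burst_spikes = c(6, 20), burst_isi = 0.01,
                       nb_rate = 2, nb_fraction = 0.8, nb_jitter = 0.02,
                       nb_count_mode = c("poisson", "fixed"),
                       treatments = NULL, seed) {
  if (missing(seed)) abort("sim_config requires a seed")
  nb_count_mode <- match.arg(nb_count_mode)
  stopifnot(n_wells >= 1, electrodes_per_well >= 1, duration > 0,
            background_rate >= 0, burst_rate >= 0, nb_rate >= 0,
            nb_fraction >= 0, nb_fraction <= 1)
  if (is.null(treatments)) treatments <- list(control = list())
  structure(list(n_wells = n_wells, electrodes_per_well = electrodes_per_well,
                 duration = duration, background_rate = background_rate,
                 burst_rate = burst_rate, burst_spikes = burst_spikes,
                 burst_isi = burst_isi, nb_rate = nb_rate,
                 nb_fraction = nb_fraction, nb_jitter = nb_jitter,
                 nb_count_mode = nb_count_mode, treatments = treatments,
                 seed = seed),
            class = "sim_config")
}

well_labels <- function(n_wells) {
  rows <- LETTERS[1:ceiling(n_wells / 8)]
  paste0(rep(rows, each = 8), rep(1:8, length(rows)))[seq_len(n_wells)]
}

electrode_labels <- function(well, n_el) {
  side <- ceiling(sqrt(n_el))
  pos <- expand.grid(col = seq_len(side), row = seq_len(side))[seq_len(n_el), ]
  paste0(well, "_", pos$row, pos$col)
}

burst_packet <- function(onset, n, isi) onset + (seq_len(n) - 1) * isi

#' Simulate one plate recording with known ground truth
#'
#' @param config a [sim_config()]
#' @param label recording label
#' @return list with `recording` (an [mea_recording()]), `layout` (tibble
#'   `well`, `treatment`), and `truth`: list of `nb_events` (tibble `well`,
#'   `start_time`, `end_time`, `n_electrodes`) and `bursts` (tibble `well`,
#'   `electrode`, `start_time`, `end_time`)
#' @export
simulate_recording <- function(config, label = "rec1") {
  set.seed(config$seed)
  td <- config$duration
  wells <- well_labels(config$n_wells)
  trt_names <- names(config$treatments)
  layout <- tibble(well = wells,
                   treatment = trt_names[(seq_along(wells) - 1) %% length(trt_names) + 1])

  spikes <- list(); truth_nb <- list(); truth_b <- list()
  for (wi in seq_along(wells)) {
    w <- wells[wi]
    mult <- config$treatments[[layout$treatment[wi]]]
    m_rate <- mult$rate %||% 1
    m_brate <- mult$burst_rate %||% 1
    m_nbrate <- mult$nb_rate %||% 1
    els <- electrode_labels(w, config$electrodes_per_well)

    # well-level NB events
    n_nb <- if (config$nb_count_mode == "fixed") {
      round(config$nb_rate * m_nbrate * td / 60)
    } else {
      stats::rpois(1, config$nb_rate * m_nbrate * td / 60)
    }
    nb_onsets <- sort(stats::runif(n_nb, 0, max(td - 1, 0)))
    nb_rows <- list()
    for (ei in seq_along(els)) {
      e <- els[ei]
      # background
      n_bg <- stats::rpois(1, config$background_rate * m_rate * td)
      tt <- stats::runif(n_bg, 0, td)
      # electrode-level bursts
      n_b <- stats::rpois(1, config$burst_rate * m_brate * td / 60)
      if (n_b > 0) {
        onsets <- stats::runif(n_b, 0, max(td - 1, 0))
        for (o in onsets) {
          nsp <- sample(config$burst_spikes[1]:config$burst_spikes[2], 1)
          pk <- burst_packet(o, nsp, config$burst_isi)
          pk <- pk[pk < td]
          tt <- c(tt, pk)
          truth_b[[length(truth_b) + 1L]] <-
            tibble(well = w, electrode = e, start_time = o, end_time = max(pk))
        }
      }
      # NB participation
      if (n_nb > 0) {
        part <- stats::runif(n_nb) < config$nb_fraction
        for (k in which(part)) {
          o <- nb_onsets[k] + stats::runif(1, 0, config$nb_jitter)
          nsp <- sample(config$burst_spikes[1]:config$burst_spikes[2], 1)
          pk <- burst_packet(o, nsp, config$burst_isi)
          pk <- pk[pk < td]
          tt <- c(tt, pk)
          nb_rows[[length(nb_rows) + 1L]] <- k
        }
      }
      if (length(tt) > 0) {
        spikes[[length(spikes) + 1L]] <-
          tibble(time = sort(tt), electrode = e,
                 amplitude = round(stats::runif(length(tt), 10, 40), 2))
      }
    }
    if (n_nb > 0) {
      part_count <- tabulate(unlist(nb_rows), n_nb)
      max_packet <- (max(config$burst_spikes) - 1) * config$burst_isi + config$nb_jitter
      truth_nb[[length(truth_nb) + 1L]] <-
        tibble(well = w, start_time = nb_onsets,
               end_time = nb_onsets + max_packet,
               n_electrodes = part_count)
    }
  }
  sp <- dplyr::bind_rows(spikes)
  el_all <- dplyr::bind_rows(lapply(wells, function(w) {
    parse_electrode_names(electrode_labels(w, config$electrodes_per_well))
  }))
  rec <- mea_recording(sp, electrodes = el_all, start_time = 0, end_time = td,
                       label = label)
  list(recording = rec, layout = layout,
       truth = list(nb_events = dplyr::bind_rows(truth_nb),
                    bursts = dplyr::bind_rows(truth_b)))
}

#' Simulate a multi-recording experiment and write it to disk
#'
#' Writes `n_recordings` spike-list CSV files (labels `DIV01`, `DIV02`, ...)
#' plus a single layout CSV, all readable by [read_spike_list()] and
#' [read_plate_layout()]. Each recording uses a seed derived
#' deterministically from `config$seed`.
#'
#' @param config a [sim_config()]
#' @param n_recordings number of recordings
#' @param out_dir output directory (created if needed)
#' @return list with `spike_files`, `layout_file`, `truths` (per recording)
#' @export
simulate_experiment <- function(config, n_recordings, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spike_files <- character(n_recordings)
  truths <- vector("list", n_recordings)
  layout_file <- file.path(out_dir, "layout.csv")
  for (i in seq_len(n_recordings)) {
    cfg_i <- config
    cfg_i$seed <- (config$seed + 7919L * i) %% .Machine$integer.max
    lab <- sprintf("DIV%02d", i)
    sim <- simulate_recording(cfg_i, label = lab)
    spike_files[i] <- file.path(out_dir, paste0(lab, "_spike_list.csv"))
    write_spike_list(sim$recording, spike_files[i])
    truths[[i]] <- sim$truth
    if (i == 1) readr::write_csv(sim$layout, layout_file)
  }
  list(spike_files = spike_files, layout_file = layout_file, truths = truths)
}

#' Simulate a well-level MFR feature table directly from spike counts
#'
#' Count-level shortcut for statistical calibration: per electrode the
#' spike count is drawn as `Poisson(rate * duration)` (times the group's
#' effect multiplier) and the well mean firing rate is the mean electrode
#' count divided by the duration — distributionally identical to measuring
#' MFR on fully simulated background spike trains, at a fraction of the
#' cost.
#'
#' @param n_wells_a,n_wells_b wells per treatment group (labels carry
#'   treatments `"A"` and `"B"`)
#' @param n_recordings number of recording columns
#' @param rate background rate (Hz), default 1
#' @param effect multiplicative rate effect applied to group B, default 1
#' @param duration recording length (s), default 900
#' @param electrodes_per_well default 16
#' @param seed RNG seed
#' @return list with `table` (feature table: `well` + recording columns)
#'   and `layout` (tibble `well`, `treatment`)
#' @export
simulate_mfr_table <- function(n_wells_a, n_wells_b, n_recordings, rate = 1,
                               effect = 1, duration = 900,
                               electrodes_per_well = 16, seed) {
  set.seed(seed)
  n_wells <- n_wells_a + n_wells_b
  wells <- well_labels(n_wells)
  treatment <- rep(c("A", "B"), c(n_wells_a, n_wells_b))
  lam <- ifelse(treatment == "A", rate, rate * effect) * duration
  vals <- matrix(NA_real_, n_wells, n_recordings)
  for (r in seq_len(n_recordings)) {
    counts <- stats::rpois(n_wells * electrodes_per_well,
                           rep(lam, each = electrodes_per_well))
    cm <- matrix(counts, nrow = electrodes_per_well)
    vals[, r] <- colMeans(cm) / duration
  }
  tab <- dplyr::bind_cols(tibble(well = wells),
                          as_tibble(stats::setNames(as.data.frame(vals),
                                                    sprintf("DIV%02d", seq_len(n_recordings)))))
  list(table = tab, layout = tibble(well = wells, treatment = treatment))
}
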