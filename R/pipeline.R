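#' Extract every well-level feature set from one recording
#'
#' Runs spike statistics (11, including the synchrony means), burst
#' detection and features (19), network spikes (10) and network bursts
#' (11 per smoothing window) on all wells.
#'
#' @param rec an [mea_recording()]
#' @param min_rate active-electrode criterion (Hz), default 5 spikes/min
#' @param burst_method `"mi"` or `"ps"`, see [detect_bursts()]
#' @param nb_windows NB smoothing windows (ms)
#' @param ns_bin NS detection bin (s)
#' @param sttc_dt,entropy_bin synchrony parameters (s)
#' @return list with tibbles `spikes` (11 statistics), `bursts` (19),
#'   `ns` (10), `nb` (33 for the default windows), `activity` (per-well
#'   active-electrode counts), and `burst_list` (the per-electrode burst
#'   tibbles, for distribution analyses)
#' @export
extract_all_features <- function(rec, min_rate = 5 / 60,
                                 burst_method = c("mi", "ps"),
                                 nb_windows = c(10, 20, 50), ns_bin = 0.010,
                                 sttc_dt = 0.05, entropy_bin = 0.1) {
  burst_method <- match.arg(burst_method)
  active <- active_electrodes(rec, min_rate = min_rate)
  spk <- compute_spike_statistics(rec, active, sttc_dt = sttc_dt,
                                  entropy_bin = entropy_bin)
  bursts <- detect_bursts(rec, method = burst_method)
  bft <- summarize_burst_features(bursts, rec, active = active)
  ns_ev <- detect_network_spikes_all(rec, bin = ns_bin)
  nst <- summarize_network_spikes(ns_ev, rec)
  nb <- detect_network_bursts_all(rec, windows = nb_windows)
  activity <- spk[, c("well", "n_active_electrodes")]
  activity$recording <- rec$label
  list(spikes = spk, bursts = bft, ns = nst, nb = nb$features,
       ns_events = ns_ev, nb_events = nb$events,
       activity = activity, burst_list = bursts)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror the arguments of [run_pipeline()]
#'   (`spike_files`, `layout_file`, `out_dir`, `treatments`, `n_perm`,
#'   `seed`, plus any of the parameter arguments of
#'   [extract_all_features()])
#' @return named list usable as `do.call(run_pipeline, config)`
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run the full multi-recording analysis pipeline
#'
#' Read spike lists and layout; extract spike, burst, network-spike and
#' network-burst features per recording; aggregate into one table per
#' feature (70 tables with the default windows: 8 spike + 19 burst + 10 NS
#' + 33 NB); filter inactive wells; compare the requested treatments with
#' the Mann-Whitney + label-permutation scheme; write feature tables,
#' comparison CSVs/plots and a JSON run manifest.
#'
#' @param spike_files character vector of spike-list CSV paths, or a list
#'   of ready-made [mea_recording()] objects
#' @param layout_file layout CSV path, or a layout tibble
#' @param out_dir output directory; `NULL` skips all file output
#' @param treatments two treatment labels to compare; `NULL` skips the
#'   comparison stage
#' @param n_perm permutations for the comparison, default 100
#' @param seed RNG seed (mandatory when comparing)
#' @param min_ae,min_fraction well filter, see [filter_wells()]
#' @param verbose log stage progress to stderr
#' @param ... passed to [extract_all_features()]
#' @return list with `features` (per-recording extraction results),
#'   `tables` (filtered aggregated feature tables), `comparisons` (named
#'   list of `mea_mw_test`), `layout`, `removed_wells`, `manifest`
#' @export
run_pipeline <- function(spike_files, layout_file, out_dir = NULL,
                         treatments = NULL, n_perm = 100, seed = NULL,
                         min_ae = 4, min_fraction = 0.5, verbose = FALSE,
                         ...) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "read"
  res <- tryCatch({
    layout <- if (is.data.frame(layout_file)) as_tibble(layout_file) else read_plate_layout(layout_file)
    recs <- if (is.list(spike_files) && inherits(spike_files[[1]], "mea_recording")) {
      spike_files
    } else {
      lapply(spike_files, read_spike_list)
    }
    labels <- vapply(recs, function(r) r$label, character(1))
    if (anyDuplicated(labels)) abort("duplicate recording labels")
    names(recs) <- labels
    say("read %d recordings", length(recs))

    stage <- "features"
    feats <- lapply(recs, extract_all_features, ...)
    say("extracted features")

    stage <- "aggregate"
    all_names <- c(spike_feature_names(), burst_feature_names(),
                   ns_feature_names(), nb_feature_names())
    per_rec <- lapply(feats, function(f) {
      dplyr::bind_cols(
        f$spikes[, c("well", spike_feature_names())],
        f$bursts[, burst_feature_names()],
        f$ns[, ns_feature_names()],
        f$nb[, setdiff(names(f$nb), "well")]
      )
    })
    tables <- aggregate_features(per_rec)
    tables <- tables[intersect(c(all_names, names(tables)), names(tables))]

    stage <- "filter"
    activity <- dplyr::bind_rows(lapply(feats, `[[`, "activity"))
    tables <- filter_wells(tables, activity, min_ae = min_ae,
                           min_fraction = min_fraction)
    removed <- attr(tables, "removed_wells")
    say("filtered wells: removed %d", length(removed))

    stage <- "compare"
    comparisons <- NULL
    if (!is.null(treatments)) {
      if (is.null(seed)) abort("a seed is required for the permutation tests")
      comparisons <- purrr::imap(tables, function(tab, f) {
        tryCatch(mw_permutation_test(tab, layout, treatments, n_perm = n_perm,
                                     seed = seed, feature = f),
                 error = function(e) NULL)
      })
      comparisons <- comparisons[!vapply(comparisons, is.null, logical(1))]
      say("compared %d features", length(comparisons))
    }

    stage <- "render"
    manifest <- list(
      n_recordings = length(recs), recordings = unname(labels),
      n_features = length(tables), n_wells_kept = nrow(tables[[1]]),
      removed_wells = removed, n_perm = n_perm, seed = seed,
      treatments = treatments, timestamp = format(Sys.time(), tz = "UTC")
    )
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_feature_tables(tables, file.path(out_dir, "feature_tables"))
      if (!is.null(comparisons)) render_outputs(comparisons, file.path(out_dir, "comparisons"))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
    list(features = feats, tables = tables, comparisons = comparisons,
         layout = layout, removed_wells = removed, manifest = manifest)
  }, error = function(e) {
    abort(paste0("pipeline failed at stage '", stage, "': ", conditionMessage(e)))
  })
  res
}
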