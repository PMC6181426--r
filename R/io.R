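#' Read an Axion-style spike list CSV
#'
#' The spike list format has one row per spike with three columns: spike
#' time (s), electrode name and spike amplitude (mV). Files may carry a
#' header row or be headerless; both are accepted. Amplitudes are parsed
#' and stored but no downstream feature uses them.
#'
#' @param path path to the CSV file
#' @param end_time optional recording end time (s); defaults to
#'   `ceiling(last spike time)`
#' @param start_time optional recording start time (s); defaults to
#'   `min(0, first spike time)`
#' @param label recording label; defaults to the file name without extension
#' @param strict error (rather than return an empty recording) when the file
#'   contains no spikes
#' @param electrode_pattern see [mea_recording()]
#' @return an [mea_recording()]
#' @export
read_spike_list <- function(path, end_time = NULL, start_time = NULL,
                            label = NULL,
                            strict = FALSE,
                            electrode_pattern = default_electrode_pattern()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  has_header <- FALSE
  if (nrow(raw) > 0) {
    first_time <- suppressWarnings(as.numeric(raw[[1]][1]))
    if (is.na(first_time)) has_header <- TRUE
  }
  body <- if (has_header) raw[-1, , drop = FALSE] else raw
  if (nrow(body) == 0) {
    if (strict) abort(paste0("no spikes in ", path))
    return(mea_recording(tibble(time = numeric(), electrode = character()),
                         electrodes = tibble(electrode = character(), well = character(),
                                             pos_row = integer(), pos_col = integer()),
                         start_time = start_time %||% 0, end_time = end_time %||% 1,
                         label = label %||% tools::file_path_sans_ext(basename(path))))
  }
  if (ncol(body) < 2) abort(paste0(path, ": expected at least 2 columns (time, electrode)"))
  times <- suppressWarnings(as.numeric(body[[1]]))
  if (anyNA(times)) {
    bad <- which(is.na(times))[1] + has_header
    abort(sprintf("line %d: unparseable spike time", bad))
  }
  amp <- if (ncol(body) >= 3) suppressWarnings(as.numeric(body[[3]])) else NA_real_
  spikes <- tibble(time = times, electrode = as.character(body[[2]]), amplitude = amp)
  mea_recording(spikes, start_time = start_time, end_time = end_time,
                label = label %||% tools::file_path_sans_ext(basename(path)),
                electrode_pattern = electrode_pattern)
}

#' Read a plate layout file
#'
#' Two-column CSV mapping each well to its treatment label (genotype, drug,
#' concentration, ...). Wells with an empty treatment are kept in the layout
#' but excluded from group comparisons downstream.
#'
#' @param path path to the layout CSV (columns: well, treatment; header
#'   optional)
#' @return tibble with columns `well`, `treatment` (NA when missing)
#' @export
read_plate_layout <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) > 0 && tolower(raw[[1]][1]) %in% c("well", "well_id", "wells")) {
    raw <- raw[-1, , drop = FALSE]
  }
  if (ncol(raw) < 1) abort("layout file is empty")
  well <- as.character(raw[[1]])
  treatment <- if (ncol(raw) >= 2) as.character(raw[[2]]) else NA_character_
  treatment[!is.na(treatment) & treatment == ""] <- NA_character_
  if (anyDuplicated(well)) {
    abort(paste0("duplicate wells in layout: ",
                 paste(unique(well[duplicated(well)]), collapse = ", ")))
  }
  odd <- !grepl("^[A-Za-z]+[0-9]+$", well)
  if (any(odd)) warn(paste0("unusual well names kept verbatim: ",
                            paste(well[odd], collapse = ", ")))
  tibble(well = well, treatment = treatment)
}

#' Read the generic two-file spike format
#'
#' For platforms other than Axion: one file with the spike times recorded on
#' each electrode (columns: electrode, time) and one with the spatial
#' position of each electrode (columns: electrode, x, y). Electrodes listed
#' in the positions file but without spikes are retained as empty trains;
#' electrodes with spikes but no position are an error.
#'
#' @param times_path CSV of electrode, spike time (header optional)
#' @param positions_path CSV of electrode, x, y (header optional)
#' @param end_time,start_time,label see [read_spike_list()]
#' @param electrode_pattern used to parse well membership from electrode
#'   names; names that do not match become their own well
#' @return an [mea_recording()] (amplitudes absent)
#' @export
read_generic_spikes <- function(times_path, positions_path, end_time = NULL,
                                start_time = NULL, label = NULL,
                                electrode_pattern = default_electrode_pattern()) {
  read2 <- function(p) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
    raw <- readr::read_csv(p, col_names = FALSE, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
    if (nrow(raw) > 0 && is.na(suppressWarnings(as.numeric(raw[[2]][1])))) raw <- raw[-1, , drop = FALSE]
    raw
  }
  tr <- read2(times_path)
  pr <- read2(positions_path)
  pos_ids <- as.character(pr[[1]])
  times <- suppressWarnings(as.numeric(tr[[2]]))
  if (anyNA(times)) abort(sprintf("line %d: unparseable spike time", which(is.na(times))[1]))
  sp_ids <- as.character(tr[[1]])
  missing <- setdiff(unique(sp_ids), pos_ids)
  if (length(missing) > 0) {
    abort(paste0("electrodes in times file absent from positions file: ",
                 paste(missing, collapse = ", ")))
  }
  el <- parse_electrode_names(pos_ids, electrode_pattern)
  el$pos_row <- suppressWarnings(as.integer(round(as.numeric(pr[[2]]))))
  if (ncol(pr) >= 3) el$pos_col <- suppressWarnings(as.integer(round(as.numeric(pr[[3]]))))
  mea_recording(tibble(time = times, electrode = sp_ids), electrodes = el,
                start_time = start_time, end_time = end_time,
                label = label %||% tools::file_path_sans_ext(basename(times_path)))
}

#' Write aggregated feature tables to CSV
#'
#' One CSV per feature: wells as rows, recordings as columns, missing cells
#' empty. Rows and columns are written in sorted order so output is
#' deterministic.
#'
#' @param tables named list of feature tables (tibble with a `well` column
#'   plus one column per recording), as produced by [aggregate_features()]
#' @param out_dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_feature_tables <- function(tables, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::imap_chr(tables, function(tab, feature) {
    tab <- tab[order(tab$well), c("well", sort(setdiff(names(tab), "well")))]
    p <- file.path(out_dir, paste0(feature, ".csv"))
    readr::write_csv(tab, p, na = "")
    p
  })
  invisible(unname(paths))
}

#' Write a recording back to spike-list CSV format
#'
#' @param rec an [mea_recording()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_spike_list <- function(rec, path) {
  sp <- rec$spikes[order(rec$spikes$time, rec$spikes$electrode), ]
  readr::write_csv(
    tibble(`Time (s)` = sp$time, Electrode = sp$electrode, `Amplitude (mV)` = sp$amplitude),
    path, na = "")
  invisible(path)
}
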