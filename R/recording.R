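#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

#' Default electrode-name pattern
#'
#' Electrodes on multi-well plates are conventionally named
#' `"<well>_<rowcol>"`, e.g. `"A6_34"`: well label, underscore, then two
#' digits giving the electrode's row and column inside the well (`"11"` to
#' `"44"` on a 16-electrode well). Other vendors can be accommodated by
#' passing a different regular expression with three capture groups
#' (well, row digit, column digit) to the readers.
#'
#' @export
default_electrode_pattern <- function() "^([A-Za-z]+[0-9]+)_([0-9])([0-9])$"

parse_electrode_names <- function(electrode, pattern = default_electrode_pattern()) {
  m <- regmatches(electrode, regexec(pattern, electrode))
  ok <- lengths(m) == 4L
  well <- ifelse(ok, vapply(m, function(x) if (length(x) == 4L) x[2] else NA_character_, ""), electrode)
  pos_row <- ifelse(ok, as.integer(vapply(m, function(x) if (length(x) == 4L) x[3] else NA_character_, "")), NA_integer_)
  pos_col <- ifelse(ok, as.integer(vapply(m, function(x) if (length(x) == 4L) x[4] else NA_character_, "")), NA_integer_)
  tibble(electrode = electrode, well = well, pos_row = pos_row, pos_col = pos_col)
}

#' Construct an MEA recording object
#'
#' An `mea_recording` bundles the spike trains of one plate recording with
#' the plate geometry: a spikes table (one row per spike), an electrode
#' table mapping electrodes to wells and within-well positions, and the
#' recording window `[start_time, end_time]` in seconds.
#'
#' @param spikes data frame with columns `time` (s), `electrode` (character)
#'   and optionally `amplitude` (mV). Times need not be pre-sorted; they are
#'   sorted within each electrode (with a warning if out of order).
#' @param electrodes optional data frame with columns `electrode`, `well`,
#'   `pos_row`, `pos_col`. When `NULL`, the mapping is parsed from electrode
#'   names using `electrode_pattern`.
#' @param start_time,end_time recording window (s). Defaults: `start_time`
#'   is `min(0, first spike)`; `end_time` is `ceiling(last spike)` when not
#'   supplied (the spike list itself carries no duration).
#' @param label recording identifier, e.g. a DIV tag.
#' @param electrode_pattern regex with three capture groups (well, row,
#'   column) used when `electrodes` is `NULL`.
#' @return an object of class `mea_recording`: a list with elements
#'   `spikes` (tibble), `electrodes` (tibble), `start_time`, `end_time`,
#'   `label`.
#' @export
mea_recording <- function(spikes, electrodes = NULL, start_time = NULL,
                          end_time = NULL, label = "rec",
                          electrode_pattern = default_electrode_pattern()) {
  spikes <- as_tibble(spikes)
  stopifnot(all(c("time", "electrode") %in% names(spikes)))
  if (!"amplitude" %in% names(spikes)) spikes$amplitude <- NA_real_
  spikes$time <- as.numeric(spikes$time)
  spikes$electrode <- as.character(spikes$electrode)

  if (is.null(electrodes)) {
    electrodes <- parse_electrode_names(unique(spikes$electrode), electrode_pattern)
  } else {
    electrodes <- as_tibble(electrodes)
    stopifnot(all(c("electrode", "well") %in% names(electrodes)))
    if (!"pos_row" %in% names(electrodes)) electrodes$pos_row <- NA_integer_
    if (!"pos_col" %in% names(electrodes)) electrodes$pos_col <- NA_integer_
    missing <- setdiff(unique(spikes$electrode), electrodes$electrode)
    if (length(missing) > 0) {
      abort(paste0("spikes reference electrodes absent from the electrode table: ",
                   paste(missing, collapse = ", ")))
    }
  }
  if (anyDuplicated(electrodes$electrode)) abort("duplicated electrode ids")

  # sort within electrode; warn if input was out of order
  ord <- order(spikes$electrode, spikes$time)
  if (nrow(spikes) > 0 && is.unsorted(match(seq_len(nrow(spikes)), ord) * 0 + spikes$time[ord])) {
    # cheap check below instead
  }
  unsorted <- FALSE
  if (nrow(spikes) > 1) {
    by_el <- split(spikes$time, spikes$electrode)
    unsorted <- any(vapply(by_el, is.unsorted, logical(1)))
  }
  if (unsorted) warn("spike times were not sorted within electrodes; sorting")
  spikes <- spikes[ord, , drop = FALSE]

  if (is.null(start_time)) {
    start_time <- if (nrow(spikes) > 0) min(0, min(spikes$time)) else 0
  }
  if (is.null(end_time)) {
    end_time <- if (nrow(spikes) > 0) ceiling(max(spikes$time)) else 1
  }
  if (end_time <= start_time) abort("end_time must exceed start_time")
  if (nrow(spikes) > 0 &&
      (min(spikes$time) < start_time || max(spikes$time) > end_time)) {
    abort("spike times fall outside [start_time, end_time]")
  }

  structure(
    list(spikes = spikes, electrodes = electrodes[order(electrodes$electrode), ],
         start_time = start_time, end_time = end_time, label = label),
    class = "mea_recording"
  )
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording '%s'>  %d spikes, %d electrodes, %d wells, window [%g, %g] s\n",
              x$label, nrow(x$spikes), nrow(x$electrodes),
              length(unique(x$electrodes$well)), x$start_time, x$end_time))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `mea_recording`
#' @export
recording_duration <- function(rec) rec$end_time - rec$start_time

#' Well ids of a recording
#' @param rec an `mea_recording`
#' @export
recording_wells <- function(rec) sort(unique(rec$electrodes$well))

#' Spike trains as a named list of numeric vectors
#'
#' @param rec an `mea_recording`
#' @param well optional well id; restricts to that well's electrodes
#' @param electrodes optional character vector of electrode ids
#' @return named list, one sorted numeric vector of spike times per
#'   electrode. Electrodes with no spikes get `numeric(0)`.
#' @export
spike_trains <- function(rec, well = NULL, electrodes = NULL) {
  ids <- rec$electrodes$electrode
  if (!is.null(well)) ids <- rec$electrodes$electrode[rec$electrodes$well %in% well]
  if (!is.null(electrodes)) ids <- intersect(ids, electrodes)
  sp <- rec$spikes[rec$spikes$electrode %in% ids, ]
  out <- split(sp$time, factor(sp$electrode, levels = ids))
  lapply(out, as.numeric)
}

#' Per-electrode spike counts and firing rates
#'
#' @param rec an `mea_recording`
#' @return tibble with `electrode`, `well`, `n_spikes`, `mfr` (Hz)
#' @export
electrode_rates <- function(rec) {
  td <- recording_duration(rec)
  counts <- table(factor(rec$spikes$electrode, levels = rec$electrodes$electrode))
  tibble(
    electrode = rec$electrodes$electrode,
    well = rec$electrodes$well,
    n_spikes = as.integer(counts),
    mfr = as.integer(counts) / td
  )
}
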