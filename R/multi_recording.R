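#' Aggregate per-recording feature values into cross-recording tables
#'
#' Each recording's feature extraction yields one row per well with one
#' column per feature. Aggregation produces one table per feature with
#' recording labels as columns and well labels as rows (missing cells stay
#' `NA`), sorted deterministically.
#'
#' @param per_recording named list (by recording label) of tibbles with a
#'   `well` column plus feature columns
#' @return named list of feature tables (tibble: `well` + one column per
#'   recording)
#' @export
aggregate_features <- function(per_recording) {
  if (anyDuplicated(names(per_recording))) abort("duplicate recording labels")
  long <- dplyr::bind_rows(
    purrr::imap(per_recording, function(tab, lab) {
      tidyr::pivot_longer(tab, -dplyr::all_of("well"),
                          names_to = "feature", values_to = "value") |>
        dplyr::mutate(recording = lab)
    })
  )
  feats <- sort(unique(long$feature))
  labs <- sort(unique(long$recording))
  wells <- sort(unique(long$well))
  out <- lapply(feats, function(f) {
    wide <- tidyr::pivot_wider(long[long$feature == f, c("well", "recording", "value")],
                               names_from = "recording", values_from = "value")
    wide <- dplyr::left_join(tibble(well = wells), wide, by = "well")
    for (l in setdiff(labs, names(wide))) wide[[l]] <- NA_real_
    wide[order(wide$well), c("well", labs)]
  })
  stats::setNames(out, feats)
}

#' Filter inactive wells out of aggregated tables
#'
#' A well counts as active in a recording when it has at least `min_ae`
#' active electrodes there; a well is kept only when it was active in
#' *more than* `min_fraction` of the recordings (strict inequality; the
#' defaults are 4 electrodes and 50%).
#'
#' @param tables named list of feature tables from [aggregate_features()]
#' @param activity tibble with `well`, `recording`, `n_active_electrodes`
#' @param min_ae minimum active electrodes, default 4
#' @param min_fraction minimum fraction of active recordings (strict),
#'   default 0.5
#' @return the tables with failing wells removed; the removed wells are
#'   attached as attribute `"removed_wells"`
#' @export
filter_wells <- function(tables, activity, min_ae = 4, min_fraction = 0.5) {
  act <- activity |>
    dplyr::mutate(active = .data$n_active_electrodes >= min_ae) |>
    dplyr::group_by(.data$well) |>
    dplyr::summarise(frac = mean(.data$active), .groups = "drop")
  keep <- act$well[act$frac > min_fraction]
  removed <- setdiff(act$well, keep)
  out <- lapply(tables, function(tab) tab[tab$well %in% keep, , drop = FALSE])
  attr(out, "removed_wells") <- removed
  out
}

#' Mann-Whitney plus label-permutation treatment comparison
#'
#' For one feature table, each well's observations across recordings are
#' pooled into its treatment's sample and a two-sided Mann-Whitney test
#' (normal approximation with continuity correction) compares the two
#' treatments. Then the well treatment labels are shuffled `n_perm` times
#' (whole wells are reassigned; the observations within each well stay
#' together, preserving within-well correlation across time points) and the
#' permutation p-value is the proportion of permuted MW p-values less than
#' or equal to the observed one.
#'
#' @param table feature table (tibble: `well` + recording columns)
#' @param layout plate layout tibble (`well`, `treatment`)
#' @param treatments the two treatment labels to compare
#' @param n_perm number of shuffles, default 100
#' @param seed RNG seed (required for reproducibility)
#' @param feature optional feature name carried into the result
#' @return object of class `mea_mw_test`: list with `mw_p`, `perm_p`,
#'   `perm_pvalues`, `n_perm`, `treatments`, `summary` (per-recording,
#'   per-treatment mean and SEM tibble), `n_wells`. Has [tidy()] /
#'   [glance()] / [ggplot2::autoplot()] methods.
#' @export
mw_permutation_test <- function(table, layout, treatments, n_perm = 100,
                                seed = NULL, feature = NULL) {
  stopifnot(length(treatments) == 2)
  if (!is.null(seed)) set.seed(seed)
  trt <- stats::setNames(layout$treatment, layout$well)
  tab <- table[table$well %in% layout$well[layout$treatment %in% treatments], ]
  rec_cols <- setdiff(names(tab), "well")
  vals <- as.matrix(tab[, rec_cols, drop = FALSE])
  has_data <- rowSums(!is.na(vals)) > 0
  tab <- tab[has_data, ]; vals <- vals[has_data, , drop = FALSE]
  labels <- unname(trt[tab$well])
  n_by_grp <- base::table(factor(labels, levels = treatments))
  if (min(n_by_grp) < 2) abort("need at least 2 active wells per treatment")

  mw_p <- function(lab) {
    a <- as.vector(vals[lab == treatments[1], ]); a <- a[!is.na(a)]
    b <- as.vector(vals[lab == treatments[2], ]); b <- b[!is.na(b)]
    if (length(unique(c(a, b))) < 2) return(1)
    suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                        exact = FALSE, correct = TRUE)$p.value)
  }
  obs <- mw_p(labels)
  perm <- if (n_perm > 0) vapply(seq_len(n_perm), function(i) mw_p(sample(labels)),
                                 numeric(1)) else numeric(0)
  summary_tab <- tibble(well = tab$well, treatment = labels) |>
    dplyr::bind_cols(as_tibble(vals)) |>
    tidyr::pivot_longer(-c("well", "treatment"),
                        names_to = "recording", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$treatment, .data$recording) |>
    dplyr::summarise(mean = mean(.data$value),
                     sem = stats::sd(.data$value) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  structure(list(
    feature = feature, treatments = treatments, mw_p = obs,
    perm_p = if (n_perm > 0) mean(perm <= obs) else NA_real_,
    perm_pvalues = perm, n_perm = n_perm,
    n_wells = as.integer(n_by_grp), summary = summary_tab
  ), class = "mea_mw_test")
}

#' @export
print.mea_mw_test <- function(x, ...) {
  cat(sprintf("<mea_mw_test%s %s vs %s>  MW p = %.4g, permutation p = %s (%d permutations), wells %d vs %d\n",
              if (is.null(x$feature)) "" else paste0(" ", x$feature),
              x$treatments[1], x$treatments[2], x$mw_p, format(x$perm_p),
              x$n_perm, x$n_wells[1], x$n_wells[2]))
  invisible(x)
}

#' Write comparison tables and plots
#'
#' For each compared feature, writes a CSV with the per-recording,
#' per-treatment mean and SEM plus the MW and permutation p-values, and a
#' PDF plot of treatment means +/- SEM across recordings, into a folder per
#' activity attribute (`spikes/`, `bursts/`, `ns/`, `nb/`).
#'
#' @param comparisons named list (by feature) of `mea_mw_test` objects
#' @param out_dir output directory
#' @param attribute_of optional function mapping a feature name to its
#'   folder; defaults to classification by the canonical feature name lists
#' @return invisibly, the paths written
#' @export
render_outputs <- function(comparisons, out_dir, attribute_of = NULL) {
  if (is.null(attribute_of)) {
    attribute_of <- function(f) {
      if (f %in% spike_feature_names() || f %in% spike_statistic_names()) "spikes"
      else if (f %in% burst_feature_names()) "bursts"
      else if (f %in% ns_feature_names()) "ns"
      else if (f %in% nb_feature_names()) "nb"
      else "other"
    }
  }
  paths <- purrr::imap(comparisons, function(cmp, feature) {
    sub <- file.path(out_dir, attribute_of(feature))
    dir.create(sub, showWarnings = FALSE, recursive = TRUE)
    tab <- cmp$summary
    tab$mw_p <- cmp$mw_p
    tab$perm_p <- cmp$perm_p
    csv <- file.path(sub, paste0(feature, "_comparison.csv"))
    readr::write_csv(tab, csv, na = "")
    pdf_path <- file.path(sub, paste0(feature, ".pdf"))
    p <- ggplot2::autoplot(cmp) + ggplot2::ggtitle(feature)
    suppressMessages(ggplot2::ggsave(pdf_path, p, width = 6, height = 4))
    c(csv, pdf_path)
  })
  invisible(unlist(paths))
}
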