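#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_errorbar
#'   geom_col geom_step labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot treatment means +/- SEM across recordings
#'
#' @param object an `mea_mw_test`
#' @param ... unused
#' @return a ggplot: one line per treatment over recordings, error bars are
#'   SEM, with the MW and permutation p-values in the subtitle
#' @method autoplot mea_mw_test
#' @export
autoplot.mea_mw_test <- function(object, ...) {
  ggplot(object$summary,
         aes(x = .data$recording, y = .data$mean, colour = .data$treatment,
             group = .data$treatment)) +
    geom_line() +
    geom_point() +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem), width = 0.15) +
    labs(x = "recording", y = object$feature %||% "feature value",
         colour = "treatment",
         subtitle = sprintf("MW p = %.3g, permutation p = %s (%d permutations)",
                            object$mw_p, format(object$perm_p), object$n_perm)) +
    theme_minimal()
}

#' Plot normalized and cumulative burst-feature distributions
#'
#' @param hists named list of `mea_histogram` (e.g. from
#'   [aggregate_distributions()]), one per treatment
#' @param feature axis label
#' @param p_values optional named vector (e.g. `c(p_emd = , p_md = )`)
#'   shown in the subtitle
#' @return a ggplot with two panels: normalized frequencies and cumulative
#'   distributions
#' @export
plot_distributions <- function(hists, feature = "burst feature", p_values = NULL) {
  df <- dplyr::bind_rows(purrr::imap(hists, function(h, g) {
    mids <- (h$breaks[-1] + h$breaks[-length(h$breaks)]) / 2
    tibble(group = g, x = mids, freq = h$freq, cum = cumsum(h$freq))
  }))
  long <- tidyr::pivot_longer(df, c("freq", "cum"), names_to = "panel",
                              values_to = "y")
  long$panel <- factor(long$panel, levels = c("freq", "cum"),
                       labels = c("normalized", "cumulative"))
  sub <- if (!is.null(p_values)) {
    paste(names(p_values), signif(p_values, 3), sep = " = ", collapse = ", ")
  }
  ggplot(long, aes(x = .data$x, y = .data$y, colour = .data$group)) +
    geom_step() +
    facet_wrap(~panel, scales = "free_y") +
    labs(x = feature, y = NULL, colour = NULL, subtitle = sub) +
    theme_minimal()
}

#' Raster plot of one well's spike trains
#'
#' @param rec an [mea_recording()]
#' @param well well id
#' @param events optional event tibble (with `start_time`, `end_time`) to
#'   shade, e.g. network bursts
#' @return a ggplot raster: spike times on x, electrodes on y
#' @export
plot_raster <- function(rec, well, events = NULL) {
  ids <- rec$electrodes$electrode[rec$electrodes$well == well]
  sp <- rec$spikes[rec$spikes$electrode %in% ids, ]
  p <- ggplot(sp, aes(x = .data$time, y = .data$electrode)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    labs(x = "time (s)", y = NULL, title = well) +
    theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::annotate("rect", xmin = events$start_time,
                               xmax = events$end_time, ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "red")
  }
  p
}

#' Plot the mean around-peak network spike profile
#'
#' @param ns_features result of [summarize_network_spikes()] (the profile is
#'   carried in its `"profile"` attribute)
#' @param wells optional subset of wells
#' @return a ggplot of mean participating electrodes vs time offset from
#'   the NS peak, one panel per well
#' @export
plot_ns_profile <- function(ns_features, wells = NULL) {
  prof <- attr(ns_features, "profile")
  if (is.null(prof) || nrow(prof) == 0) abort("no around-peak profile available")
  if (!is.null(wells)) prof <- prof[prof$well %in% wells, ]
  ggplot(prof, aes(x = .data$offset, y = .data$mean_electrodes)) +
    geom_col() +
    facet_wrap(~well) +
    labs(x = "time from NS peak (s)", y = "mean participating electrodes") +
    theme_minimal()
}
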