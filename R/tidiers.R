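#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Mann-Whitney permutation comparison
#'
#' @param x an `mea_mw_test`
#' @param ... unused
#' @return the per-recording, per-treatment summary tibble (`treatment`,
#'   `recording`, `mean`, `sem`, `n`) with the feature name attached
#' @method tidy mea_mw_test
#' @export
tidy.mea_mw_test <- function(x, ...) {
  out <- x$summary
  out$feature <- x$feature %||% NA_character_
  out[, c("feature", setdiff(names(out), "feature"))]
}

#' One-row summary of a Mann-Whitney permutation comparison
#'
#' @param x an `mea_mw_test`
#' @param ... unused
#' @return tibble with `feature`, `mw_p`, `perm_p`, `n_perm`,
#'   `n_wells_a`, `n_wells_b`
#' @method glance mea_mw_test
#' @export
glance.mea_mw_test <- function(x, ...) {
  tibble(feature = x$feature %||% NA_character_, mw_p = x$mw_p,
         perm_p = x$perm_p, n_perm = x$n_perm,
         n_wells_a = x$n_wells[1], n_wells_b = x$n_wells[2])
}

#' Tidy a distribution comparison
#'
#' @param x an `mea_dist_test`
#' @param ... unused
#' @return for permutation mode, a tibble of the permuted EMD/MD values
#'   (one row per permutation); for KS mode, a one-row tibble
#' @method tidy mea_dist_test
#' @export
tidy.mea_dist_test <- function(x, ...) {
  if (x$mode == "ks") {
    return(tibble(statistic = x$ks_statistic, p_value = x$ks_p, method = "ks"))
  }
  tibble(permutation = seq_along(x$perm_emd %||% numeric(0)),
         emd = x$perm_emd %||% numeric(0), md = x$perm_md %||% numeric(0))
}

#' One-row summary of a distribution comparison
#'
#' @param x an `mea_dist_test`
#' @param ... unused
#' @return tibble with the observed distances and permutation p-values (or
#'   the KS statistic and p)
#' @method glance mea_dist_test
#' @export
glance.mea_dist_test <- function(x, ...) {
  if (x$mode == "ks") {
    return(tibble(ks_statistic = x$ks_statistic, ks_p = x$ks_p))
  }
  tibble(emd = x$emd, md = x$md, p_emd = x$p_emd, p_md = x$p_md,
         n_perm = x$n_perm)
}
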