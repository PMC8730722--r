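#' Density-score filter for microscopy samples
#'
#' Samples are scored 0-5 for cell density in the imaging well, where 0
#' is very low to no density (fewer than ~50 cells/well) and 5 is too
#' high for reliable segmentation; scores 0 and 5 are excluded.
#'
#' @param samples data frame with `sample` and `density_score`.
#' @return the retained rows (scores 1-4).
#' @export
density_filter <- function(samples) {
  s <- samples$density_score
  if (any(is.na(s) | s < 0 | s > 5)) {
    stop("validation error: density scores must lie in 0-5",
         call. = FALSE)
  }
  samples[s %in% 1:4, , drop = FALSE]
}

#' Cell-size phenotype call from binucleate cell lengths
#'
#' Fold change of the median binucleated-cell length of a mutant sample
#' relative to wild type, with a two-sided Wilcoxon rank-sum test on
#' the per-cell length distributions. A size phenotype is called when
#' the fold change deviates from 1 by at least `size_threshold` (5%)
#' and p < `alpha`.
#'
#' @param mutant,wildtype per-cell data frames (`length_um`, `nuclei`).
#' @param size_threshold minimal relative difference in median length.
#' @param alpha significance level.
#' @param min_cells minimal number of binucleated cells per group.
#' @return one-row data frame: n_mutant, n_wildtype, median_mutant,
#'   median_wildtype, fold_change, p_value, call
#'   (`"longer"`/`"shorter"`/`"none"`, NA when not assessable).
#' @export
size_phenotype <- function(mutant, wildtype, size_threshold = 0.05,
                           alpha = 0.05, min_cells = 20L) {
  ml <- mutant$length_um[mutant$nuclei == 2L]
  wl <- wildtype$length_um[wildtype$nuclei == 2L]
  out <- data.frame(n_mutant = length(ml), n_wildtype = length(wl),
                    median_mutant = NA_real_, median_wildtype = NA_real_,
                    fold_change = NA_real_, p_value = NA_real_,
                    call = NA_character_, stringsAsFactors = FALSE)
  if (length(ml) < min_cells || length(wl) < min_cells) return(out)
  out$median_mutant <- stats::median(ml)
  out$median_wildtype <- stats::median(wl)
  out$fold_change <- out$median_mutant / out$median_wildtype
  out$p_value <- stats::wilcox.test(ml, wl, exact = FALSE)$p.value
  hit <- abs(out$fold_change - 1) >= size_threshold &
    out$p_value < alpha
  out$call <- if (!hit) "none" else if (out$fold_change > 1) "longer"
              else "shorter"
  out
}

#' Cell-cycle phenotype call from per-field binucleate percentages
#'
#' Computes the percentage of binucleated cells in every microscopic
#' field, compares mutant and wild-type median per-field percentages by
#' fold change and a two-sided Wilcoxon rank-sum test, and calls a
#' cell-cycle phenotype when the fold change deviates from 1 by at
#' least `binuc_threshold` (20%) with p < `alpha`. Fields without
#' cells are excluded.
#'
#' @param mutant,wildtype per-cell data frames (`field`, `nuclei`).
#' @param binuc_threshold minimal relative difference in binucleate
#'   percentage.
#' @param alpha significance level.
#' @param min_fields minimal number of non-empty fields per group.
#' @return one-row data frame: n_fields_mutant, n_fields_wildtype,
#'   median_pct_mutant, median_pct_wildtype, fold_change, p_value,
#'   call (`"more_binucleates"`/`"fewer_binucleates"`/`"none"`).
#' @export
cellcycle_phenotype <- function(mutant, wildtype, binuc_threshold = 0.20,
                                alpha = 0.05, min_fields = 10L) {
  field_pct <- function(cells) {
    pct <- tapply(cells$nuclei == 2L, cells$field, mean) * 100
    pct[!is.na(pct)]
  }
  mp <- field_pct(mutant)
  wp <- field_pct(wildtype)
  out <- data.frame(n_fields_mutant = length(mp),
                    n_fields_wildtype = length(wp),
                    median_pct_mutant = NA_real_,
                    median_pct_wildtype = NA_real_,
                    fold_change = NA_real_, p_value = NA_real_,
                    call = NA_character_, stringsAsFactors = FALSE)
  if (length(mp) < min_fields || length(wp) < min_fields) return(out)
  out$median_pct_mutant <- stats::median(mp)
  out$median_pct_wildtype <- stats::median(wp)
  if (out$median_pct_wildtype == 0) return(out)
  out$fold_change <- out$median_pct_mutant / out$median_pct_wildtype
  out$p_value <- stats::wilcox.test(mp, wp, exact = FALSE)$p.value
  hit <- abs(out$fold_change - 1) >= binuc_threshold &
    out$p_value < alpha
  out$call <- if (!hit) "none" else if (out$fold_change > 1)
    "more_binucleates" else "fewer_binucleates"
  out
}

#' Agreement between microscopy and flow-cytometry readouts
#'
#' Pearson correlation between the microscopy-derived binucleate
#' fraction and the flow-cytometry-derived G1 + S population fraction
#' (binucleated cells are in G1/S, so the two should co-vary) across
#' paired samples.
#'
#' @param binucleate_fraction,g1s_fraction paired numeric vectors.
#' @return Pearson r (`NA` when fewer than 3 pairs or zero variance).
#' @export
microscopy_flow_agreement <- function(binucleate_fraction, g1s_fraction) {
  stopifnot(length(binucleate_fraction) == length(g1s_fraction))
  ok <- !is.na(binucleate_fraction) & !is.na(g1s_fraction)
  x <- binucleate_fraction[ok]
  y <- g1s_fraction[ok]
  if (length(x) < 3L) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
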