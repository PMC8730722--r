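#' Mating efficiency from meiotic cell-fate counts
#'
#' Mating efficiency is the fraction of cells that committed to mating,
#' computed from counts of non-mating cells, zygotes, asci and free
#' spores as
#' \deqn{\frac{2(z + a) + s/2}{2(z + a) + s/2 + n}}
#' where z = zygotes, a = asci, s = free spores (four per completed
#' meiosis, hence the factor 1/2 per originating cell) and n =
#' non-mating cells. At least 500 counted cells per sample are
#' recommended.
#'
#' @param counts a `meiosis_counts` (see [simulate_meiosis_counts()])
#'   or any list/data frame with fields `non_mating_cells`, `zygotes`,
#'   `asci`, `free_spores`.
#' @return mating efficiency in \[0, 1\].
#' @export
mating_efficiency <- function(counts) {
  z <- counts$zygotes
  a <- counts$asci
  s <- counts$free_spores
  n <- counts$non_mating_cells
  if (any(c(z, a, s, n) < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  mated <- 2 * (z + a) + s / 2
  denom <- mated + n
  if (any(denom == 0)) {
    stop("undefined mating efficiency: all counts are zero",
         call. = FALSE)
  }
  mated / denom
}

#' Spore viability from plating counts
#'
#' Proportion of plated spores that formed colonies. Counts from
#' several plates of the same sample are pooled (sum of colonies over
#' sum of spores); per-plate proportions are also returned. A colony
#' count exceeding the spores plated is a miscount: it triggers a
#' warning and the pooled proportion is capped at 1 in the report while
#' the raw value is preserved.
#'
#' @param colonies_formed,spores_plated numeric vectors (one entry per
#'   plate).
#' @return list with `viability` (pooled, capped at 1), `raw` (pooled,
#'   uncapped), `per_plate` (vector of per-plate proportions).
#' @export
spore_viability <- function(colonies_formed, spores_plated) {
  stopifnot(length(colonies_formed) == length(spores_plated))
  if (any(spores_plated <= 0)) {
    stop("spores_plated must be positive", call. = FALSE)
  }
  if (any(colonies_formed < 0)) {
    stop("colonies_formed must be non-negative", call. = FALSE)
  }
  raw <- sum(colonies_formed) / sum(spores_plated)
  if (any(colonies_formed > spores_plated)) {
    warning("more colonies than spores plated: probable miscount; ",
            "pooled viability capped at 1", call. = FALSE)
  }
  list(viability = min(raw, 1), raw = raw,
       per_plate = colonies_formed / spores_plated)
}
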