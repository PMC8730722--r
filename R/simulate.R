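#' Configuration for a synthetic colony-array experiment
#'
#' Defines the study conditions emulated by [simulate_experiment()]:
#' plate format (384 colonies with a 96-position wild-type reference
#' grid), replicate structure, measurement noise, spatial/batch
#' structure and the injected strain effects (the ground truth).
#'
#' Defaults follow the screening design the pipeline is built for:
#' nine biological repeats with two technical repeats (independently
#' pinned colonies) each, wild-type colony-size coefficient of variation
#' 0.050 and redness coefficient of variation 0.007.
#'
#' @param strains character vector of library strain ids.
#' @param conditions either a character vector (first element taken as
#'   the benign control condition) or a data frame with columns
#'   `condition`, `is_control`, `control_condition`, `stressor_set`.
#' @param strain_effects optional data frame (`strain`, `condition`,
#'   `growth`, and optionally `redness`) of multiplicative effects;
#'   pairs not listed are neutral (multiplier 1).
#' @param n_bio,n_tech biological and technical repeats per strain.
#' @param wt_size_cv,wt_redness_cv lognormal noise CV for colony size
#'   and redness.
#' @param spatial list with elements `slope_row`, `slope_col` (maximal
#'   relative plane gradients across the plate; each plate draws its
#'   slopes uniformly within these bounds), `bump_amp` (relative
#'   amplitude of one smooth Gaussian bump at a random centre) and
#'   `bump_sd` (bump width in grid units). All zero gives flat plates.
#' @param batch_sd standard deviation (log scale) of the per-batch
#'   multiplicative plate factor.
#' @param p_missing,p_artifact per-colony probabilities of a pinning
#'   failure (size 0) and of a low-circularity shape artifact.
#' @param base_size mean raw colony size in area units.
#' @param redness logical; also simulate the phloxine-B redness readout.
#' @param seed integer RNG seed; a fixed seed makes the simulated
#'   experiment fully reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(strains, conditions,
                       strain_effects = NULL,
                       n_bio = 9L, n_tech = 2L,
                       wt_size_cv = 0.050, wt_redness_cv = 0.007,
                       spatial = list(slope_row = 0, slope_col = 0,
                                      bump_amp = 0, bump_sd = 4),
                       batch_sd = 0, p_missing = 0, p_artifact = 0,
                       base_size = 100, redness = FALSE, seed = 1L) {
  stopifnot(is.character(strains), length(strains) >= 1L)
  if (is.character(conditions)) {
    conditions <- data.frame(
      condition = conditions,
      is_control = seq_along(conditions) == 1L,
      control_condition = conditions[1L],
      stressor_set = conditions,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("condition", "is_control", "control_condition",
                  "stressor_set") %in% names(conditions)))
  if (!any(conditions$is_control)) {
    stop("configuration error: at least one condition must be flagged ",
         "as control", call. = FALSE)
  }
  bad_link <- setdiff(conditions$control_condition,
                      conditions$condition[conditions$is_control])
  if (length(bad_link)) {
    stop("configuration error: control link(s) not a control condition: ",
         paste(bad_link, collapse = ", "), call. = FALSE)
  }
  for (cv in c(wt_size_cv, wt_redness_cv)) {
    if (cv < 0 || cv >= 1) stop("CVs must lie in [0, 1)", call. = FALSE)
  }
  for (p in c(p_missing, p_artifact)) {
    if (p < 0 || p >= 1) {
      stop("probabilities must lie in [0, 1)", call. = FALSE)
    }
  }
  spatial <- utils::modifyList(
    list(slope_row = 0, slope_col = 0, bump_amp = 0, bump_sd = 4),
    spatial
  )
  if (abs(spatial$slope_row) + abs(spatial$slope_col) >= 1.9 ||
      spatial$bump_amp <= -1) {
    stop("spatial surface parameters would allow non-positive surfaces",
         call. = FALSE)
  }
  if (!is.null(strain_effects)) {
    stopifnot(all(c("strain", "condition", "growth")
                  %in% names(strain_effects)))
    unknown <- setdiff(strain_effects$strain, strains)
    if (length(unknown)) {
      stop("key error: strain_effects reference unknown strain(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    unknown_c <- setdiff(strain_effects$condition, conditions$condition)
    if (length(unknown_c)) {
      stop("key error: strain_effects reference unknown condition(s): ",
           paste(unknown_c, collapse = ", "), call. = FALSE)
    }
    if (any(strain_effects$growth <= 0)) {
      stop("growth multipliers must be strictly positive", call. = FALSE)
    }
    if (!is.null(strain_effects$redness) &&
        any(strain_effects$redness <= 0)) {
      stop("redness multipliers must be strictly positive", call. = FALSE)
    }
  }
  structure(list(
    strains = strains, conditions = conditions,
    strain_effects = strain_effects,
    n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
    wt_size_cv = wt_size_cv, wt_redness_cv = wt_redness_cv,
    spatial = spatial, batch_sd = batch_sd,
    p_missing = p_missing, p_artifact = p_artifact,
    base_size = base_size, redness = redness, seed = as.integer(seed)
  ), class = "sim_config")
}

# sdlog such that a lognormal has coefficient of variation cv
lognormal_sdlog <- function(cv) sqrt(log(1 + cv^2))

# multiplicative plate surface: plane times one Gaussian bump
plate_surface <- function(row, col, slopes, bump, n_rows = 16L,
                          n_cols = 24L) {
  plane <- 1 + slopes[1] * (row - (n_rows + 1) / 2) / (n_rows - 1) +
    slopes[2] * (col - (n_cols + 1) / 2) / (n_cols - 1)
  bumpf <- 1 + bump$amp *
    exp(-((row - bump$r0)^2 + (col - bump$c0)^2) / (2 * bump$sd^2))
  plane * bumpf
}

#' Simulate a full colony-array experiment with known ground truth
#'
#' Generates raw quantified colony tables for every plate of a screening
#' experiment: one plate per condition x biological repeat (x layout
#' chunk when the library does not fit on a single 384 plate), each with
#' the 96-colony wild-type reference grid, per-plate multiplicative
#' spatial surface, per-batch factor, lognormal measurement noise,
#' injected strain effects, random pinning failures and shape artifacts.
#'
#' @param config a [sim_config()].
#' @return A list of class `phenomics_experiment` with elements
#'   `colonies` (tidy colony table: plate_id, condition, batch, bio_rep,
#'   tech_rep, row, col, strain, ref, size, circularity and optionally
#'   redness), `layouts` (list of `plate_layout`s), `design` (plate
#'   design table), `conditions`, and `truth` (injected log2 effects,
#'   per-plate surfaces, missing/artifact positions).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_tech <- config$n_tech
  slots_per_plate <- 288L

  # layout chunks: each strain occupies n_tech adjacent slots
  strain_slots <- rep(config$strains, each = n_tech)
  n_chunks <- max(1L, ceiling(length(strain_slots) / slots_per_plate))
  layouts <- vector("list", n_chunks)
  for (k in seq_len(n_chunks)) {
    idx <- seq.int((k - 1L) * slots_per_plate + 1L,
                   min(k * slots_per_plate, length(strain_slots)))
    layouts[[k]] <- standard384_layout(strain_slots[idx], randomize = TRUE)
  }

  conds <- config$conditions
  design <- expand.grid(chunk = seq_len(n_chunks),
                        bio_rep = seq_len(config$n_bio),
                        condition = conds$condition,
                        KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  design$batch <- design$bio_rep
  design$plate_id <- sprintf("%s_b%02d_c%02d", design$condition,
                             design$bio_rep, design$chunk)
  design$layout <- design$chunk
  design <- design[c("plate_id", "condition", "batch", "bio_rep", "layout")]

  # effect lookup tables (multiplier 1 when unlisted)
  eff_key <- function(strain, condition) paste(strain, condition, sep = "\r")
  growth_mult <- redness_mult <- NULL
  if (!is.null(config$strain_effects)) {
    se <- config$strain_effects
    growth_mult <- stats::setNames(se$growth, eff_key(se$strain, se$condition))
    if (!is.null(se$redness)) {
      redness_mult <- stats::setNames(se$redness,
                                      eff_key(se$strain, se$condition))
    }
  }

  batch_factor <- exp(stats::rnorm(config$n_bio, 0, config$batch_sd))
  sp <- config$spatial

  pieces <- vector("list", nrow(design))
  surfaces <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    lay <- layouts[[design$layout[i]]]
    n <- nrow(lay)
    slopes <- c(stats::runif(1, -sp$slope_row, sp$slope_row),
                stats::runif(1, -sp$slope_col, sp$slope_col))
    bump <- list(amp = sp$bump_amp, sd = sp$bump_sd,
                 r0 = stats::runif(1, 1, 16), c0 = stats::runif(1, 1, 24))
    surf <- plate_surface(lay$row, lay$col, slopes, bump)
    surfaces[[i]] <- surf

    mult <- rep(1, n)
    if (!is.null(growth_mult)) {
      m <- growth_mult[eff_key(lay$strain, design$condition[i])]
      mult[!is.na(m)] <- m[!is.na(m)]
    }
    noise <- exp(stats::rnorm(n, 0, lognormal_sdlog(config$wt_size_cv)))
    size <- config$base_size * batch_factor[design$bio_rep[i]] *
      surf * mult * noise
    size[is.na(lay$strain)] <- 0  # empty positions read as pinning failures

    circularity <- stats::runif(n, 0.90, 0.99)
    artifact <- stats::runif(n) < config$p_artifact & size > 0
    circularity[artifact] <- stats::runif(sum(artifact), 0.50, 0.849)
    missing <- stats::runif(n) < config$p_missing
    size[missing] <- 0

    piece <- data.frame(
      plate_id = design$plate_id[i], condition = design$condition[i],
      batch = design$batch[i], bio_rep = design$bio_rep[i],
      row = lay$row, col = lay$col, strain = lay$strain, ref = lay$ref,
      size = size, circularity = circularity, stringsAsFactors = FALSE
    )
    if (config$redness) {
      rmult <- rep(1, n)
      if (!is.null(redness_mult)) {
        m <- redness_mult[eff_key(lay$strain, design$condition[i])]
        rmult[!is.na(m)] <- m[!is.na(m)]
      }
      rnoise <- exp(stats::rnorm(n, 0,
                                 lognormal_sdlog(config$wt_redness_cv)))
      piece$redness <- 0.5 * batch_factor[design$bio_rep[i]] * surf *
        rmult * rnoise
      piece$redness[size == 0] <- NA_real_
    }
    # technical repeat index: copy number of each strain on the plate
    piece$tech_rep <- stats::ave(seq_len(n), piece$strain,
                                 FUN = seq_along)
    piece$tech_rep[lay$ref | is.na(lay$strain)] <- NA_integer_
    pieces[[i]] <- piece
  }
  colonies <- do.call(rbind, pieces)
  rownames(colonies) <- NULL

  truth_eff <- expand.grid(strain = config$strains,
                           condition = conds$condition,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth_eff$log2_growth <- 0
  truth_eff$log2_redness <- 0
  if (!is.null(config$strain_effects)) {
    se <- config$strain_effects
    m <- match(eff_key(truth_eff$strain, truth_eff$condition),
               eff_key(se$strain, se$condition))
    truth_eff$log2_growth[!is.na(m)] <- log2(se$growth[m[!is.na(m)]])
    if (!is.null(se$redness)) {
      truth_eff$log2_redness[!is.na(m)] <- log2(se$redness[m[!is.na(m)]])
    }
  }
  names(surfaces) <- design$plate_id
  missing_tab <- colonies[colonies$size == 0,
                          c("plate_id", "row", "col"), drop = FALSE]
  artifact_tab <- colonies[colonies$size > 0 & colonies$circularity < 0.85,
                           c("plate_id", "row", "col"), drop = FALSE]
  rownames(missing_tab) <- rownames(artifact_tab) <- NULL

  structure(list(
    colonies = colonies, layouts = layouts, design = design,
    conditions = conds,
    truth = list(effects = truth_eff, surfaces = surfaces,
                 missing = missing_tab, artifacts = artifact_tab),
    config = config
  ), class = "phenomics_experiment")
}

#' @export
print.phenomics_experiment <- function(x, ...) {
  cat("Synthetic colony-array experiment\n")
  cat("  plates:    ", nrow(x$design), "\n")
  cat("  conditions:", nrow(x$conditions), "\n")
  cat("  strains:   ", length(x$config$strains), "\n")
  cat("  colonies:  ", nrow(x$colonies), "\n")
  invisible(x)
}

#' Simulate per-cell high-throughput microscopy tables
#'
#' Emulates the imaging readout used for cell-size and cell-cycle
#' phenotyping: for each sample, 63 microscopic fields of cells with a
#' length (lognormal around the sample median) and a nuclei count (1 or
#' 2), plus a per-sample density score on the 0-5 scale used for sample
#' QC. Wild-type defaults: median binucleate length 9.7 um and 13.2%
#' binucleated cells.
#'
#' @param n_samples number of samples to simulate (named `S001`, ...).
#' @param wt_median_length_um wild-type median cell length (um).
#' @param wt_binucleate_fraction wild-type fraction of binucleated cells.
#' @param effects optional data frame (`sample`, `length_fold`,
#'   `binuc_fold`) of multiplicative effects; unlisted samples are
#'   neutral (wild-type-like).
#' @param n_fields microscopic fields per sample (default 63).
#' @param cells_per_field mean cells per field (Poisson).
#' @param length_cv lognormal CV of cell length around the sample median.
#' @param density_scores optional integer vector (0-5) per sample;
#'   drawn from 1-4 when `NULL`.
#' @param seed integer RNG seed.
#' @return list with `cells` (sample, field, length_um, nuclei) and
#'   `samples` (sample, density_score and the true injected effects).
#' @export
simulate_cell_samples <- function(n_samples,
                                  wt_median_length_um = 9.7,
                                  wt_binucleate_fraction = 0.132,
                                  effects = NULL,
                                  n_fields = 63L, cells_per_field = 35,
                                  length_cv = 0.14,
                                  density_scores = NULL, seed = 1L) {
  if (n_fields <= 0) stop("n_fields must be positive", call. = FALSE)
  if (wt_median_length_um <= 0) stop("lengths must be positive",
                                     call. = FALSE)
  if (wt_binucleate_fraction <= 0 || wt_binucleate_fraction >= 1) {
    stop("wt_binucleate_fraction must lie in (0, 1)", call. = FALSE)
  }
  set.seed(seed)
  samples <- sprintf("S%03d", seq_len(n_samples))
  length_fold <- rep(1, n_samples)
  binuc_fold <- rep(1, n_samples)
  if (!is.null(effects)) {
    m <- match(effects$sample, samples)
    if (anyNA(m)) stop("effects reference unknown sample(s)", call. = FALSE)
    if (!is.null(effects$length_fold)) length_fold[m] <- effects$length_fold
    if (!is.null(effects$binuc_fold)) binuc_fold[m] <- effects$binuc_fold
  }
  if (is.null(density_scores)) {
    density_scores <- sample(1:4, n_samples, replace = TRUE)
  }
  stopifnot(all(density_scores %in% 0:5))

  sdlog <- lognormal_sdlog(length_cv)
  cells <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    ncell <- stats::rpois(n_fields, cells_per_field)
    field <- rep(seq_len(n_fields), ncell)
    n <- length(field)
    len <- stats::rlnorm(n, log(wt_median_length_um * length_fold[i]), sdlog)
    p2 <- min(0.99, wt_binucleate_fraction * binuc_fold[i])
    nuc <- 1L + stats::rbinom(n, 1L, p2)
    cells[[i]] <- data.frame(sample = samples[i], field = field,
                             length_um = len, nuclei = nuc,
                             stringsAsFactors = FALSE)
  }
  list(
    cells = do.call(rbind, cells),
    samples = data.frame(sample = samples, density_score = density_scores,
                         true_length_fold = length_fold,
                         true_binuc_fold = binuc_fold,
                         stringsAsFactors = FALSE)
  )
}

#' Simulate meiotic differentiation counts
#'
#' Generates cell-fate counts (non-mating cells, zygotes, asci, free
#' spores) consistent with a given true mating efficiency, and a
#' binomial viable-colony count for spores plated at a given true spore
#' viability.
#'
#' @param true_mating_efficiency,true_spore_viability true proportions
#'   in \[0, 1\].
#' @param n_cells number of cells scored (>= 500 recommended).
#' @param n_spores_plated number of spores plated.
#' @param seed integer RNG seed.
#' @return list of class `meiosis_counts` with fields `non_mating_cells`,
#'   `zygotes`, `asci`, `free_spores`, `spores_plated`,
#'   `colonies_formed`, plus the truths.
#' @export
simulate_meiosis_counts <- function(true_mating_efficiency,
                                    true_spore_viability,
                                    n_cells, n_spores_plated, seed = 1L) {
  if (n_cells <= 0 || n_spores_plated <= 0) {
    stop("n_cells and n_spores_plated must be positive", call. = FALSE)
  }
  stopifnot(true_mating_efficiency >= 0, true_mating_efficiency <= 1,
            true_spore_viability >= 0, true_spore_viability <= 1)
  n_cells <- as.integer(n_cells)
  n_spores_plated <- as.integer(n_spores_plated)
  set.seed(seed)
  non_mating <- stats::rbinom(1L, n_cells, 1 - true_mating_efficiency)
  mating <- n_cells - non_mating
  fusions <- mating %/% 2L
  fate <- if (fusions > 0) {
    drop(stats::rmultinom(1L, fusions, c(0.35, 0.35, 0.30)))
  } else c(0L, 0L, 0L)
  spores <- 4L * fate[3L] + 2L * (mating %% 2L)
  colonies <- stats::rbinom(1L, n_spores_plated, true_spore_viability)
  structure(list(
    non_mating_cells = non_mating, zygotes = fate[1L], asci = fate[2L],
    free_spores = spores, spores_plated = n_spores_plated,
    colonies_formed = colonies,
    true_mating_efficiency = true_mating_efficiency,
    true_spore_viability = true_spore_viability
  ), class = "meiosis_counts")
}
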