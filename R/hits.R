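#' Welch's two-sample t-test
#'
#' Welch's unequal-variance t-test (two-sided), the test used for all
#' mutant-vs-baseline fitness comparisons. Degenerate inputs follow a
#' documented convention: if both samples have zero variance the test
#' returns p = 1 for equal means and p = 0 (t = +/-Inf) for unequal
#' means.
#'
#' @param a,b numeric vectors (NAs dropped), each with at least two
#'   values.
#' @return list with elements `t`, `df` and two-sided `p`.
#' @export
welch_test <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("welch_test needs at least 2 values per sample", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2L, p = 0))
  }
  ht <- stats::t.test(a, b)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Benjamini-Hochberg adjustment within groups
#'
#' Step-up false-discovery-rate adjustment applied separately within
#' each group (conventionally: within each condition).
#'
#' @param p numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @param groups optional grouping vector (same length as `p`); `NULL`
#'   treats all p-values as one family.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p, groups = NULL) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("validation error: p-values must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(groups)) return(stats::p.adjust(p, method = "BH"))
  stopifnot(length(groups) == length(p))
  out <- rep(NA_real_, length(p))
  for (idx in split(seq_along(p), groups)) {
    out[idx] <- stats::p.adjust(p[idx], method = "BH")
  }
  out
}

#' Summarize replicate fitness per strain and condition
#'
#' Computes, for every strain x condition, the median effect size (MES)
#' and a Welch test against the appropriate baseline, then adjusts
#' p-values per condition with Benjamini-Hochberg:
#'
#' * deletion mode, control (benign) conditions: mutant colonies vs the
#'   wild-type control colonies in the same condition; MES =
#'   median(mutant) / median(wild type);
#' * deletion mode, stress conditions: mutant colonies in the stress
#'   condition vs the same mutant in the linked control condition;
#' * overexpression mode: the empty-vector control strain replaces the
#'   wild type as baseline, and in stress conditions every strain's
#'   colony fitness is first divided by that strain's median fitness in
#'   the linked benign condition.
#'
#' Tests are run on colony-level fitness values pooled across
#' biological and technical replicates. Pairs with fewer than two
#' observations on either side are reported with the test fields
#' absent.
#'
#' @param dataset normalized, QC-filtered tidy dataset.
#' @param conditions conditions metadata (`condition`, `is_control`,
#'   `control_condition`, `stressor_set`); see [design_conditions()].
#' @param mode `"deletion"` or `"overexpression"`.
#' @param readout `"size"` or `"redness"`.
#' @param empty_vector strain id of the empty-vector control
#'   (overexpression mode).
#' @return data frame of class `strain_summary`: strain, condition,
#'   readout, baseline kind, MES, log2_MES, observation_count, welch_t,
#'   welch_df, p_value, adjusted_p.
#' @export
summarize_effects <- function(dataset, conditions,
                              mode = c("deletion", "overexpression"),
                              readout = c("size", "redness"),
                              empty_vector = "empty_vector") {
  mode <- match.arg(mode)
  readout <- match.arg(readout)
  fit_col <- paste0("fitness_", readout)
  stopifnot(fit_col %in% names(dataset))
  missing_ctrl <- setdiff(conditions$control_condition,
                          conditions$condition)
  if (length(missing_ctrl)) {
    stop("design error: missing linked control condition(s): ",
         paste(missing_ctrl, collapse = ", "), call. = FALSE)
  }

  fit <- dataset[[fit_col]]
  usable <- !is.na(fit) & !is.na(dataset$strain)
  mut_rows <- usable & !dataset$ref
  key <- function(s, cond) paste(s, cond, sep = "\r")
  mut_vals <- split(fit[mut_rows],
                    key(dataset$strain[mut_rows],
                        dataset$condition[mut_rows]))
  wt_vals <- split(fit[usable & dataset$ref],
                   dataset$condition[usable & dataset$ref])

  is_ctrl <- stats::setNames(conditions$is_control, conditions$condition)
  ctrl_of <- stats::setNames(conditions$control_condition,
                             conditions$condition)

  # overexpression: per-strain median fitness in the linked benign
  # condition, used to renormalize stress-condition colonies
  benign_med <- NULL
  if (mode == "overexpression") {
    benign_med <- vapply(mut_vals, stats::median, numeric(1))
  }

  pairs <- unique(data.frame(
    strain = dataset$strain[mut_rows],
    condition = dataset$condition[mut_rows],
    stringsAsFactors = FALSE))
  if (mode == "overexpression") {
    pairs <- pairs[pairs$strain != empty_vector, , drop = FALSE]
  }

  n <- nrow(pairs)
  res <- data.frame(
    strain = pairs$strain, condition = pairs$condition,
    readout = readout,
    baseline = NA_character_, MES = NA_real_, log2_MES = NA_real_,
    observation_count = 0L, welch_t = NA_real_, welch_df = NA_real_,
    p_value = NA_real_, stringsAsFactors = FALSE)

  get_pair_values <- function(strain, cond) {
    v <- mut_vals[[key(strain, cond)]]
    if (is.null(v)) numeric(0) else v
  }
  for (i in seq_len(n)) {
    s <- pairs$strain[i]
    cond <- pairs$condition[i]
    ctrl <- ctrl_of[[cond]]
    if (mode == "deletion") {
      if (isTRUE(is_ctrl[[cond]])) {
        x <- get_pair_values(s, cond)
        y <- wt_vals[[cond]]
        res$baseline[i] <- "vs-wild-type"
      } else {
        x <- get_pair_values(s, cond)
        y <- get_pair_values(s, ctrl)
        res$baseline[i] <- "vs-control-condition"
      }
    } else {
      if (isTRUE(is_ctrl[[cond]])) {
        x <- get_pair_values(s, cond)
        y <- get_pair_values(empty_vector, cond)
      } else {
        bm_s <- benign_med[[key(s, ctrl)]]
        bm_e <- benign_med[[key(empty_vector, ctrl)]]
        x <- get_pair_values(s, cond) /
          (if (is.null(bm_s)) NA_real_ else bm_s)
        y <- get_pair_values(empty_vector, cond) /
          (if (is.null(bm_e)) NA_real_ else bm_e)
        x <- x[!is.na(x)]
        y <- y[!is.na(y)]
      }
      res$baseline[i] <- "vs-empty-vector"
    }
    if (is.null(y)) y <- numeric(0)
    res$observation_count[i] <- length(x)
    if (length(x) >= 1L && length(y) >= 1L) {
      res$MES[i] <- stats::median(x) / stats::median(y)
      res$log2_MES[i] <- log2(res$MES[i])
    }
    if (length(x) >= 2L && length(y) >= 2L) {
      wt <- welch_test(x, y)
      res$welch_t[i] <- wt$t
      res$welch_df[i] <- wt$df
      res$p_value[i] <- wt$p
    }
  }
  res$adjusted_p <- bh_adjust(res$p_value, res$condition)
  class(res) <- c("strain_summary", "data.frame")
  res
}

#' Call growth / viability hits from strain-condition summaries
#'
#' Deletion mode: a strain x condition is a hit when the BH-adjusted p
#' is below `alpha` (default 0.05) and the effect passes the
#' readout-specific size filter: |log2 MES| > log2(1.05) for colony
#' size (a 5% fitness difference, similar to the median control CV) or
#' |log2 MES| > log2(1.015) for redness. Overexpression mode: adjusted
#' p <= 0.01 and |MES - 1| >= 0.05. Direction is the sign of log2 MES
#' (`"+"` resistant/faster, `"-"` sensitive/slower).
#'
#' @param summaries a `strain_summary` from [summarize_effects()].
#' @param mode `"deletion"` or `"overexpression"`.
#' @param alpha significance threshold on the adjusted p (default by
#'   mode).
#' @param effect_size relative effect-size threshold (default by mode
#'   and readout: 0.05 for size, 0.015 for deletion-mode redness).
#' @return `summaries` with logical `is_hit` and `direction` columns.
#' @export
call_hits <- function(summaries, mode = c("deletion", "overexpression"),
                      alpha = NULL, effect_size = NULL) {
  mode <- match.arg(mode)
  if (is.null(alpha)) alpha <- if (mode == "deletion") 0.05 else 0.01
  if (is.null(effect_size)) {
    effect_size <- ifelse(summaries$readout == "redness" &
                            mode == "deletion", 0.015, 0.05)
  }
  if (mode == "deletion") {
    sig <- !is.na(summaries$adjusted_p) & summaries$adjusted_p < alpha
    eff <- !is.na(summaries$log2_MES) &
      abs(summaries$log2_MES) > log2(1 + effect_size)
  } else {
    sig <- !is.na(summaries$adjusted_p) & summaries$adjusted_p <= alpha
    eff <- !is.na(summaries$MES) &
      abs(summaries$MES - 1) >= effect_size
  }
  summaries$is_hit <- sig & eff
  summaries$direction <- ifelse(is.na(summaries$log2_MES), NA_character_,
                                ifelse(summaries$log2_MES > 0, "+", "-"))
  summaries
}

#' Concordance of independent mutants of the same gene
#'
#' For genes represented by two or more independently constructed
#' mutants, classifies each gene x condition by how well the mutants'
#' median effect sizes agree: `"agree"` (all deviate from 1 by more
#' than 5%, same direction), `"trend"` (all by more than 2%, same
#' direction), `"opposite"` (all by more than 2% but in opposing
#' directions) or `"no-phenotype"` (at least one mutant within 2% of
#' 1). Genes with a single mutant are skipped.
#'
#' @param summaries a `strain_summary` (one row per mutant x condition).
#' @param gene_map data frame mapping `strain` to `gene`.
#' @return data frame: gene, condition, readout, n_mutants, class.
#' @export
concordance <- function(summaries, gene_map) {
  stopifnot(all(c("strain", "gene") %in% names(gene_map)))
  df <- merge(as.data.frame(summaries), gene_map, by = "strain")
  df <- df[!is.na(df$MES), , drop = FALSE]
  keys <- split(seq_len(nrow(df)),
                list(df$gene, df$condition, df$readout), drop = TRUE)
  out <- lapply(keys, function(idx) {
    if (length(idx) < 2L) return(NULL)
    dev <- df$MES[idx] - 1
    same_dir <- length(unique(sign(dev))) == 1L
    cls <- if (all(abs(dev) > 0.05) && same_dir) "agree"
      else if (all(abs(dev) > 0.02) && same_dir) "trend"
      else if (all(abs(dev) > 0.02)) "opposite"
      else "no-phenotype"
    data.frame(gene = df$gene[idx[1L]], condition = df$condition[idx[1L]],
               readout = df$readout[idx[1L]], n_mutants = length(idx),
               class = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Analytic variance inflation of normalized reference-colony fitness on
# a complete standard384 plate: the leave-one-out estimate contributes
# mean(sum of squared weights) extra variance (interior 0.25, lattice
# edges 1.375, corners 2.5). Used to translate a post-normalization
# wild-type CV (the scale on which plate QC reports it) into the raw
# lognormal noise CV of the generator.
standard384_cv_inflation <- function() {
  lay <- standard384_layout()
  lay$size <- 1
  sqrt(1 + mean(ref_loo_varw(lay)))
}

#' Minimum confidently detectable growth effect by simulation
#'
#' For each effect size on a grid, simulates `n_runs` seeded screening
#' experiments in which one strain carries the effect in the benign
#' condition (alongside neutral filler strains for a realistic
#' multiple-testing family), runs grid normalization and deletion-mode
#' hit calling, and records the fraction of runs in which the injected
#' strain is detected. Detection is `"hit"` (significance plus the 5%
#' effect-size filter, the full hit definition) or `"significant"`
#' (BH-adjusted p below alpha only).
#'
#' @param effect_grid ascending relative effect sizes (e.g. 0.05 = 5%).
#' @param n_runs simulation runs per effect size.
#' @param n_strains strains per plate (one carries the effect).
#' @param n_bio,n_tech replicate structure.
#' @param wt_size_cv target post-normalization wild-type control CV
#'   (the scale on which plate QC reports it); the generator's raw
#'   noise CV is derived by dividing out the analytic normalization
#'   inflation.
#' @param target_rate detection-rate target defining "confidently
#'   detectable" (default 0.8).
#' @param criterion detection criterion, see above.
#' @param alpha significance threshold for hit calling.
#' @param seed integer seed for the whole scan.
#' @return object of class `power_scan`: data frame (`effect`,
#'   `detection_rate`, `n_runs`) with attributes `min_effect` (smallest
#'   effect with rate >= `target_rate`; `NA` if none) and
#'   `target_rate`.
#' @export
power_scan <- function(effect_grid, n_runs = 100L, n_strains = 144L,
                       n_bio = 9L, n_tech = 2L, wt_size_cv = 0.050,
                       target_rate = 0.8,
                       criterion = c("hit", "significant"),
                       alpha = 0.05, seed = 1L) {
  criterion <- match.arg(criterion)
  if (!length(effect_grid)) stop("empty effect grid", call. = FALSE)
  stopifnot(!is.unsorted(effect_grid), n_runs >= 1L)
  set.seed(seed)
  run_seeds <- matrix(sample.int(.Machine$integer.max,
                                 n_runs * length(effect_grid)),
                      nrow = n_runs)
  raw_cv <- wt_size_cv / standard384_cv_inflation()
  strains <- c("mut", sprintf("null%03d", seq_len(n_strains - 1L)))
  rates <- numeric(length(effect_grid))
  for (k in seq_along(effect_grid)) {
    e <- effect_grid[k]
    detected <- logical(n_runs)
    for (r in seq_len(n_runs)) {
      cfg <- sim_config(
        strains = strains, conditions = "benign",
        strain_effects = data.frame(strain = "mut", condition = "benign",
                                    growth = 1 + e,
                                    stringsAsFactors = FALSE),
        n_bio = n_bio, n_tech = n_tech, wt_size_cv = raw_cv,
        seed = run_seeds[r, k])
      expt <- simulate_experiment(cfg)
      ds <- normalize_dataset(expt$colonies, rcmedian = FALSE)
      summ <- summarize_effects(ds, expt$conditions, mode = "deletion")
      summ <- call_hits(summ, mode = "deletion", alpha = alpha)
      row <- summ[summ$strain == "mut", , drop = FALSE]
      detected[r] <- if (criterion == "hit") isTRUE(row$is_hit[1L]) else
        isTRUE(row$adjusted_p[1L] < alpha)
    }
    rates[k] <- mean(detected)
  }
  out <- data.frame(effect = effect_grid, detection_rate = rates,
                    n_runs = n_runs)
  ok <- which(rates >= target_rate)
  attr(out, "min_effect") <- if (length(ok)) effect_grid[min(ok)]
                             else NA_real_
  attr(out, "target_rate") <- target_rate
  class(out) <- c("power_scan", "data.frame")
  out
}

#' @export
print.power_scan <- function(x, ...) {
  cat("Detection-rate scan (", x$n_runs[1], " runs per effect)\n",
      sep = "")
  print(data.frame(effect = x$effect,
                   detection_rate = x$detection_rate))
  me <- attr(x, "min_effect")
  cat("minimum effect with rate >=", attr(x, "target_rate"), ":",
      if (is.na(me)) "none on grid" else sprintf("%.3g", me), "\n")
  invisible(x)
}

#' Empirical false discovery rate on a synthetic null/effect mixture
#'
#' Simulates screening experiments in which a known fraction of
#' strain x stress-condition pairs carry a true multiplicative growth
#' effect while the rest are null, runs the full deletion-mode pipeline
#' (grid + row/column normalization, Welch tests against the linked
#' control condition, per-condition Benjamini-Hochberg adjustment and
#' the effect-size filter), and measures the proportion of called hits
#' that are false, averaged over seeded repetitions.
#'
#' @param n_strains number of library strains.
#' @param n_stress number of stress conditions (a benign control
#'   condition is always included as the baseline).
#' @param prop_effect fraction of strain x stress pairs with a true
#'   effect.
#' @param effect relative effect size of true pairs (e.g. 0.10).
#' @param n_bio,n_tech replicate structure.
#' @param wt_size_cv target post-normalization wild-type control CV
#'   (see [power_scan()]).
#' @param reps number of seeded repetitions.
#' @param seed integer seed.
#' @return list: `fdr` (mean over repetitions), `per_rep` (data frame
#'   with hits, false hits and per-repetition FDR), `power` (mean
#'   fraction of true pairs called).
#' @export
fdr_benchmark <- function(n_strains = 500L, n_stress = 4L,
                          prop_effect = 0.2, effect = 0.10,
                          n_bio = 9L, n_tech = 2L, wt_size_cv = 0.050,
                          reps = 20L, seed = 1L) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, reps)
  raw_cv <- wt_size_cv / standard384_cv_inflation()
  strains <- sprintf("s%04d", seq_len(n_strains))
  stress <- sprintf("stress%02d", seq_len(n_stress))
  per_rep <- data.frame(rep = seq_len(reps), n_hits = NA_integer_,
                        n_false = NA_integer_, fdr = NA_real_,
                        power = NA_real_)
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    all_pairs <- expand.grid(strain = strains, condition = stress,
                             KEEP.OUT.ATTRS = FALSE,
                             stringsAsFactors = FALSE)
    true_idx <- sample.int(nrow(all_pairs),
                           round(prop_effect * nrow(all_pairs)))
    eff <- all_pairs[true_idx, , drop = FALSE]
    eff$growth <- 1 + effect
    cfg <- sim_config(strains = strains,
                      conditions = c("benign", stress),
                      strain_effects = eff, n_bio = n_bio,
                      n_tech = n_tech, wt_size_cv = raw_cv,
                      seed = rep_seeds[r])
    expt <- simulate_experiment(cfg)
    ds <- normalize_dataset(expt$colonies)
    summ <- summarize_effects(ds, expt$conditions, mode = "deletion")
    hits <- call_hits(summ, mode = "deletion")
    hits <- hits[hits$condition %in% stress, , drop = FALSE]
    true_key <- paste(eff$strain, eff$condition)
    hit_key <- paste(hits$strain, hits$condition)[hits$is_hit]
    n_hits <- length(hit_key)
    n_false <- sum(!hit_key %in% true_key)
    per_rep$n_hits[r] <- n_hits
    per_rep$n_false[r] <- n_false
    per_rep$fdr[r] <- if (n_hits > 0) n_false / n_hits else 0
    per_rep$power[r] <- mean(true_key %in% hit_key)
  }
  list(fdr = mean(per_rep$fdr), per_rep = per_rep,
       power = mean(per_rep$power))
}
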