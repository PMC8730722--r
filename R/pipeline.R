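#' Run the full phenomics analysis pipeline
#'
#' Executes assemble -> normalize -> QC -> summarize -> hit calling ->
#' z-score profiling -> discretization -> clustering -> correlation
#' network on a dataset, and optionally writes every intermediate to
#' `out_dir`. The input is either a simulated experiment
#' ([simulate_experiment()]) or a design table / design CSV path whose
#' plates are read from disk.
#'
#' @param x a `phenomics_experiment`, a design data frame, or the path
#'   of a design CSV (relative data/layout paths are resolved against
#'   the design file's directory).
#' @param base_dir directory against which relative paths in a design
#'   data frame are resolved (set automatically for a design CSV path).
#' @param out_dir optional output directory for all result files.
#' @param mode `"deletion"` or `"overexpression"`.
#' @param z_threshold discretization threshold in wild-type SD units.
#' @param min_hits minimal non-zero responses per strain for profiling.
#' @param k number of flat clusters.
#' @param r_min,network_alpha correlation-network edge filters.
#' @param core_conditions optional whitelist of stressor sets used for
#'   profiling (e.g. the core conditions measured for all mutants).
#' @param qc list of QC thresholds passed to [qc_filter()].
#' @param seed seed for the community detection step.
#' @return list of class `phenogrid_pipeline` with elements `dataset`,
#'   `qc`, `summaries`, `hits`, `z`, `aggregated`, `ternary`,
#'   `profile_matrix`, `clustering`, `network`, `communities`.
#' @export
run_pipeline <- function(x, out_dir = NULL,
                         mode = c("deletion", "overexpression"),
                         z_threshold = 1.5, min_hits = 5L, k = 3L,
                         r_min = 0.6, network_alpha = 0.01,
                         core_conditions = NULL, qc = list(),
                         base_dir = ".", seed = 1L) {
  mode <- match.arg(mode)
  if (is.character(x)) {
    base_dir <- dirname(x)
    x <- read_design(x)
  }
  if (inherits(x, "phenomics_experiment")) {
    dataset <- x$colonies
    conditions <- x$conditions
  } else {
    dataset <- assemble_dataset(x, base_dir = base_dir)
    conditions <- design_conditions(x)
  }

  dataset <- normalize_dataset(dataset)
  qc_res <- do.call(qc_filter,
                    c(list(dataset = dataset, mode = mode), qc))
  dataset <- qc_res$dataset

  readouts <- intersect(c("size", "redness"),
                        sub("^fitness_", "",
                            grep("^fitness_", names(dataset),
                                 value = TRUE)))
  summaries <- do.call(rbind, lapply(readouts, function(rd) {
    summarize_effects(dataset, conditions, mode = mode, readout = rd)
  }))
  class(summaries) <- c("strain_summary", "data.frame")
  hits <- call_hits(summaries, mode = mode)

  # profiling on the growth readout
  size_sum <- summaries[summaries$readout == "size", , drop = FALSE]
  mes <- mes_matrix(size_sum)
  wt_sd <- wt_condition_sd(dataset, "size")
  z <- zscore_transform(mes, wt_sd)
  sets <- stats::setNames(conditions$stressor_set, conditions$condition)
  agg <- aggregate_conditions(z, sets[colnames(z)])
  if (!is.null(core_conditions)) {
    agg <- agg[, intersect(colnames(agg), core_conditions), drop = FALSE]
  }
  tern <- discretize(agg, threshold = z_threshold)
  prof <- filter_min_hits(tern, min_hits = min_hits,
                          filter_conditions = mode == "overexpression")

  clustering <- NULL
  network <- NULL
  communities <- NULL
  if (nrow(prof) >= 2L) {
    kk <- min(k, nrow(prof))
    clustering <- if (mode == "deletion") {
      cluster_profiles(prof, "ward", "euclidean", k = kk)
    } else {
      cluster_profiles(prof, "complete", "canberra", k = kk)
    }
    network <- correlation_network(prof, r_min = r_min,
                                   alpha = network_alpha)
    communities <- detect_communities(network, seed = seed)
  }

  out <- structure(list(
    dataset = dataset, qc = qc_res[c("plates", "exclusions")],
    summaries = summaries, hits = hits, z = z, aggregated = agg,
    ternary = tern, profile_matrix = prof, clustering = clustering,
    network = network, communities = communities,
    conditions = conditions, mode = mode
  ), class = "phenogrid_pipeline")

  if (!is.null(out_dir)) write_pipeline(out, out_dir, seed = seed)
  out
}

#' @export
print.phenogrid_pipeline <- function(x, ...) {
  cat("phenogrid pipeline (", x$mode, " mode)\n", sep = "")
  cat("  colonies:        ", nrow(x$dataset), "\n")
  cat("  strain summaries:", nrow(x$summaries), "\n")
  cat("  hits:            ", sum(x$hits$is_hit, na.rm = TRUE), "\n")
  cat("  profiled strains:", nrow(x$profile_matrix), "\n")
  if (!is.null(x$network)) {
    cat("  network edges:   ", nrow(x$network$edges), "\n")
  }
  invisible(x)
}

#' Write all pipeline results to a directory
#'
#' @param result a `phenogrid_pipeline`.
#' @param out_dir output directory (created if needed).
#' @param seed seed recorded in the provenance file.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline <- function(result, out_dir, seed = NA) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  utils::write.table(result$dataset, p("fitness.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(result$qc$plates, p("qc_plates.csv"),
                   row.names = FALSE)
  utils::write.table(result$hits, p("hits.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(result$z, p("zscores.csv"))
  utils::write.csv(result$ternary, p("ternary.csv"))
  if (!is.null(result$clustering)) {
    write_linkage_newick(result$clustering, p("linkage.nwk"))
    utils::write.csv(
      data.frame(strain = names(result$clustering$labels),
                 cluster = result$clustering$labels),
      p("clusters.csv"), row.names = FALSE)
  }
  if (!is.null(result$network)) {
    write_network_sif(result$network, p("network.sif"))
    write_network_graphml(result$network, p("network.graphml"))
  }
  prov <- c(
    sprintf("package: phenogrid %s",
            as.character(utils::packageVersion("phenogrid"))),
    sprintf("R: %s", R.version.string),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("mode: %s", result$mode),
    sprintf("seed: %s", seed))
  writeLines(prov, p("provenance.txt"))
  invisible(out_dir)
}
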