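#' Phenotype correlation network
#'
#' Computes pairwise Pearson correlations between strain phenotype
#' profiles (rows of the discretized matrix), tests each with a
#' two-sided t-test on n - 2 degrees of freedom, adjusts p-values with
#' Benjamini-Hochberg across all tested pairs, and keeps edges with
#' |r| > `r_min` and adjusted p < `alpha`. Pairs with fewer than three
#' shared defined conditions are skipped (and counted); constant
#' (zero-variance) profiles yield no edges.
#'
#' @param mat strains x conditions matrix (typically the ternary matrix
#'   after [filter_min_hits()]).
#' @param r_min minimal absolute Pearson correlation (default 0.6).
#' @param alpha threshold on the BH-adjusted p-value (default 0.01).
#' @return list of class `phenotype_network`: `graph` (igraph, all
#'   strains as vertices, edge attributes `r`, `p`, `adjusted_p`,
#'   `sign`), `edges` (the same as a data frame), `n_pairs_tested`,
#'   `n_pairs_skipped`.
#' @export
correlation_network <- function(mat, r_min = 0.6, alpha = 0.01) {
  stopifnot(nrow(mat) >= 2L)
  strains <- rownames(mat)
  if (is.null(strains)) strains <- as.character(seq_len(nrow(mat)))
  pairs <- utils::combn(nrow(mat), 2L)
  np <- ncol(pairs)
  r <- p <- rep(NA_real_, np)
  n_shared <- integer(np)
  for (k in seq_len(np)) {
    a <- mat[pairs[1L, k], ]
    b <- mat[pairs[2L, k], ]
    ok <- !is.na(a) & !is.na(b)
    n <- sum(ok)
    n_shared[k] <- n
    if (n < 3L) next
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) next
    rk <- stats::cor(a[ok], b[ok])
    r[k] <- rk
    tt <- rk * sqrt((n - 2) / max(1 - rk^2, .Machine$double.eps))
    p[k] <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  tested <- !is.na(r)
  adj <- rep(NA_real_, np)
  adj[tested] <- bh_adjust(p[tested])
  keep <- tested & abs(r) > r_min & adj < alpha
  edges <- data.frame(
    from = strains[pairs[1L, keep]], to = strains[pairs[2L, keep]],
    r = r[keep], p = p[keep], adjusted_p = adj[keep],
    sign = ifelse(r[keep] > 0, "+", "-"), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = strains))
  structure(list(graph = g, edges = edges,
                 n_pairs_tested = sum(tested),
                 n_pairs_skipped = sum(n_shared < 3L)),
            class = "phenotype_network")
}

#' @export
print.phenotype_network <- function(x, ...) {
  cat("Phenotype correlation network\n")
  cat("  nodes:", igraph::vcount(x$graph),
      " edges:", nrow(x$edges), "\n")
  cat("  pairs tested:", x$n_pairs_tested,
      " skipped (<3 shared conditions):", x$n_pairs_skipped, "\n")
  invisible(x)
}

#' Seeded modularity-based community detection
#'
#' Louvain modularity communities on the phenotype network (edge
#' weights |r|), with a fixed RNG seed for deterministic labels.
#'
#' @param network a `phenotype_network`.
#' @param seed integer RNG seed.
#' @return named integer vector of community labels per strain (empty
#'   when the network has no edges).
#' @export
detect_communities <- function(network, seed = 1L) {
  stopifnot(inherits(network, "phenotype_network"))
  if (!nrow(network$edges)) {
    return(stats::setNames(integer(0), character(0)))
  }
  set.seed(seed)
  comm <- igraph::cluster_louvain(network$graph,
                                  weights = abs(igraph::E(network$graph)$r))
  stats::setNames(as.integer(igraph::membership(comm)),
                  names(igraph::membership(comm)))
}

#' Export a phenotype network
#'
#' `write_network_sif()` writes a Cytoscape-style SIF edge list
#' (node, interaction sign, node); `write_network_graphml()` writes
#' GraphML.
#'
#' @param network a `phenotype_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_sif <- function(network, path) {
  e <- network$edges
  writeLines(paste(e$from, e$sign, e$to, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_network_sif
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}
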