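#' Median-effect-size matrix from strain-condition summaries
#'
#' @param summaries a `strain_summary` from [summarize_effects()].
#' @param value column to spread (`"MES"` or `"log2_MES"`).
#' @return numeric matrix, strains x conditions (NA where a pair was
#'   not measured).
#' @export
mes_matrix <- function(summaries, value = "MES") {
  strains <- sort(unique(summaries$strain))
  conds <- sort(unique(summaries$condition))
  M <- matrix(NA_real_, length(strains), length(conds),
              dimnames = list(strains, conds))
  M[cbind(match(summaries$strain, strains),
          match(summaries$condition, conds))] <- summaries[[value]]
  M
}

#' Wild-type control standard deviation per condition
#'
#' Standard deviation of the normalized wild-type (reference grid)
#' fitness in each condition; the scaling unit of the modified z-score.
#'
#' @param dataset normalized tidy dataset.
#' @param readout `"size"` or `"redness"`.
#' @return named numeric vector, one SD per condition.
#' @export
wt_condition_sd <- function(dataset, readout = "size") {
  fit <- dataset[[paste0("fitness_", readout)]]
  keep <- dataset$ref & !is.na(fit)
  vapply(split(fit[keep], dataset$condition[keep]), stats::sd, numeric(1))
}

#' Modified z-score transform of median effect sizes
#'
#' z = (MES - 1) / SD_wt(condition): the deviation from the expected
#' (wild-type-like) phenotype in units of wild-type standard deviations
#' for that condition.
#'
#' @param mes strains x conditions MES matrix (see [mes_matrix()]).
#' @param wt_sd named vector of wild-type SDs per condition.
#' @return z matrix over the conditions with positive SD; conditions
#'   with non-positive or missing SD are dropped with a warning.
#' @export
zscore_transform <- function(mes, wt_sd) {
  sd_use <- wt_sd[colnames(mes)]
  bad <- is.na(sd_use) | sd_use <= 0
  if (any(bad)) {
    warning("excluding condition(s) with non-positive wild-type SD: ",
            paste(colnames(mes)[bad], collapse = ", "), call. = FALSE)
  }
  sweep(mes[, !bad, drop = FALSE] - 1, 2L, sd_use[!bad], "/")
}

#' Aggregate related conditions by the strongest response
#'
#' Conditions that probe the same stressor (e.g. several doses of one
#' drug) are collapsed to a single column per stressor set, keeping for
#' each strain the signed value of maximal absolute z across the
#' member conditions. Ties between equal-magnitude responses of
#' opposite sign resolve to the positive value (deterministic output).
#'
#' @param z strains x conditions z matrix.
#' @param sets condition -> stressor-set map: a named character vector
#'   (names = conditions) or a data frame with columns `condition`,
#'   `stressor_set`.
#' @return strains x stressor-set matrix.
#' @export
aggregate_conditions <- function(z, sets) {
  if (is.data.frame(sets)) {
    sets <- stats::setNames(sets$stressor_set, sets$condition)
  }
  unmapped <- setdiff(colnames(z), names(sets))
  if (length(unmapped)) {
    stop("unmapped condition(s): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  grp <- sets[colnames(z)]
  out_sets <- unique(grp)
  A <- matrix(NA_real_, nrow(z), length(out_sets),
              dimnames = list(rownames(z), out_sets))
  for (s in out_sets) {
    sub <- z[, grp == s, drop = FALSE]
    A[, s] <- apply(sub, 1L, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return(NA_real_)
      m <- max(abs(v))
      if (m %in% v) m else -m  # positive wins equal-magnitude ties
    })
  }
  A
}

#' Ternary discretization of a z matrix
#'
#' Classes each strain x condition as resistant (+1, z above the
#' threshold), sensitive (-1, z below the negative threshold) or
#' similar to wild type (0). The default threshold of 1.5 wild-type
#' standard deviations applies to both growth and viability data.
#'
#' @param z numeric matrix of modified z-scores (or any effect scale).
#' @param threshold positive cut-off (default 1.5).
#' @return integer matrix in \{-1, 0, +1\} (NA preserved).
#' @export
discretize <- function(z, threshold = 1.5) {
  stopifnot(threshold > 0)
  d <- z
  d[] <- ifelse(is.na(z), NA,
                ifelse(z > threshold, 1L, ifelse(z < -threshold, -1L, 0L)))
  d
}

#' Filter sparse profiles and impute absent cells
#'
#' Keeps strains with at least `min_hits` non-zero responses (and, when
#' `filter_conditions` is set, then conditions with at least `min_hits`
#' non-zero responses, the overexpression-mode convention), and imputes
#' absent cells with `impute_absent_with`. An all-zero input yields an
#' explicit empty matrix, not an error.
#'
#' @param ternary discretized matrix from [discretize()].
#' @param min_hits minimum number of non-zero responses (default 5).
#' @param impute_absent_with value for absent cells (default 0).
#' @param filter_conditions also filter condition columns
#'   (overexpression mode).
#' @return filtered, imputed matrix (possibly with zero rows).
#' @export
filter_min_hits <- function(ternary, min_hits = 5L,
                            impute_absent_with = 0,
                            filter_conditions = FALSE) {
  stopifnot(min_hits >= 1L)
  nz <- function(v) sum(!is.na(v) & v != 0)
  keep_r <- apply(ternary, 1L, nz) >= min_hits
  out <- ternary[keep_r, , drop = FALSE]
  if (filter_conditions && nrow(out)) {
    keep_c <- apply(out, 2L, nz) >= min_hits
    out <- out[, keep_c, drop = FALSE]
  }
  out[is.na(out)] <- impute_absent_with
  out
}

#' Hierarchical clustering of phenotype profiles
#'
#' Deletion-mode convention: Ward linkage on Euclidean distances
#' (equivalent to scipy's "ward"); overexpression-mode convention:
#' complete linkage on Canberra distances. Flat clusters are obtained
#' by cutting the tree into exactly `k` groups (maxclust-style cut).
#'
#' @param mat numeric matrix (rows are clustered); no absent cells.
#' @param method `"ward"` or any [stats::hclust()] linkage method.
#' @param metric any [stats::dist()] metric (`"euclidean"`,
#'   `"canberra"`, ...).
#' @param k number of flat clusters.
#' @return list of class `profile_clustering`: `tree` (hclust),
#'   `labels` (named cluster id per row), `method`, `metric`, `k`.
#' @export
cluster_profiles <- function(mat, method = "ward", metric = "euclidean",
                             k = 3L) {
  if (anyNA(mat)) stop("matrix has absent cells; impute first",
                       call. = FALSE)
  if (nrow(mat) < 2L) stop("need at least 2 rows to cluster",
                           call. = FALSE)
  if (k > nrow(mat)) stop("k exceeds the number of rows", call. = FALSE)
  hmethod <- if (method == "ward") "ward.D2" else method
  tree <- stats::hclust(stats::dist(mat, method = metric),
                        method = hmethod)
  labels <- stats::cutree(tree, k = k)
  structure(list(tree = tree, labels = labels, method = method,
                 metric = metric, k = as.integer(k)),
            class = "profile_clustering")
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat("Hierarchical clustering:", x$method, "linkage,", x$metric,
      "distance, k =", x$k, "\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Write an hclust tree as Newick text
#'
#' @param clustering a `profile_clustering` (or an `hclust`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_linkage_newick <- function(clustering, path) {
  tree <- if (inherits(clustering, "profile_clustering"))
    clustering$tree else clustering
  stopifnot(inherits(tree, "hclust"))
  lab <- tree$labels
  if (is.null(lab)) lab <- as.character(seq_along(tree$order))
  rec <- function(i) {
    if (i < 0) return(lab[-i])
    h <- tree$height[i]
    kids <- tree$merge[i, ]
    child_h <- function(j) if (j < 0) 0 else tree$height[j]
    paste0("(", rec(kids[1]), ":", format(h - child_h(kids[1])), ",",
           rec(kids[2]), ":", format(h - child_h(kids[2])), ")")
  }
  writeLines(paste0(rec(nrow(tree$merge)), ";"), path)
  invisible(path)
}
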