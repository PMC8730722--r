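#' Read a quantified colony table
#'
#' Reads a per-plate colony quantification table (tab-separated, one
#' line per colony position) in one of three dialects: `"size_table"`
#' (gitter-style: row, col, size, circularity), `"redness_table"` (row,
#' col, redness) or `"combined"` (row, col, size, circularity, redness).
#' Positions absent from the file are materialized as missing records,
#' and colonies reported with size 0 (pinning failures) are flagged
#' missing.
#'
#' @param path file path.
#' @param dialect one of `"size_table"`, `"redness_table"`, `"combined"`.
#' @param n_rows,n_cols plate dimensions (default 16 x 24).
#' @return data frame with one record per plate position: `row`, `col`,
#'   `size`/`redness` as appropriate, `circularity` and `qc_flag`
#'   (`"ok"` or `"missing"`).
#' @export
read_colony_table <- function(path,
                              dialect = c("size_table", "redness_table",
                                          "combined"),
                              n_rows = 16L, n_cols = 24L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- switch(dialect,
                 size_table = c("row", "col", "size", "circularity"),
                 redness_table = c("row", "col", "redness"),
                 combined = c("row", "col", "size", "circularity",
                              "redness"))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("format error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df[c("row", "col")])) {
    stop("format error in ", path, ": duplicate (row, col) positions",
         call. = FALSE)
  }
  for (col in setdiff(need, c("row", "col"))) {
    if (!is.numeric(df[[col]])) {
      stop("format error in ", path, ": non-numeric ", col, call. = FALSE)
    }
  }
  if (any(df$row < 1 | df$row > n_rows | df$col < 1 | df$col > n_cols)) {
    stop("format error in ", path, ": positions out of range",
         call. = FALSE)
  }
  full <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols),
                      KEEP.OUT.ATTRS = FALSE)
  full <- full[order(full$row, full$col), , drop = FALSE]
  out <- merge(full, df, by = c("row", "col"), all.x = TRUE, sort = FALSE)
  out <- out[order(out$row, out$col), , drop = FALSE]
  value_col <- if (dialect == "redness_table") "redness" else "size"
  out$qc_flag <- ifelse(is.na(out[[value_col]]) | out[[value_col]] == 0,
                        "missing", "ok")
  rownames(out) <- NULL
  out
}

#' Write a quantified colony table (TSV)
#'
#' @param records data frame with `row`, `col` and the measurement
#'   columns of the chosen dialect.
#' @param path output path.
#' @inheritParams read_colony_table
#' @return `path`, invisibly.
#' @export
write_colony_table <- function(records, path,
                               dialect = c("size_table", "redness_table",
                                           "combined")) {
  dialect <- match.arg(dialect)
  cols <- switch(dialect,
                 size_table = c("row", "col", "size", "circularity"),
                 redness_table = c("row", "col", "redness"),
                 combined = c("row", "col", "size", "circularity",
                              "redness"))
  utils::write.table(records[cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write an experiment design table (CSV)
#'
#' The design lists, for every plate, the path to its colony data file
#' and layout, the condition with its control-condition link and
#' stressor-set label, and the batch / biological-repeat indices.
#'
#' @param path file path.
#' @return `read_design()` returns the design data frame.
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "condition", "control_condition", "stressor_set",
            "batch", "bio_rep", "data_path", "layout_path")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("design error: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_design
#' @param design design data frame.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble the tidy colony dataset for an experiment
#'
#' Joins every plate's quantified colony table with its layout and the
#' design metadata into one tidy table with a single measured colony per
#' row. Reference (wild-type grid) colonies are labelled, missing
#' positions flagged, and technical-replicate indices assigned by
#' occurrence order of each strain on a plate.
#'
#' @param design design data frame (see [read_design()]); file paths are
#'   interpreted relative to `base_dir`.
#' @param base_dir directory against which relative paths are resolved.
#' @param dialect colony-table dialect (see [read_colony_table()]).
#' @return tidy colony data frame (one row per plate position).
#' @export
assemble_dataset <- function(design, base_dir = ".",
                             dialect = c("size_table", "combined",
                                         "redness_table")) {
  dialect <- match.arg(dialect)
  controls <- unique(design$control_condition)
  unknown <- setdiff(controls, unique(design$condition))
  if (length(unknown)) {
    stop("design error: control condition(s) not present in design: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base_dir, p))
  layout_cache <- new.env(parent = emptyenv())
  pieces <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    lp <- resolve(design$layout_path[i])
    if (!file.exists(lp)) {
      stop("design error: missing layout file ", lp, call. = FALSE)
    }
    key <- normalizePath(lp)
    lay <- if (exists(key, envir = layout_cache)) {
      get(key, envir = layout_cache)
    } else {
      l <- read_layout(lp)
      assign(key, l, envir = layout_cache)
      l
    }
    rec <- read_colony_table(resolve(design$data_path[i]), dialect)
    if (nrow(rec) != nrow(lay)) {
      stop("structural error: plate ", design$plate_id[i],
           " dimensions do not match its layout", call. = FALSE)
    }
    piece <- merge(lay, rec, by = c("row", "col"), sort = FALSE)
    piece <- piece[order(piece$row, piece$col), , drop = FALSE]
    piece$plate_id <- design$plate_id[i]
    piece$condition <- design$condition[i]
    piece$batch <- design$batch[i]
    piece$bio_rep <- design$bio_rep[i]
    piece$tech_rep <- stats::ave(seq_len(nrow(piece)), piece$strain,
                                 FUN = seq_along)
    piece$tech_rep[piece$ref | is.na(piece$strain)] <- NA_integer_
    pieces[[i]] <- piece
  }
  out <- do.call(rbind, pieces)
  front <- c("plate_id", "condition", "batch", "bio_rep", "tech_rep",
             "row", "col", "strain", "ref")
  out <- out[c(front, setdiff(names(out), front))]
  rownames(out) <- NULL
  out
}

#' Conditions metadata from a design table
#'
#' @param design design data frame with `condition`, `control_condition`
#'   and `stressor_set` columns.
#' @return data frame with one row per condition (`condition`,
#'   `is_control`, `control_condition`, `stressor_set`).
#' @export
design_conditions <- function(design) {
  u <- unique(design[c("condition", "control_condition", "stressor_set")])
  u$is_control <- u$condition == u$control_condition
  rownames(u) <- NULL
  u[c("condition", "is_control", "control_condition", "stressor_set")]
}

#' Write a simulated experiment to disk
#'
#' Writes per-plate colony TSVs, layout CSVs, a design CSV (with
#' relative paths) and the ground-truth effects CSV, so that
#' [assemble_dataset()] on the written design reproduces the simulated
#' tidy dataset.
#'
#' @param experiment a `phenomics_experiment` from
#'   [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @return path of the written design CSV, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "phenomics_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(experiment$layouts)) {
    write_layout(experiment$layouts[[k]],
                 file.path(dir, sprintf("layout_%02d.csv", k)))
  }
  dialect <- if (isTRUE(experiment$config$redness)) "combined"
             else "size_table"
  des <- experiment$design
  des$data_path <- sprintf("%s.tsv", des$plate_id)
  des$layout_path <- sprintf("layout_%02d.csv", des$layout)
  cond <- experiment$conditions
  m <- match(des$condition, cond$condition)
  des$control_condition <- cond$control_condition[m]
  des$stressor_set <- cond$stressor_set[m]
  for (i in seq_len(nrow(des))) {
    plate <- experiment$colonies[
      experiment$colonies$plate_id == des$plate_id[i], , drop = FALSE]
    write_colony_table(plate, file.path(dir, des$data_path[i]), dialect)
  }
  write_design(des[c("plate_id", "condition", "control_condition",
                     "stressor_set", "batch", "bio_rep", "data_path",
                     "layout_path")],
               file.path(dir, "design.csv"))
  utils::write.csv(experiment$truth$effects,
                   file.path(dir, "ground_truth.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(file.path(dir, "design.csv"))
}
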