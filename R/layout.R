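#' Standard 384-colony plate layout with a 96-colony reference grid
#'
#' Builds the standard layout used throughout the pipeline: a 16 x 24
#' colony array in which every position with odd row and odd column
#' (8 x 12 = 96 positions) carries the wild-type reference grid used for
#' spatial normalization. The remaining 288 positions hold library
#' strains.
#'
#' @param strains optional character vector of strain ids to place on the
#'   non-reference positions (length <= 288). Supply repeated ids to
#'   create technical replicate colonies of the same strain.
#' @param randomize logical; if `TRUE` the strains are placed at random
#'   positions around the grid (uses the current RNG state), otherwise in
#'   row-major order. Strains are conventionally arrayed randomly around
#'   the control grid.
#' @param fill value used for non-reference positions left without a
#'   strain (default `NA`; such positions are treated as empty).
#'
#' @return A `plate_layout`: a data frame with columns `row`, `col`,
#'   `strain` and logical `ref`, plus attributes `n_rows` and `n_cols`.
#' @export
standard384_layout <- function(strains = NULL, randomize = FALSE,
                               fill = NA_character_) {
  pos <- expand.grid(row = 1:16, col = 1:24, KEEP.OUT.ATTRS = FALSE)
  pos <- pos[order(pos$row, pos$col), , drop = FALSE]
  ref <- pos$row %% 2L == 1L & pos$col %% 2L == 1L
  strain <- rep(fill, nrow(pos))
  strain[ref] <- "grid"
  if (!is.null(strains)) {
    slots <- which(!ref)
    if (length(strains) > length(slots)) {
      stop("too many strains for a 384 layout: ", length(strains),
           " > ", length(slots), " available positions", call. = FALSE)
    }
    if (randomize) slots <- sample(slots)
    strain[slots[seq_along(strains)]] <- strains
  }
  layout <- data.frame(row = pos$row, col = pos$col, strain = strain,
                       ref = ref, stringsAsFactors = FALSE)
  rownames(layout) <- NULL
  attr(layout, "n_rows") <- 16L
  attr(layout, "n_cols") <- 24L
  class(layout) <- c("plate_layout", "data.frame")
  layout
}

#' Construct a plate layout from a position -> strain table
#'
#' @param df data frame with columns `row`, `col`, `strain`; reference
#'   positions are those with `strain == "grid"` unless a logical `ref`
#'   column is supplied.
#' @param n_rows,n_cols plate dimensions (default 16 x 24).
#' @return A `plate_layout` (see [standard384_layout()]).
#' @export
plate_layout <- function(df, n_rows = 16L, n_cols = 24L) {
  stopifnot(all(c("row", "col", "strain") %in% names(df)))
  if (any(df$row < 1 | df$row > n_rows | df$col < 1 | df$col > n_cols)) {
    stop("layout positions out of range for a ", n_rows, " x ", n_cols,
         " plate", call. = FALSE)
  }
  if (anyDuplicated(df[c("row", "col")])) {
    stop("duplicate (row, col) positions in layout", call. = FALSE)
  }
  if (is.null(df$ref)) df$ref <- !is.na(df$strain) & df$strain == "grid"
  df <- df[order(df$row, df$col), c("row", "col", "strain", "ref")]
  rownames(df) <- NULL
  attr(df, "n_rows") <- as.integer(n_rows)
  attr(df, "n_cols") <- as.integer(n_cols)
  class(df) <- c("plate_layout", "data.frame")
  df
}

#' Read / write a layout CSV (columns: row, col, strain)
#'
#' Reference positions are recognised by the strain id `"grid"`.
#'
#' @param path file path.
#' @param n_rows,n_cols plate dimensions.
#' @return `read_layout()` returns a `plate_layout`; `write_layout()`
#'   returns `path` invisibly.
#' @export
read_layout <- function(path, n_rows = 16L, n_cols = 24L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$strain[!is.na(df$strain) & df$strain == ""] <- NA_character_
  plate_layout(df, n_rows = n_rows, n_cols = n_cols)
}

#' @rdname read_layout
#' @param layout a `plate_layout`.
#' @export
write_layout <- function(layout, path) {
  utils::write.csv(layout[c("row", "col", "strain")], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
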