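#' Reference-grid spatial normalization of one plate
#'
#' Estimates the expected wild-type value at every plate position from
#' the 96-colony reference grid and divides the observed value by it,
#' yielding a dimensionless fitness (observed / expected wild-type).
#'
#' Non-reference positions use bilinear interpolation over the reference
#' lattice; positions beyond the outermost reference rows/columns are
#' covered by linear extension of the nearest lattice cell, so an exact
#' planar gradient is reproduced (fitness exactly 1) everywhere on the
#' plate. At reference positions themselves, the expected value is
#' estimated leave-one-out from lattice neighbours (axis-symmetric
#' averages in the lattice interior, linear extrapolation at its edges,
#' both exact for planes), so that reference fitness retains the
#' measurement noise and plate-level control CV and FUV statistics are
#' well defined.
#'
#' Missing reference colonies invalidate every position whose
#' interpolation cell (or leave-one-out estimate) uses them; those
#' colonies are set to `NA` with flag `grid_neighbour_missing`.
#'
#' @param plate data frame for one plate with columns `row`, `col`,
#'   `ref` (logical), the measurement column and optionally `qc_flag`.
#' @param value name of the raw measurement column (default `"size"`).
#' @param out name of the fitness column to create.
#' @return `plate` with the fitness column and updated `qc_flag`.
#' @export
grid_normalize <- function(plate, value = "size",
                           out = paste0("fitness_", value)) {
  stopifnot(all(c("row", "col", "ref", value) %in% names(plate)))
  if (is.null(plate$qc_flag)) plate$qc_flag <- "ok"
  x <- plate[[value]]
  x[!is.na(x) & x == 0] <- NA_real_
  plate$qc_flag[is.na(x) & plate$qc_flag == "ok"] <- "missing"

  ref_rows <- sort(unique(plate$row[plate$ref]))
  ref_cols <- sort(unique(plate$col[plate$ref]))
  nr <- length(ref_rows)
  nc <- length(ref_cols)
  if (nr < 2L || nc < 2L) {
    stop("reference grid too sparse for interpolation", call. = FALSE)
  }
  V <- matrix(NA_real_, nr, nc)
  is_ref <- plate$ref
  V[cbind(match(plate$row[is_ref], ref_rows),
          match(plate$col[is_ref], ref_cols))] <- x[is_ref]
  n_ref_ok <- sum(!is.na(V))
  if (n_ref_ok == 0L) {
    plate$qc_flag[] <- "plate_failed"
    plate[[out]] <- NA_real_
    return(plate)
  }
  if (n_ref_ok < 4L) {
    stop("plate failure: fewer than 4 non-missing reference colonies",
         call. = FALSE)
  }

  expected <- rep(NA_real_, nrow(plate))

  ## non-reference positions: bilinear over the enclosing (or nearest)
  ## lattice cell, linearly extended beyond the outer reference lines
  mut <- !is_ref
  if (any(mut)) {
    i <- pmin(pmax(findInterval(plate$row[mut], ref_rows), 1L), nr - 1L)
    j <- pmin(pmax(findInterval(plate$col[mut], ref_cols), 1L), nc - 1L)
    t <- (plate$row[mut] - ref_rows[i]) / (ref_rows[i + 1L] - ref_rows[i])
    u <- (plate$col[mut] - ref_cols[j]) / (ref_cols[j + 1L] - ref_cols[j])
    v00 <- V[cbind(i, j)]
    v10 <- V[cbind(i + 1L, j)]
    v01 <- V[cbind(i, j + 1L)]
    v11 <- V[cbind(i + 1L, j + 1L)]
    expected[mut] <- (1 - t) * (1 - u) * v00 + t * (1 - u) * v10 +
      (1 - t) * u * v01 + t * u * v11
  }

  ## reference positions: leave-one-out neighbour estimate per axis
  if (any(is_ref)) {
    a <- match(plate$row[is_ref], ref_rows)
    b <- match(plate$col[is_ref], ref_cols)
    axis_est <- function(a, b, n, along_rows) {
      p <- ifelse(a == 1L, 2L, ifelse(a == n, n - 1L, a - 1L))
      q <- ifelse(a == 1L, 3L, ifelse(a == n, n - 2L, a + 1L))
      w1 <- ifelse(a == 1L | a == n, 2, 0.5)
      w2 <- ifelse(a == 1L | a == n, -1, 0.5)
      if (along_rows) {
        w1 * V[cbind(p, b)] + w2 * V[cbind(q, b)]
      } else {
        w1 * V[cbind(b, p)] + w2 * V[cbind(b, q)]
      }
    }
    er <- axis_est(a, b, nr, TRUE)
    ec <- axis_est(b, a, nc, FALSE)
    both <- !is.na(er) & !is.na(ec)
    e <- ifelse(both, (er + ec) / 2, ifelse(is.na(er), ec, er))
    expected[is_ref] <- e
  }

  if (any(!is.na(expected) & expected <= 0)) {
    stop("plate failure: non-positive expected wild-type value",
         call. = FALSE)
  }
  fit <- x / expected
  bad <- is.na(expected) & !is.na(x)
  plate$qc_flag[bad & plate$qc_flag == "ok"] <- "grid_neighbour_missing"
  fit[bad] <- NA_real_
  fit[!is.finite(fit)] <- NA_real_
  plate[[out]] <- fit
  plate
}

#' Row/column median correction of one plate
#'
#' Divides each value by its row median, then by the column median of
#' the row-corrected values, and finally rescales so the overall plate
#' median is 1. Absent values are excluded from the medians and remain
#' absent; an entirely absent row or column simply stays absent.
#'
#' @param plate data frame for one plate with `row`, `col` and the
#'   value column.
#' @param value name of the column to correct (typically a fitness
#'   column from [grid_normalize()], or raw redness).
#' @param out name of the output column (defaults to `value`, i.e.
#'   correction in place).
#' @return `plate` with the corrected column.
#' @export
rcmedian_normalize <- function(plate, value = "fitness_size",
                               out = value) {
  stopifnot(all(c("row", "col", value) %in% names(plate)))
  n_rows <- max(plate$row)
  n_cols <- max(plate$col)
  M <- matrix(NA_real_, n_rows, n_cols)
  M[cbind(plate$row, plate$col)] <- plate[[value]]
  rmed <- apply(M, 1L, stats::median, na.rm = TRUE)
  M <- M / rmed
  cmed <- apply(M, 2L, stats::median, na.rm = TRUE)
  M <- sweep(M, 2L, cmed, "/")
  overall <- stats::median(M, na.rm = TRUE)
  if (!is.na(overall) && overall > 0) M <- M / overall
  plate[[out]] <- M[cbind(plate$row, plate$col)]
  plate
}

## variance inflation of the leave-one-out reference estimate at each
## reference node, given the availability pattern of its neighbours:
## sum of squared estimator weights (the relative extra variance the
## estimate adds to the normalized reference value)
ref_loo_varw <- function(plate) {
  ref_rows <- sort(unique(plate$row[plate$ref]))
  ref_cols <- sort(unique(plate$col[plate$ref]))
  nr <- length(ref_rows)
  nc <- length(ref_cols)
  x <- plate[[if ("size" %in% names(plate)) "size" else "redness"]]
  ok <- matrix(FALSE, nr, nc)
  is_ref <- plate$ref
  ok[cbind(match(plate$row[is_ref], ref_rows),
           match(plate$col[is_ref], ref_cols))] <-
    !is.na(x[is_ref]) & x[is_ref] != 0
  axis_w2 <- function(a, n) ifelse(a == 1L | a == n, 5, 0.5)
  nbr_ok <- function(a, b, n, rows) {
    p <- ifelse(a == 1L, 2L, ifelse(a == n, n - 1L, a - 1L))
    q <- ifelse(a == 1L, 3L, ifelse(a == n, n - 2L, a + 1L))
    if (rows) ok[cbind(p, b)] & ok[cbind(q, b)]
    else ok[cbind(b, p)] & ok[cbind(b, q)]
  }
  a <- match(plate$row[is_ref], ref_rows)
  b <- match(plate$col[is_ref], ref_cols)
  has_r <- nbr_ok(a, b, nr, TRUE)
  has_c <- nbr_ok(b, a, nc, FALSE)
  w2r <- axis_w2(a, nr)
  w2c <- axis_w2(b, nc)
  varw <- ifelse(has_r & has_c, (w2r + w2c) / 4,
                 ifelse(has_r, w2r, ifelse(has_c, w2c, NA_real_)))
  stats::setNames(varw, which(is_ref))
}

#' Plate-level signal metrics: control CV and fraction of unexplained
#' variance
#'
#' The control CV is the coefficient of variation (sd/mean) of the
#' post-normalization reference-colony fitness. The FUV is the variance
#' of post-normalization reference fitness divided by the variance of
#' the pre-normalization reference sizes rescaled to mean 1, corrected
#' for the variance the leave-one-out reference estimate itself
#' contributes (so that a plate of pure i.i.d. noise has FUV near 1):
#' values near 0 mean normalization explains most of the spatial
#' variation, values near 1 that the plate carried no removable
#' structure.
#'
#' @param plate one plate's data frame with `ref`, the raw column and
#'   the fitness column.
#' @param raw,fitness column names of the raw and normalized values.
#' @param grid whether `fitness` came from reference-grid normalization
#'   (enables the leave-one-out variance correction of the FUV); the
#'   redness readout, corrected only by row/column medians, uses
#'   `FALSE`.
#' @return one-row data frame with `cv` and `fuv` (`NA` when fewer than
#'   two reference values are available or variances are degenerate).
#' @export
plate_signal_metrics <- function(plate, raw = "size",
                                 fitness = "fitness_size",
                                 grid = identical(raw, "size")) {
  f <- plate[[fitness]][plate$ref]
  r <- plate[[raw]][plate$ref]
  r[!is.na(r) & r == 0] <- NA_real_
  f <- f[!is.na(f)]
  r <- r[!is.na(r)]
  cv <- if (length(f) >= 2L) stats::sd(f) / mean(f) else NA_real_
  fuv <- NA_real_
  if (length(f) >= 2L && length(r) >= 2L) {
    vraw <- stats::var(r / mean(r))
    if (is.finite(vraw) && vraw > 0) {
      inflation <- 1
      if (grid && "ref" %in% names(plate)) {
        varw <- ref_loo_varw(plate)
        if (any(!is.na(varw))) {
          inflation <- 1 + mean(varw, na.rm = TRUE)
        }
      }
      fuv <- stats::var(f) / vraw / inflation
    }
  }
  data.frame(cv = cv, fuv = fuv)
}

#' Normalize a tidy colony dataset plate by plate
#'
#' Applies reference-grid normalization followed by row/column median
#' correction to the colony-size readout, and row/column median
#' correction (only) to the redness readout when present, mirroring the
#' standard processing of the two readouts.
#'
#' @param dataset tidy colony data frame (see [assemble_dataset()] or
#'   [simulate_experiment()]).
#' @param gridnorm,rcmedian logical switches for the two size
#'   corrections.
#' @return `dataset` with `fitness_size` (and `fitness_redness`)
#'   columns and updated `qc_flag`s.
#' @export
normalize_dataset <- function(dataset, gridnorm = TRUE, rcmedian = TRUE) {
  if (is.null(dataset$qc_flag)) dataset$qc_flag <- "ok"
  plates <- split(seq_len(nrow(dataset)), dataset$plate_id)
  pieces <- lapply(plates, function(idx) {
    plate <- dataset[idx, , drop = FALSE]
    if ("size" %in% names(plate)) {
      if (gridnorm) {
        plate <- grid_normalize(plate, "size")
      } else {
        plate$fitness_size <- ifelse(plate$size > 0, plate$size, NA_real_)
      }
      if (rcmedian) plate <- rcmedian_normalize(plate, "fitness_size")
    }
    if ("redness" %in% names(plate)) {
      plate <- rcmedian_normalize(plate, "redness", out = "fitness_redness")
    }
    plate
  })
  out <- do.call(rbind, pieces)
  out <- out[order(unlist(plates)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quality-control filtering of a normalized dataset
#'
#' Colony level: missing colonies stay absent; colonies with circularity
#' below `circ_min` are set absent for the size readout (flag
#' `low_circularity`). Plate level: size plates whose wild-type control
#' CV exceeds `cv_max_size` and redness plates whose control CV exceeds
#' `cv_max_redness` are failed entirely; in overexpression mode, size
#' plates with FUV above `fuv_max` or control CV above `cv_max_control`
#' are additionally failed. QC never errors on data content; every
#' exclusion is listed in the report.
#'
#' @param dataset normalized tidy dataset (see [normalize_dataset()]).
#' @param mode `"deletion"` or `"overexpression"`.
#' @param circ_min circularity threshold (size readout only).
#' @param cv_max_size,cv_max_redness plate-level control-CV thresholds.
#' @param fuv_max,cv_max_control additional overexpression-mode plate
#'   thresholds.
#' @return list with `dataset` (filtered), `plates` (per-plate QC table
#'   with `cv`, `fuv`, `pass`, `reason` per readout) and `exclusions`
#'   (per-reason colony counts).
#' @export
qc_filter <- function(dataset, mode = c("deletion", "overexpression"),
                      circ_min = 0.85, cv_max_size = 0.2,
                      cv_max_redness = 0.05, fuv_max = 1,
                      cv_max_control = 0.5) {
  mode <- match.arg(mode)
  if (is.null(dataset$qc_flag)) dataset$qc_flag <- "ok"

  has_size <- "fitness_size" %in% names(dataset)
  has_red <- "fitness_redness" %in% names(dataset)

  if (has_size && "circularity" %in% names(dataset)) {
    low <- !is.na(dataset$circularity) & dataset$circularity < circ_min &
      !is.na(dataset$fitness_size)
    dataset$fitness_size[low] <- NA_real_
    dataset$qc_flag[low & dataset$qc_flag == "ok"] <- "low_circularity"
  }

  plates <- split(seq_len(nrow(dataset)), dataset$plate_id)
  qc <- list()
  for (pid in names(plates)) {
    idx <- plates[[pid]]
    plate <- dataset[idx, , drop = FALSE]
    if (has_size) {
      m <- plate_signal_metrics(plate, "size", "fitness_size")
      fail <- !is.na(m$cv) &
        (m$cv > cv_max_size ||
           (mode == "overexpression" &&
              (m$cv > cv_max_control ||
                 (!is.na(m$fuv) && m$fuv > fuv_max))))
      reason <- if (!fail) "" else if (m$cv > cv_max_size) {
        "control CV above threshold"
      } else "FUV or control CV above overexpression threshold"
      if (fail) {
        dataset$fitness_size[idx] <- NA_real_
        dataset$qc_flag[idx] <- "plate_failed"
      }
      qc[[length(qc) + 1L]] <- data.frame(
        plate_id = pid, readout = "size", cv = m$cv, fuv = m$fuv,
        pass = !fail, reason = reason, stringsAsFactors = FALSE)
    }
    if (has_red) {
      m <- plate_signal_metrics(plate, "redness", "fitness_redness")
      fail <- !is.na(m$cv) && m$cv > cv_max_redness
      if (fail) {
        dataset$fitness_redness[idx] <- NA_real_
        dataset$qc_flag[idx] <- "plate_failed"
      }
      qc[[length(qc) + 1L]] <- data.frame(
        plate_id = pid, readout = "redness", cv = m$cv, fuv = m$fuv,
        pass = !fail,
        reason = if (fail) "control CV above threshold" else "",
        stringsAsFactors = FALSE)
    }
  }
  qc <- do.call(rbind, qc)
  excl <- as.data.frame(table(flag = dataset$qc_flag),
                        stringsAsFactors = FALSE)
  names(excl) <- c("flag", "n")
  list(dataset = dataset, plates = qc, exclusions = excl)
}
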