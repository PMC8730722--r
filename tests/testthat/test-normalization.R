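test_that("grid normalization is exact on uniform and planar plates", {
  p <- make_plate(100)
  g <- grid_normalize(p)
  expect_true(all(abs(g$fitness_size - 1) < 1e-12))

  # an exact plane is reproduced everywhere, including reference nodes
  # and the border rows/columns beyond the outer reference lines
  p$size <- 50 + 3 * p$row + 2 * p$col
  g <- grid_normalize(p)
  expect_true(all(abs(g$fitness_size - 1) < 1e-12))
})

test_that("missing reference colonies invalidate their interpolation cells", {
  p <- make_plate(100)
  p$size[p$row == 1 & p$col == 1] <- 0
  g <- grid_normalize(p)
  flagged <- g$qc_flag == "grid_neighbour_missing"
  expect_true(all(g$row[flagged] <= 3 & g$col[flagged] <= 3))
  expect_true(sum(flagged) >= 3)
  expect_true(all(is.na(g$fitness_size[flagged])))
  # the rest of the plate is normalized as usual
  rest <- !flagged & g$qc_flag == "ok"
  expect_true(all(abs(g$fitness_size[rest] - 1) < 1e-12))
  # an all-missing grid fails the whole plate
  p2 <- make_plate(100)
  p2$size[p2$ref] <- 0
  g2 <- grid_normalize(p2)
  expect_true(all(g2$qc_flag == "plate_failed"))
})

test_that("row/column median correction fixes single-row bias and keeps NAs", {
  p <- make_plate(100)
  g <- grid_normalize(p)
  r0 <- rcmedian_normalize(g)
  expect_true(all(abs(r0$fitness_size - 1) < 1e-12))  # all-equal unchanged

  g$fitness_size[g$row == 5] <- g$fitness_size[g$row == 5] * 2
  g$fitness_size[g$row == 7 & g$col == 3] <- NA
  r <- rcmedian_normalize(g)
  expect_true(all(abs(r$fitness_size[!is.na(r$fitness_size)] - 1) < 1e-12))
  expect_true(is.na(r$fitness_size[r$row == 7 & r$col == 3]))
})

test_that("normalization is scale-equivariant and removes planar bias", {
  set.seed(42)
  cfg <- sim_config(sprintf("s%02d", 1:40), "benign", wt_size_cv = 0.05,
                    n_bio = 6, seed = 11,
                    spatial = list(slope_row = 0.4, slope_col = 0.3))
  ex <- simulate_experiment(cfg)
  ds <- normalize_dataset(ex$colonies)
  ds2 <- ex$colonies
  ds2$size <- ds2$size * 7.3
  ds2 <- normalize_dataset(ds2)
  expect_equal(ds$fitness_size, ds2$fitness_size, tolerance = 1e-12)

  # per plate: the raw reference colonies carry a row/column trend that
  # is gone (below the noise floor) after normalization
  slope <- function(v, d) {
    max(abs(stats::coef(stats::lm(v ~ row + col, data = d))[c("row",
                                                              "col")]))
  }
  pre <- post <- cv_pre <- cv_post <- numeric(0)
  for (pid in unique(ds$plate_id)) {
    wt <- ds[ds$plate_id == pid & ds$ref & !is.na(ds$fitness_size), ]
    raw <- ex$colonies[ex$colonies$plate_id == pid & ex$colonies$ref, ]
    raw$rel <- raw$size / mean(raw$size)
    pre <- c(pre, slope(raw$rel, raw))
    post <- c(post, slope(wt$fitness_size, wt))
    cv_pre <- c(cv_pre, stats::sd(raw$rel) / mean(raw$rel))
    cv_post <- c(cv_post, stats::sd(wt$fitness_size) / mean(wt$fitness_size))
  }
  expect_gt(mean(pre), 0.005)    # gradients are present before
  expect_lt(max(post), 0.003)    # and gone after
  # normalization reduces the wild-type CV on gradient plates
  expect_lt(mean(cv_post), mean(cv_pre))
  # and never emits negative or infinite fitness
  expect_true(all(is.na(ds$fitness_size) |
                    (is.finite(ds$fitness_size) & ds$fitness_size > 0)))
})

test_that("plate signal metrics follow their contracts", {
  # zero noise: CV 0, FUV guarded to absent
  p <- make_plate(100)
  g <- grid_normalize(p)
  m <- plate_signal_metrics(g)
  expect_equal(m$cv, 0)
  expect_true(is.na(m$fuv))

  # pure i.i.d. noise: FUV near 1 after the leave-one-out correction
  cfg <- sim_config("a", "benign", wt_size_cv = 0.05, n_bio = 40,
                    seed = 3)
  ds <- normalize_dataset(simulate_experiment(cfg)$colonies,
                          rcmedian = FALSE)
  mm <- do.call(rbind, lapply(split(ds, ds$plate_id),
                              plate_signal_metrics))
  expect_lt(abs(mean(mm$fuv) - 1), 0.15)

  # plane-gradient plates: normalization explains the gradient, FUV << 1
  cfg2 <- sim_config("a", "benign", wt_size_cv = 0.02, n_bio = 15,
                     seed = 4,
                     spatial = list(slope_row = 0.5, slope_col = 0.4,
                                    bump_amp = 0.2))
  ds2 <- normalize_dataset(simulate_experiment(cfg2)$colonies,
                           rcmedian = FALSE)
  mm2 <- do.call(rbind, lapply(split(ds2, ds2$plate_id),
                               plate_signal_metrics))
  expect_lt(mean(mm2$fuv), 0.3)
  # fewer than two reference values: metrics absent
  p3 <- make_plate(100)
  g3 <- grid_normalize(p3)
  g3$fitness_size[g3$ref] <- NA
  m3 <- plate_signal_metrics(g3)
  expect_true(is.na(m3$cv) && is.na(m3$fuv))
})

test_that("QC filtering applies colony and plate rules without throwing", {
  cfg <- sim_config(sprintf("s%02d", 1:20), "benign", wt_size_cv = 0.05,
                    n_bio = 2, seed = 8)
  ds <- normalize_dataset(simulate_experiment(cfg)$colonies)

  # colony with low circularity is excluded for the size readout
  ds$circularity[1] <- 0.80
  q <- qc_filter(ds)
  expect_identical(q$dataset$qc_flag[1], "low_circularity")
  expect_true(is.na(q$dataset$fitness_size[1]))

  # plate with inflated wild-type spread fails entirely
  ds2 <- ds
  pid <- ds2$plate_id[1]
  on_plate <- ds2$plate_id == pid & ds2$ref
  set.seed(1)
  ds2$fitness_size[on_plate] <-
    ds2$fitness_size[on_plate] * exp(stats::rnorm(sum(on_plate), 0, 0.3))
  q2 <- qc_filter(ds2)
  row <- q2$plates[q2$plates$plate_id == pid & q2$plates$readout == "size", ]
  expect_false(row$pass)
  expect_true(all(is.na(q2$dataset$fitness_size[q2$dataset$plate_id == pid])))

  # clean plates: no plate failures, report says so
  q3 <- qc_filter(ds[ds$circularity >= 0.85, ])
  expect_true(all(q3$plates$pass))
})
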