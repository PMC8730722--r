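test_that("welch_test matches hand computation and the textbook formula", {
  w <- welch_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$t, -1.224745, tolerance = 1e-6)
  expect_equal(w$df, 4)
  expect_equal(w$p, 0.2878641, tolerance = 1e-6)

  set.seed(10)
  for (i in 1:25) {
    a <- stats::rnorm(sample(3:12, 1), mean = stats::runif(1, 0, 2))
    b <- stats::rnorm(sample(3:12, 1), sd = stats::runif(1, 0.5, 2))
    w <- welch_test(a, b)
    o <- welch_oracle(a, b)
    expect_equal(w$t, o$t, tolerance = 1e-10)
    expect_equal(w$df, o$df, tolerance = 1e-10)
    expect_equal(w$p, o$p, tolerance = 1e-10)
    # scale invariance
    w10 <- welch_test(10 * a, 10 * b)
    expect_equal(w10$t, w$t, tolerance = 1e-10)
    expect_equal(w10$p, w$p, tolerance = 1e-10)
  }
})

test_that("welch_test degenerate-variance conventions hold", {
  expect_equal(welch_test(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(welch_test(c(2, 2), c(2, 2))$p, 1)
  z <- welch_test(c(2, 2), c(3, 3))
  expect_equal(z$p, 0)
  expect_true(is.infinite(z$t) && z$t < 0)
  expect_error(welch_test(1, c(1, 2)), "at least 2")
})

test_that("bh_adjust is a per-group step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "validation error")

  set.seed(11)
  for (i in 1:20) {
    p <- stats::runif(sample(2:30, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    # permutation leaves the multiset of adjusted values invariant
    perm <- sample(length(p))
    expect_equal(sort(bh_adjust(p[perm])), sort(bh_adjust(p)),
                 tolerance = 1e-12)
  }
  # grouping adjusts each condition family separately
  p <- c(0.01, 0.04, 0.01, 0.04)
  g <- c("a", "a", "b", "b")
  expect_equal(bh_adjust(p, g), c(bh_oracle(p[1:2]), bh_oracle(p[3:4])))
})

test_that("summaries compute MES by definition with the right baselines", {
  mk <- function(strain, fit, ref = FALSE, cond = "benign") {
    data.frame(plate_id = "P1", condition = cond, strain = strain,
               ref = ref, fitness_size = fit, stringsAsFactors = FALSE)
  }
  ds <- rbind(mk("m", c(1.10, 1.08, 1.12)),
              mk("grid", c(0.99, 1.00, 1.01, 1.00), ref = TRUE))
  conds <- data.frame(condition = "benign", is_control = TRUE,
                      control_condition = "benign",
                      stressor_set = "benign")
  s <- summarize_effects(ds, conds)
  expect_equal(s$MES, 1.10)
  expect_equal(s$log2_MES, log2(1.10))
  expect_equal(s$observation_count, 3L)
  expect_identical(s$baseline, "vs-wild-type")

  # identical mutant and baseline: MES 1, p 1
  ds2 <- rbind(mk("m", c(1, 2, 3)), mk("grid", c(1, 2, 3), ref = TRUE))
  s2 <- summarize_effects(ds2, conds)
  expect_equal(s2$MES, 1)
  expect_equal(s2$p_value, 1)

  # stress condition uses the strain's own control-condition baseline
  conds3 <- data.frame(condition = c("benign", "stress"),
                       is_control = c(TRUE, FALSE),
                       control_condition = "benign",
                       stressor_set = c("benign", "stress"))
  ds3 <- rbind(mk("m", c(0.8, 0.82, 0.78), cond = "stress"),
               mk("m", c(1.0, 1.02, 0.98), cond = "benign"),
               mk("grid", c(1, 1, 1, 1.0001), ref = TRUE, cond = "benign"),
               mk("grid", c(1, 1, 1, 1.0001), ref = TRUE, cond = "stress"))
  s3 <- summarize_effects(ds3, conds3)
  st <- s3[s3$condition == "stress", ]
  expect_identical(st$baseline, "vs-control-condition")
  expect_equal(st$MES, 0.8)
})

test_that("hit calling applies the significance and effect-size filters", {
  summ <- data.frame(
    strain = c("a", "b", "c", "d"), condition = "x", readout = "size",
    MES = c(1.08, 1.03, 0.90, 0.85),
    log2_MES = log2(c(1.08, 1.03, 0.90, 0.85)),
    adjusted_p = c(0.01, 0.001, 0.2, 0.003),
    stringsAsFactors = FALSE)
  h <- call_hits(summ, mode = "deletion")
  expect_identical(h$is_hit, c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(h$direction, c("+", "+", "-", "-"))
  # redness readout uses the 1.5% effect threshold
  summ$readout <- "redness"
  summ$MES <- c(1.02, 1.01, 0.99, 1.0)
  summ$log2_MES <- log2(summ$MES)
  hr <- call_hits(summ, mode = "deletion")
  expect_identical(hr$is_hit, c(TRUE, FALSE, FALSE, FALSE))
  # overexpression: p <= 0.01 and |MES - 1| >= 5%
  summ2 <- data.frame(
    strain = c("a", "b"), condition = "x", readout = "size",
    MES = c(1.05, 1.04), log2_MES = log2(c(1.05, 1.04)),
    adjusted_p = c(0.01, 0.001), stringsAsFactors = FALSE)
  ho <- call_hits(summ2, mode = "overexpression")
  expect_identical(ho$is_hit, c(TRUE, FALSE))
})

test_that("concordance classes follow the effect-size agreement rules", {
  summ <- data.frame(
    strain = c("a1", "a2", "b1", "b2", "c1", "c2", "d1"),
    condition = "x", readout = "size",
    MES = c(1.08, 1.07, 1.08, 1.03, 1.08, 0.92, 1.2),
    stringsAsFactors = FALSE)
  gm <- data.frame(strain = summ$strain,
                   gene = sub("[0-9]$", "", summ$strain))
  cc <- concordance(summ, gm)
  cls <- stats::setNames(cc$class, cc$gene)
  expect_identical(cls[["a"]], "agree")
  expect_identical(cls[["b"]], "trend")
  expect_identical(cls[["c"]], "opposite")
  expect_false("d" %in% cc$gene)  # single mutants are skipped
  # a mutant within 2% of neutral: no phenotype
  summ$MES[2] <- 1.01
  expect_identical(concordance(summ, gm)$class[1], "no-phenotype")
})

test_that("injected effects are recovered with the right direction", {
  # full 384 plates (144 strains x 2 technical replicates) so that the
  # row/column median correction sees well-populated rows
  eff <- data.frame(strain = c("up", "down"), condition = "stress",
                    growth = c(1.15, 1 / 1.15))
  cfg <- sim_config(c("up", "down", sprintf("n%03d", 1:142)),
                    c("benign", "stress"), strain_effects = eff,
                    seed = 21)
  ex <- simulate_experiment(cfg)
  ds <- normalize_dataset(ex$colonies)
  h <- call_hits(summarize_effects(ds, ex$conditions), mode = "deletion")
  up <- h[h$strain == "up" & h$condition == "stress", ]
  dn <- h[h$strain == "down" & h$condition == "stress", ]
  expect_lt(abs(up$MES - 1.15), 0.08)
  expect_lt(abs(dn$MES - 1 / 1.15), 0.08)
  expect_identical(up$direction, "+")
  expect_identical(dn$direction, "-")
  expect_true(up$is_hit && dn$is_hit)
})

test_that("detection rate is monotone in effect size with sane endpoints", {
  ps <- power_scan(c(0, 0.5), n_runs = 8, n_strains = 60, n_bio = 4,
                   seed = 31)
  expect_lt(ps$detection_rate[1], 0.3)   # null effect: near the FPR
  expect_equal(ps$detection_rate[2], 1)  # saturating effect
})
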