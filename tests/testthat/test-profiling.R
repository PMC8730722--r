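test_that("z-score transform follows (MES - 1) / SD_wt", {
  mes <- matrix(c(1.10, 1.00, 0.85), 1,
                dimnames = list("s", c("c1", "c2", "c3")))
  z <- zscore_transform(mes, c(c1 = 0.05, c2 = 0.10, c3 = 0.05))
  expect_equal(unname(z[1, ]), c(2, 0, -3))
  expect_warning(
    z2 <- zscore_transform(mes, c(c1 = 0.05, c2 = 0, c3 = 0.05)),
    "non-positive")
  expect_identical(colnames(z2), c("c1", "c3"))
})

test_that("condition aggregation keeps the signed strongest response", {
  z <- matrix(c(0.5, -2.1, 1.0,
                0.7, NA, NA,
                NA, NA, NA,
                1.5, -1.5, 0), 4, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c", "d"),
                              c("x_lo", "x_mid", "x_hi")))
  sets <- c(x_lo = "x", x_mid = "x", x_hi = "x")
  a <- aggregate_conditions(z, sets)
  expect_equal(a["a", "x"], -2.1)       # strongest |z| wins, sign kept
  expect_equal(a["b", "x"], 0.7)
  expect_true(is.na(a["c", "x"]))       # all-absent set stays absent
  expect_equal(a["d", "x"], 1.5)        # equal-magnitude tie: positive
  # singleton sets are the identity
  s1 <- aggregate_conditions(z, c(x_lo = "l", x_mid = "m", x_hi = "h"))
  expect_equal(unname(s1[, c("l", "m", "h")]), unname(z))
  # aggregation is idempotent on already-aggregated matrices
  expect_equal(aggregate_conditions(a, c(x = "x")), a)
  expect_error(aggregate_conditions(z, c(x_lo = "x")), "unmapped")
})

test_that("discretization at +/-1.5 SD is correct and monotone", {
  z <- matrix(c(2, -1.49, 0, 1.51, -1.5, 1.5), 1)
  expect_equal(as.vector(discretize(z)), c(1, 0, 0, 1, 0, 0))
  # monotone in MES for fixed SD
  mes <- sort(stats::runif(50, 0.5, 1.5))
  d <- as.vector(discretize(matrix((mes - 1) / 0.05, 1)))
  expect_true(all(diff(d) >= 0))
})

test_that("minimum-hit filtering and imputation match the conventions", {
  set.seed(3)
  tern <- matrix(0L, 4, 41,
                 dimnames = list(c("four", "five", "zero", "many"), NULL))
  tern["four", 1:4] <- 1L
  tern["five", 1:5] <- -1L
  tern["many", 1:12] <- 1L
  tern["many", 40] <- NA
  f <- filter_min_hits(tern, min_hits = 5)
  expect_identical(rownames(f), c("five", "many"))
  expect_false(anyNA(f))
  expect_equal(unname(f["many", 40]), 0L)
  # an all-zero matrix yields an explicit empty result
  empty <- filter_min_hits(matrix(0L, 3, 5))
  expect_equal(nrow(empty), 0L)
})

test_that("ward clustering matches an independent linkage oracle", {
  # 6-profile toy matrix; reference flat clusters computed externally
  # with scipy.cluster.hierarchy ward/maxclust and frozen here
  M <- matrix(c( 1, 1, 0, -1,  0,  1,
                 1, 1, 0, -1,  0,  0,
                 1, 0, 0, -1,  1,  1,
                -1,-1, 1,  1,  0, -1,
                -1,-1, 1,  0,  0, -1,
                 0,-1, 1,  1, -1, -1), 6, 6, byrow = TRUE,
              dimnames = list(paste0("s", 1:6), paste0("c", 1:6)))
  cl <- cluster_profiles(M, "ward", "euclidean", k = 2)
  frozen <- c(1, 1, 1, 2, 2, 2)
  expect_equal(ari(cl$labels, frozen), 1)
  # frozen merge heights from the same reference linkage
  expect_equal(sort(cl$tree$height),
               c(1, 1, 1.73205081, 1.73205081, 6.13731755),
               tolerance = 1e-6)
  expect_error(cluster_profiles(M, k = 10), "exceeds")
  # identical rows always share a label
  M2 <- rbind(a = c(1, 0, 1), b = c(1, 0, 1), c = c(-1, 1, -1))
  cl2 <- cluster_profiles(M2, k = 2)
  expect_equal(cl2$labels[["a"]], cl2$labels[["b"]])
  # newick export covers every leaf
  dir <- withr::local_tempdir()
  nwk <- readLines(write_linkage_newick(cl, file.path(dir, "t.nwk")))
  expect_true(all(vapply(paste0("s", 1:6), grepl, logical(1), x = nwk)))
})

test_that("correlation network edges satisfy both filters by reconstruction", {
  set.seed(7)
  M <- matrix(sample(c(-1L, 0L, 1L), 20 * 15, replace = TRUE,
                     prob = c(0.15, 0.7, 0.15)), 20, 15,
              dimnames = list(sprintf("s%02d", 1:20), NULL))
  M[2, ] <- M[1, ]            # a planted perfect correlation
  M[3, ] <- 0L                # a constant profile: no edges allowed
  net <- correlation_network(M)
  expect_true(all(abs(net$edges$r) > 0.6))
  expect_true(all(net$edges$adjusted_p < 0.01))
  expect_false(any(net$edges$from == net$edges$to))
  expect_false("s03" %in% c(net$edges$from, net$edges$to))
  expect_true(any(net$edges$from == "s01" & net$edges$to == "s02"))

  # independent reconstruction with cor.test + step-up BH
  pairs <- utils::combn(nrow(M), 2)
  keep <- apply(pairs, 2, function(ij) {
    stats::sd(M[ij[1], ]) > 0 && stats::sd(M[ij[2], ]) > 0
  })
  ct <- apply(pairs[, keep, drop = FALSE], 2, function(ij) {
    h <- suppressWarnings(stats::cor.test(M[ij[1], ], M[ij[2], ]))
    c(r = unname(h$estimate), p = h$p.value)
  })
  adj <- bh_oracle(ct["p", ])
  want <- which(abs(ct["r", ]) > 0.6 & adj < 0.01)
  got_keys <- paste(net$edges$from, net$edges$to)
  want_keys <- apply(pairs[, keep, drop = FALSE][, want, drop = FALSE],
                     2, function(ij) {
                       paste(rownames(M)[ij[1]], rownames(M)[ij[2]])
                     })
  expect_setequal(got_keys, want_keys)
})

test_that("borderline correlations pass the r filter but fail the p filter", {
  # hand-checked pair: r ~ 0.845, t-test p ~ 0.0715 on 3 df
  M <- rbind(a = c(1, 1, 0, 0, -1), b = c(1, 0, 0, 0, -1))
  net <- correlation_network(M)
  expect_equal(net$n_pairs_tested, 1L)
  expect_equal(nrow(net$edges), 0L)
  # the underlying statistics match the frozen hand computation
  ct <- stats::cor.test(M[1, ], M[2, ])
  expect_equal(unname(ct$estimate), 0.8451543, tolerance = 1e-6)
  expect_equal(ct$p.value, 0.0714, tolerance = 2e-3)
})

test_that("community detection separates disconnected cliques deterministically", {
  prof1 <- c(1, 1, -1, 0, 1, -1, 0, 1)
  prof2 <- c(-1, 0, 1, 1, -1, 0, 1, -1)
  M <- rbind(a1 = prof1, a2 = prof1, a3 = prof1,
             b1 = prof2, b2 = prof2, b3 = prof2)
  net <- correlation_network(M)
  comm <- detect_communities(net, seed = 4)
  expect_equal(length(unique(comm[c("a1", "a2", "a3")])), 1L)
  expect_equal(length(unique(comm[c("b1", "b2", "b3")])), 1L)
  expect_false(comm[["a1"]] == comm[["b1"]])
  expect_identical(comm, detect_communities(net, seed = 4))
  # single edge: one community of two
  M2 <- rbind(x = c(1, 0, -1, 1), y = c(1, 0, -1, 1),
              z = c(0, 0, 0, 0))
  net2 <- correlation_network(M2)
  comm2 <- detect_communities(net2, seed = 1)
  expect_equal(comm2[["x"]], comm2[["y"]])
  # SIF and GraphML exports round-trip the edge list
  dir <- withr::local_tempdir()
  sif <- readLines(write_network_sif(net2, file.path(dir, "n.sif")))
  expect_length(sif, nrow(net2$edges))
  write_network_graphml(net2, file.path(dir, "n.graphml"))
  g <- igraph::read_graph(file.path(dir, "n.graphml"), format = "graphml")
  expect_equal(igraph::ecount(g), nrow(net2$edges))
})
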