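# independent oracles used to cross-check the pipeline's statistics

# Welch statistic from the textbook formula (independent of stats::t.test)
welch_oracle <- function(a, b) {
  va <- stats::var(a)
  vb <- stats::var(b)
  na <- length(a)
  nb <- length(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# step-up Benjamini-Hochberg written out directly
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- pmin(rev(cummin(rev(ranked))), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# one bare plate data frame on the standard layout
make_plate <- function(size, strains = sprintf("s%03d", 1:288)) {
  lay <- standard384_layout(strains)
  data.frame(plate_id = "P1", row = lay$row, col = lay$col,
             strain = lay$strain, ref = lay$ref, size = size,
             stringsAsFactors = FALSE)
}
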