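# Independent oracles, deliberately implemented without reusing package
# internals.

# brute-force univariate selection: filter by margins, full sort
oracle_select <- function(va, vb, base_a, base_b, condition, margin,
                          n_select, ids) {
  dir <- switch(condition,
                drive_both = c(1, 1), suppress_both = c(-1, -1),
                drive_A_suppress_B = c(1, -1), drive_B_suppress_A = c(-1, 1))
  ok <- rep(TRUE, length(va))
  ok <- ok & if (dir[1] > 0) va > base_a + margin else va < base_a - margin
  ok <- ok & if (dir[2] > 0) vb > base_b + margin else vb < base_b - margin
  score <- switch(condition,
                  drive_both = va + vb, suppress_both = va + vb,
                  drive_A_suppress_B = va - vb, drive_B_suppress_A = va - vb)
  decreasing <- condition %in% c("drive_both", "drive_A_suppress_B")
  idx <- which(ok)
  ord <- idx[order(if (decreasing) -score[idx] else score[idx], ids[idx])]
  head(ids[ord], n_select)
}

# direct Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# binomial tail by explicit pmf summation
oracle_binom_tail <- function(k, n, a) {
  if (k >= n) return(0)
  sum(vapply((k + 1):n, function(j) choose(n, j) * a^j * (1 - a)^(n - j),
             numeric(1)))
}

# exhaustive best batch by RSA over all size-`batch` subsets
oracle_exhaustive_best <- function(rs_a, rs_b, batch, objective) {
  combos <- utils::combn(length(rs_a$image_ids), batch)
  scores <- apply(combos, 2, function(ix) {
    ids <- rs_a$image_ids[ix]
    rsa_score(compute_rsm(rs_a, ids), compute_rsm(rs_b, ids))
  })
  if (objective == "align") max(scores) else min(abs(scores))
}

spearman <- function(x, y) stats::cor(x, y, method = "spearman")
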