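# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own computation paths.

# mean pairwise Hamming distance over all C(n,2) rows of a haplotype matrix
# (rows = sequences, columns = sites, entries = allele indices)
oracle_khat_pairwise <- function(mat) {
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(mat[i, ] != mat[j, ])
    }
  }
  tot / choose(n, 2)
}

# per-site allele counts of a haplotype matrix, as the list-of-counts form
# the estimators consume (segregating sites only when seg_only)
counts_from_matrix <- function(mat, seg_only = FALSE) {
  out <- lapply(seq_len(ncol(mat)), function(j) {
    as.integer(table(factor(mat[, j], levels = sort(unique(mat[, j])))))
  })
  if (seg_only) out <- out[vapply(out, length, 1L) >= 2] else out
  out
}

# callable bases of [start, end] (1-based closed) given 0-based half-open
# mask intervals, by an explicit per-base boolean array
oracle_callable_bases <- function(start, end, mask_start0, mask_end0) {
  base_ok <- rep(TRUE, end - start + 1)
  for (k in seq_along(mask_start0)) {
    lo <- max(mask_start0[k] + 1, start)
    hi <- min(mask_end0[k], end)
    if (lo <= hi) base_ok[(lo:hi) - start + 1] <- FALSE
  }
  sum(base_ok)
}

# two-sided Fisher exact p by full enumeration over all tables with the
# observed margins: sum of hypergeometric point probabilities <= observed
oracle_fisher_minlik <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  support <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(support, c1, N - c1, r1)
  p_obs <- stats::dhyper(a, c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# flagged tail members by explicit sort-and-count with whole tied blocks
oracle_tail_flags <- function(values, tail_fraction, upper = TRUE) {
  v <- if (upper) sort(values, decreasing = TRUE) else sort(values)
  blocks <- rle(v)
  cum <- cumsum(blocks$lengths) / length(v)
  k <- sum(cum <= tail_fraction)
  if (k == 0) return(numeric())
  v[seq_len(sum(blocks$lengths[seq_len(k)]))]
}

# gene bases covered by a set of windows, per-base boolean array
oracle_gene_coverage <- function(g_start, g_end, w_start, w_end) {
  covered <- rep(FALSE, g_end - g_start + 1)
  for (k in seq_along(w_start)) {
    lo <- max(w_start[k], g_start)
    hi <- min(w_end[k], g_end)
    if (lo <= hi) covered[(lo:hi) - g_start + 1] <- TRUE
  }
  mean(covered)
}
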