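# Independent brute-force oracles used by several test files.

# Consensus rule evaluated directly on a +/-/0 pattern vector.
oracle_consensus <- function(pattern, min_same = 4, max_opposite = 1) {
  up <- sum(pattern == 1); dn <- sum(pattern == -1)
  if (up >= min_same && dn <= max_opposite) return(1L)
  if (dn >= min_same && up <= max_opposite) return(-1L)
  0L
}

# All 3^n significance patterns for n pairs, one row each.
all_patterns <- function(n) {
  as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), n)))
}

# Turn a matrix of patterns (features x pairs) into the long pairwise
# data.frame call_de_consensus consumes: significant entries get p below
# alpha, non-significant ones above.
pairwise_from_patterns <- function(pat, alpha = 0.05) {
  nf <- nrow(pat); np <- ncol(pat)
  data.frame(
    feature_id = rep(sprintf("f%04d", seq_len(nf)), np),
    pair_id = rep(sprintf("P%d", seq_len(np)), each = nf),
    p_raw = as.vector(ifelse(pat == 0L, 1, alpha / 2)),
    p_adj = as.vector(ifelse(pat == 0L, 1, alpha / 2)),
    log2fc = as.vector(pat) * 1.0,
    direction = as.vector(pat),
    stringsAsFactors = FALSE)
}

# Exhaustive hypergeometric tails by enumeration of every size-n draw
# from a universe of N with K marked elements.
oracle_hyper_tails <- function(N, K, n) {
  sets <- utils::combn(N, n)
  ov <- colSums(sets <= K)
  ks <- 0:min(K, n)
  list(over = vapply(ks, function(k) mean(ov >= k), 0),
       under = vapply(ks, function(k) mean(ov <= k), 0),
       ks = ks)
}

# Brute-force RRHO cell: overlap count and both exact tails by summing
# hypergeometric point masses.
oracle_rrho_cell <- function(topA, topB, N) {
  i <- length(topA); j <- length(topB)
  k <- length(intersect(topA, topB))
  over <- sum(stats::dhyper(k:min(i, j), i, N - i, j))
  under <- sum(stats::dhyper(max(0, i + j - N):k, i, N - i, j))
  list(k = k, over = over, under = under)
}

# Rank-based AUROC (Mann-Whitney form), independent of any package.
oracle_auroc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
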