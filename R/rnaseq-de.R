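# Paired-design exact-test differential expression on RNA-seq counts.
#
# Each (control, treated) pair is tested gene by gene with a two-sided
# Fisher exact test on the 2x2 table
#     [ gene count      , library total - gene count ]  (control)
#     [ gene count      , library total - gene count ]  (treated)
# and genes are called differentially expressed by a cross-pair consensus
# rule: significant in the same direction in at least `min_same` pairs and
# in the opposite direction in at most `max_opposite` pairs.

#' Vectorized two-sided Fisher exact test for gene-vs-library tables
#'
#' Computes, for each feature, the two-sided Fisher exact p-value of the
#' 2x2 table contrasting the feature's count against the library remainder
#' in two samples. The two-sided p sums all hypergeometric point masses
#' not exceeding the observed one (the same convention as
#' [stats::fisher.test()]), by direct enumeration of the support - the
#' support length is the feature's total count plus one, so enumeration is
#' cheap even for deep libraries.
#'
#' @param x1,x2 non-negative integer count vectors (same length).
#' @param n1,n2 library totals of the two samples.
#' @return numeric vector of two-sided p-values.
#' @keywords internal
fisher_2x2_p <- function(x1, x2, n1, n2) {
  stopifnot(length(x1) == length(x2))
  N <- n1 + n2
  vapply(seq_along(x1), function(i) {
    K <- x1[i] + x2[i]
    if (K == 0) return(1)
    lo <- max(0L, K - n2); hi <- min(K, n1)
    supp <- lo:hi
    d <- stats::dhyper(supp, n1, n2, K)
    obs <- stats::dhyper(x1[i], n1, n2, K)
    min(1, sum(d[d <= obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Per-pair exact test on a paired count matrix
#'
#' Applies the two-sided Fisher exact test to every feature of one
#' (control, treated) pair and reports raw and Benjamini-Hochberg adjusted
#' p-values, the library-size-normalized log2 fold change, and its sign.
#' The fold change uses a 0.5 pseudo-count on zero cells and is used only
#' for direction and ranking, never for the test itself; features with
#' zero counts in both samples get p = 1 and direction 0.
#'
#' @param counts a [paired_counts()] object.
#' @param pair_index which pair (row of `counts$pairs`) to test.
#' @return data.frame with columns `feature_id`, `pair_id`, `p_raw`,
#'   `p_adj`, `log2fc`, `direction`.
#' @examples
#' sim <- simulate_paired_counts(sim_config(n_genes = 50, seed = 1))
#' head(pairwise_exact_test(sim$counts, 1))
#' @export
pairwise_exact_test <- function(counts, pair_index) {
  stopifnot(inherits(counts, "paired_counts"))
  if (!is_count(pair_index) || pair_index > nrow(counts$pairs))
    xo_stop("pair_index out of range", "invalid_input")
  pr <- counts$pairs[pair_index, ]
  xc <- counts$counts[, pr$control_sample]
  xt <- counts$counts[, pr$treated_sample]
  nc <- sum(xc); nt <- sum(xt)
  if (nc == 0 || nt == 0) xo_stop("zero library total", "degenerate_library")
  p <- fisher_2x2_p(xc, xt, nc, nt)
  pc <- ifelse(xc == 0, 0.5, xc); pt <- ifelse(xt == 0, 0.5, xt)
  lfc <- log2((pt / nt) / (pc / nc))
  lfc[xc == 0 & xt == 0] <- 0
  data.frame(feature_id = rownames(counts$counts),
             pair_id = pr$pair_id,
             p_raw = p,
             p_adj = bh_adjust(p),
             log2fc = lfc,
             direction = as.integer(sign(lfc)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validating wrapper around [stats::p.adjust()] with
#' `method = "BH"`: step-up adjusted values, monotone in rank order,
#' capped at 1.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) xo_stop("empty p-value vector", "invalid_input")
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    xo_stop("p-values must lie in [0,1]", "invalid_input")
  stats::p.adjust(p_values, method = "BH")
}

#' Run the exact test over all pairs
#'
#' @param counts a [paired_counts()] object.
#' @return long data.frame: one row per feature per pair (see
#'   [pairwise_exact_test()]).
#' @export
rnaseq_pairwise <- function(counts) {
  stopifnot(inherits(counts, "paired_counts"))
  do.call(rbind, lapply(seq_len(nrow(counts$pairs)),
                        function(i) pairwise_exact_test(counts, i)))
}

#' Cross-pair consensus differential-expression call
#'
#' Reduces each feature's per-pair significance pattern to {+, -, 0}
#' (significant up / significant down / not significant at `alpha`) and
#' calls the feature +1 when at least `min_same` pairs are significant up
#' with at most `max_opposite` significant down (and symmetrically -1);
#' otherwise 0.
#'
#' @param pairwise long data.frame from [rnaseq_pairwise()].
#' @param alpha per-pair significance level (applied to the adjusted p by
#'   default).
#' @param min_same minimum number of pairs significant in the call
#'   direction.
#' @param max_opposite maximum number of pairs significant in the
#'   opposite direction.
#' @param use_adjusted logical; test `p_adj` (default) or `p_raw` against
#'   `alpha`.
#' @return a `de_table` data.frame: `feature_id`, `call`,
#'   `n_same_direction_significant`, `n_opposite_significant`,
#'   `n_up_significant`, `n_down_significant`, `mean_log2fc`, with the
#'   calling parameters in `attr(, "params")`.
#' @examples
#' sim <- simulate_paired_counts(sim_config(n_genes = 50, seed = 1))
#' de <- call_de_consensus(rnaseq_pairwise(sim$counts))
#' table(de$call)
#' @export
call_de_consensus <- function(pairwise, alpha = 0.05, min_same = 4L,
                              max_opposite = 1L, use_adjusted = TRUE) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    xo_stop("alpha must lie in (0,1)", "invalid_config")
  n_pairs <- length(unique(pairwise$pair_id))
  if (n_pairs < min_same)
    xo_stop("fewer pairs than min_same", "invalid_input")
  if (min_same + max_opposite > n_pairs)
    message("note: min_same + max_opposite exceeds the number of pairs; ",
            "calls are still well defined")
  p <- if (use_adjusted) pairwise$p_adj else pairwise$p_raw
  status <- ifelse(p < alpha, pairwise$direction, 0L)
  ids <- unique(pairwise$feature_id)
  f <- factor(pairwise$feature_id, levels = ids)
  n_up <- as.integer(tapply(status == 1L, f, sum))
  n_dn <- as.integer(tapply(status == -1L, f, sum))
  mean_lfc <- as.numeric(tapply(pairwise$log2fc, f, mean))
  call <- integer(length(ids))
  call[n_up >= min_same & n_dn <= max_opposite] <- 1L
  call[n_dn >= min_same & n_up <= max_opposite] <- -1L
  out <- data.frame(
    feature_id = ids,
    call = call,
    n_same_direction_significant =
      ifelse(call == 1L, n_up, ifelse(call == -1L, n_dn, pmax(n_up, n_dn))),
    n_opposite_significant =
      ifelse(call == 1L, n_dn, ifelse(call == -1L, n_up, pmin(n_up, n_dn))),
    n_up_significant = n_up,
    n_down_significant = n_dn,
    mean_log2fc = mean_lfc,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "params") <- list(alpha = alpha, min_same = min_same,
                              max_opposite = max_opposite,
                              use_adjusted = use_adjusted,
                              n_pairs = n_pairs)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Paired RNA-seq differential expression, end to end
#'
#' Convenience wrapper: per-pair exact tests followed by the consensus
#' call.
#'
#' @inheritParams call_de_consensus
#' @param counts a [paired_counts()] object.
#' @return list with `pairwise` (long per-pair results) and `de` (the
#'   consensus `de_table`).
#' @export
rnaseq_de <- function(counts, alpha = 0.05, min_same = 4L, max_opposite = 1L,
                      use_adjusted = TRUE) {
  pw <- rnaseq_pairwise(counts)
  list(pairwise = pw,
       de = call_de_consensus(pw, alpha = alpha, min_same = min_same,
                              max_opposite = max_opposite,
                              use_adjusted = use_adjusted))
}
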