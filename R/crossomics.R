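# Cross-omics mapping and direction-consistent intersection.

#' Map proteome calls onto gene symbols and restrict both platforms
#'
#' Carries the proteome differential-expression table onto the
#' transcriptome's symbol namespace through an ortholog map, defines the
#' analysis universe as the mapped symbols quantified on both platforms,
#' and re-expresses both DE tables on that universe.
#'
#' Many-to-one collisions are resolved by any-evidence: a symbol is
#' called up (down) if any of its source proteins is, and a symbol whose
#' sources disagree in sign is set to 0 and reported as a conflict.
#'
#' @param proteome_de `de_table` keyed by source (protein) identifiers.
#' @param rnaseq_de `de_table` keyed by target symbols.
#' @param map an `ortholog_map` data.frame (`source_id`,
#'   `target_symbol`, `NA` for unmapped).
#' @return list with `proteome` and `rnaseq` (call data.frames restricted
#'   to the universe), `universe` (symbol vector) and `report` (mapping
#'   counts: mapped, unmapped, collided_symbols, conflicted_symbols,
#'   universe_size).
#' @export
map_and_restrict <- function(proteome_de, rnaseq_de, map) {
  sym <- map$target_symbol[match(proteome_de$feature_id, map$source_id)]
  mapped <- !is.na(sym)
  prot <- data.frame(symbol = sym[mapped],
                     call = proteome_de$call[mapped],
                     stringsAsFactors = FALSE)
  agg_max <- tapply(prot$call, prot$symbol, max)
  agg_min <- tapply(prot$call, prot$symbol, min)
  symbols <- names(agg_max)
  call <- integer(length(symbols))
  call[agg_max == 1 & agg_min > -1] <- 1L
  call[agg_min == -1 & agg_max < 1] <- -1L
  conflict <- agg_max == 1 & agg_min == -1   # any-evidence disagreement -> 0
  n_sources <- table(prot$symbol)
  universe <- intersect(symbols, rnaseq_de$feature_id)
  if (length(universe) == 0) xo_stop("empty cross-platform universe", "empty_universe")
  pi <- match(universe, symbols)
  prot_out <- data.frame(feature_id = universe, call = call[pi],
                         conflict = as.vector(conflict[pi]),
                         stringsAsFactors = FALSE)
  ri <- match(universe, rnaseq_de$feature_id)
  rna_out <- data.frame(feature_id = universe, call = rnaseq_de$call[ri],
                        stringsAsFactors = FALSE)
  list(proteome = prot_out, rnaseq = rna_out, universe = universe,
       report = list(mapped = sum(mapped), unmapped = sum(!mapped),
                     collided_symbols = sum(n_sources > 1),
                     conflicted_symbols = sum(conflict),
                     universe_size = length(universe)))
}

#' Exact hypergeometric overlap tail probability
#'
#' For `X ~ Hypergeometric(N, K, n)` (universe `N`, first set `K`, second
#' set `n`, observed overlap `k`) returns the exact over-enrichment tail
#' `P(X >= k)`, the under-enrichment tail `P(X <= k)`, or a two-sided
#' value `min(1, 2 * min(over, under))`. Tails come from the exact
#' hypergeometric distribution function; no normal approximation is used.
#'
#' @param k observed overlap.
#' @param K size of the first set.
#' @param n size of the second set.
#' @param N universe size.
#' @param tail one of `"over"`, `"under"`, `"two_sided"`.
#' @param log_p return the natural-log tail (only for `over`/`under`).
#' @return probability in `[0, 1]` (or its log).
#' @examples
#' hypergeom_overlap_p(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeom_overlap_p <- function(k, K, n, N, tail = c("over", "under", "two_sided"),
                                log_p = FALSE) {
  tail <- match.arg(tail)
  bad <- k < 0 | K < 0 | n < 0 | k > pmin(K, n) | K > N | n > N |
    k < pmax(0, K + n - N)
  if (any(bad)) xo_stop("inconsistent hypergeometric sizes", "invalid_input")
  over <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = log_p)
  if (tail == "over") return(over)
  under <- stats::phyper(k, K, N - K, n, lower.tail = TRUE, log.p = log_p)
  if (tail == "under") return(under)
  if (log_p) xo_stop("log_p is not supported for the two-sided tail", "invalid_input")
  pmin(1, 2 * pmin(over, under))
}

#' Direction-consistent cross-omics intersection
#'
#' Counts the genes called up on both platforms and down on both
#' platforms within a common universe, and attaches exact hypergeometric
#' over-enrichment p-values for each direction. Because the construction
#' of a single "intersection p-value" is ambiguous, the per-direction
#' tails and their product are all reported, each labeled.
#'
#' @param deA,deB call data.frames (`feature_id`, `call`) restricted to
#'   `universe`.
#' @param universe character vector of symbols.
#' @return an `overlap_result` list: `N`, `A_up`, `A_down`, `B_up`,
#'   `B_down`, `k_up`, `k_down`, `p_up`, `p_down`, `p_combined`
#'   (product of the two over-tails), plus `genes_up`, `genes_down`.
#' @export
direction_consistent_intersection <- function(deA, deB, universe) {
  a <- deA$call[match(universe, deA$feature_id)]
  b <- deB$call[match(universe, deB$feature_id)]
  if (any(is.na(a)) || any(is.na(b)))
    xo_stop("DE tables must cover the whole universe", "invalid_input")
  N <- length(universe)
  up <- universe[a == 1 & b == 1]; dn <- universe[a == -1 & b == -1]
  A_up <- sum(a == 1); A_dn <- sum(a == -1)
  B_up <- sum(b == 1); B_dn <- sum(b == -1)
  p_up <- if (A_up > 0 && B_up > 0)
    hypergeom_overlap_p(length(up), A_up, B_up, N, "over") else 1
  p_dn <- if (A_dn > 0 && B_dn > 0)
    hypergeom_overlap_p(length(dn), A_dn, B_dn, N, "over") else 1
  structure(list(N = N, A_up = A_up, A_down = A_dn, B_up = B_up, B_down = B_dn,
                 k_up = length(up), k_down = length(dn),
                 p_up = p_up, p_down = p_dn, p_combined = p_up * p_dn,
                 genes_up = up, genes_down = dn),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Direction-consistent cross-omics intersection\n")
  cat(sprintf("  universe N = %d\n", x$N))
  cat(sprintf("  up:   %d & %d -> overlap %d (over-tail p = %.3g)\n",
              x$A_up, x$B_up, x$k_up, x$p_up))
  cat(sprintf("  down: %d & %d -> overlap %d (over-tail p = %.3g)\n",
              x$A_down, x$B_down, x$k_down, x$p_down))
  cat(sprintf("  product of per-direction over-tails = %.3g\n", x$p_combined))
  invisible(x)
}
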