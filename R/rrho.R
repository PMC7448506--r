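# Modified two-tailed rank-rank hypergeometric overlap (RRHO).
#
# Two ranked differential-expression lists are compared on a grid of rank
# thresholds: cell (i, j) tests the overlap of the top-i of list A with
# the top-j of list B against the hypergeometric expectation. Departures
# from the original procedure, made explicit here: (a) tail probabilities
# are computed in log space and floored at the smallest representable
# positive double, so no cell is ever reported as p = 0; (b) every cell
# attaining the minimal p is reported in summaries, not just the first;
# (c) the two-tailed p of a cell is 2 * min(over, under) capped at 1;
# (d) lists of unequal composition are reduced to their shared symbols
# (logged), the grid is rectangular over each list's own length, and the
# universe is the shared-symbol count, which accommodates asymmetric
# numbers of up- and down-regulated genes in the two lists.

LOG10_FLOOR <- -log10(.Machine$double.xmin)  # ~307.65, cap for -log10(p)

#' Rank features by signed log fold change
#'
#' Orders features from most up-regulated (largest score) to most
#' down-regulated. Ties are broken deterministically by score then
#' lexicographic symbol.
#'
#' @param x named numeric vector of signed scores (names are symbols), or
#'   a data.frame with columns `symbol` (or `feature_id`) and `score`.
#' @return a `ranked_list` data.frame: `symbol`, `score`, `rank` (1 =
#'   most up-regulated).
#' @export
rank_by_lfc <- function(x) {
  if (is.data.frame(x)) {
    sym <- if ("symbol" %in% names(x)) x$symbol else x$feature_id
    sc <- x$score
  } else {
    sym <- names(x); sc <- as.numeric(x)
  }
  if (is.null(sym) || anyDuplicated(sym))
    xo_stop("scores must carry unique symbols", "invalid_input")
  if (any(is.na(sc)) || any(!is.finite(sc)))
    xo_stop("scores must be finite and non-missing", "invalid_input")
  o <- order(-sc, sym)
  structure(data.frame(symbol = sym[o], score = sc[o],
                       rank = seq_along(o), stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

#' Rank-rank hypergeometric overlap map
#'
#' For each grid cell `(i, j)` computes `k`, the overlap between the
#' top-`i` symbols of `listA` and the top-`j` of `listB`, and the exact
#' hypergeometric over- and under-enrichment tails with universe `N` (the
#' shared symbol count), first margin `i` and draw size `j`. The signed
#' display value is `-log10` of the smaller tail, positive for
#' over-enrichment (`k` at or above expectation), negative for
#' under-enrichment.
#'
#' @param listA,listB `ranked_list` objects from [rank_by_lfc()].
#' @param step grid step in ranks; default `max(1, floor(L / 100))` per
#'   list so toy and realistic inputs both render.
#' @return an `rrho_map` list: `k` (overlap counts), `signed_logp`,
#'   `p_two` (two-tailed p per cell), `grid_i`, `grid_j`, `N`, `step`,
#'   `n_dropped` (non-shared symbols removed).
#' @examples
#' a <- rank_by_lfc(stats::setNames(rnorm(30), paste0("g", 1:30)))
#' m <- rrho_map(a, a, step = 1)
#' max(m$signed_logp)
#' @export
rrho_map <- function(listA, listB, step = NULL) {
  stopifnot(inherits(listA, "ranked_list"), inherits(listB, "ranked_list"))
  shared <- intersect(listA$symbol, listB$symbol)
  n_drop <- (nrow(listA) - length(shared)) + (nrow(listB) - length(shared))
  if (length(shared) == 0) xo_stop("no shared symbols", "invalid_input")
  if (n_drop > 0) {
    message("rrho_map: dropping ", n_drop, " non-shared symbol entries")
    listA <- listA[listA$symbol %in% shared, ]
    listB <- listB[listB$symbol %in% shared, ]
  }
  la <- nrow(listA); lb <- nrow(listB); N <- length(shared)
  rank_a <- seq_len(la)                       # position in A
  rank_b <- match(listA$symbol, listB$symbol) # matching position in B
  grid_of <- function(L, st) unique(c(seq(st, L, by = st), L))
  if (is.null(step)) {
    gi <- grid_of(la, max(1, floor(la / 100)))
    gj <- grid_of(lb, max(1, floor(lb / 100)))
    step <- max(1, floor(la / 100))
  } else {
    if (!is_count(step)) xo_stop("step must be a positive integer", "invalid_input")
    gi <- grid_of(la, step); gj <- grid_of(lb, step)
  }
  # 2D histogram of (rank in A, rank in B), then cumulative counts
  bi <- findInterval(rank_a - 0.5, gi) + 1L
  bj <- findInterval(rank_b - 0.5, gj) + 1L
  H <- matrix(tabulate(bi + (bj - 1L) * length(gi), nbins = length(gi) * length(gj)),
              length(gi), length(gj))
  K <- apply(apply(H, 2, cumsum), 1, cumsum)
  K <- t(K)                                    # rows: grid_i, cols: grid_j
  ii <- matrix(gi, length(gi), length(gj))
  jj <- matrix(gj, length(gi), length(gj), byrow = TRUE)
  l_over <- stats::phyper(K - 1, ii, N - ii, jj, lower.tail = FALSE, log.p = TRUE)
  l_under <- stats::phyper(K, ii, N - ii, jj, lower.tail = TRUE, log.p = TRUE)
  over_enriched <- K >= ii * jj / N
  l_min <- pmin(l_over, l_under)
  signed <- ifelse(over_enriched, 1, -1) *
    pmin(-l_min / log(10), LOG10_FLOOR)
  # floor at the smallest positive double so no cell reports p = 0
  p_two <- pmin(pmax(2 * exp(l_min), .Machine$double.xmin), 1)
  structure(list(k = K, signed_logp = signed, p_two = p_two,
                 grid_i = gi, grid_j = gj, N = N, step = step,
                 n_dropped = n_drop),
            class = "rrho_map")
}

#' Benjamini-Yekutieli correction of an RRHO map
#'
#' Applies the BY step-up procedure (valid under arbitrary dependence,
#' appropriate for the strongly dependent grid cells) across all cells'
#' two-tailed p-values and stores the corrected map; signs are preserved.
#'
#' @param map an `rrho_map`.
#' @return the map with added `p_two_adj` and `corrected_logp` matrices.
#' @export
by_adjust_map <- function(map) {
  stopifnot(inherits(map, "rrho_map"))
  adj <- stats::p.adjust(as.vector(map$p_two), method = "BY")
  padj <- matrix(adj, nrow(map$p_two), ncol(map$p_two))
  map$p_two_adj <- padj
  map$corrected_logp <- sign(map$signed_logp) *
    pmin(-log10(pmax(padj, .Machine$double.xmin)), LOG10_FLOOR)
  map
}

#' Quadrant summaries of a corrected RRHO map
#'
#' Splits the grid at half of each list's length into the four
#' concordance quadrants - up-up (both lists' top halves; the bottom-left
#' corner of the conventional plot), down-down (both bottom halves),
#' up-down and down-up - and reports the minimal BY-corrected p-value per
#' quadrant with every grid coordinate attaining it.
#'
#' The concordant quadrants (up-up, down-down) summarize over-enriched
#' cells only; the discordant quadrants (up-down, down-up) summarize
#' under-enriched cells, since depletion of top-top overlap is exactly
#' what discordance (one list's top overlapping the other's bottom)
#' looks like on the two-tailed map. A quadrant with no cell of the
#' relevant sign reports `min_p = 1`.
#'
#' @param map an `rrho_map` that has been through [by_adjust_map()].
#' @return list of four quadrant entries, each with `min_p`, `coords`
#'   (data.frame `i`, `j` of every cell attaining the minimum) and
#'   `direction` (sign of the signed log p at the minimum).
#' @export
summarize_quadrants <- function(map) {
  stopifnot(inherits(map, "rrho_map"))
  if (is.null(map$p_two_adj)) xo_stop("apply by_adjust_map first", "invalid_input")
  hi <- max(map$grid_i) / 2; hj <- max(map$grid_j) / 2
  qdef <- list(up_up = list(map$grid_i <= hi, map$grid_j <= hj, 1),
               down_down = list(map$grid_i > hi, map$grid_j > hj, 1),
               up_down = list(map$grid_i <= hi, map$grid_j > hj, -1),
               down_up = list(map$grid_i > hi, map$grid_j <= hj, -1))
  lapply(qdef, function(q) {
    sub <- map$p_two_adj[q[[1]], q[[2]], drop = FALSE]
    sgn <- map$signed_logp[q[[1]], q[[2]], drop = FALSE]
    sub[sign(sgn) != q[[3]]] <- 1  # only cells of the quadrant's sense
    if (length(sub) == 0) return(list(min_p = NA_real_, coords = NULL, direction = NA))
    mn <- min(sub)
    w <- which(sub == mn, arr.ind = TRUE)  # all cells sharing the minimum
    coords <- data.frame(i = map$grid_i[q[[1]]][w[, 1]],
                         j = map$grid_j[q[[2]]][w[, 2]])
    list(min_p = mn, coords = coords, direction = sign(sgn[w][1]))
  })
}
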