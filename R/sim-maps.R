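#' Simulate an ortholog/identifier mapping table
#'
#' Builds a source-to-target symbol map of the kind used to carry protein
#' identifiers from one species onto gene symbols of another: each source
#' maps to zero or one target, a controlled fraction stays unmapped, and a
#' controlled fraction collides onto a target symbol already used by
#' another source (many-to-one).
#'
#' @param features character vector of distinct source identifiers.
#' @param unmapped_fraction fraction of sources with no target; realized
#'   as `round(unmapped_fraction * length(features))` sources exactly.
#' @param many_to_one_fraction fraction of sources mapped onto another
#'   source's target symbol.
#' @param seed integer seed.
#' @param targets optional character vector (same length as `features`)
#'   of the target symbol each source would map to when plainly mapped;
#'   defaults to generated `SYM....` symbols.
#' @return an `ortholog_map`: data.frame with columns `source_id`,
#'   `target_symbol` (`NA` for unmapped sources).
#' @examples
#' m <- simulate_ortholog_map(sprintf("R%03d", 1:100), 0.1, 0.2, seed = 3)
#' sum(is.na(m$target_symbol))
#' @export
simulate_ortholog_map <- function(features, unmapped_fraction = 0,
                                  many_to_one_fraction = 0, seed = 1L,
                                  targets = NULL) {
  if (anyDuplicated(features))
    xo_stop("duplicate source identifiers", "invalid_input")
  if (!is_fraction(unmapped_fraction) || !is_fraction(many_to_one_fraction) ||
      unmapped_fraction + many_to_one_fraction > 1)
    xo_stop("fractions must lie in [0,1] and sum to at most 1", "invalid_config")
  n <- length(features)
  n_un <- round(unmapped_fraction * n)
  n_m2o <- round(many_to_one_fraction * n)
  with_seed(seed, {
    ord <- sample.int(n)
    unmapped <- ord[seq_len(n_un)]
    m2o <- if (n_m2o > 0) ord[n_un + seq_len(n_m2o)] else integer(0)
    plain <- setdiff(ord, c(unmapped, m2o))
    target <- rep(NA_character_, n)
    if (is.null(targets)) {
      target[plain] <- sprintf("SYM%04d", seq_along(plain))
    } else {
      stopifnot(length(targets) == n)
      target[plain] <- targets[plain]
    }
    if (n_m2o > 0) {
      if (length(plain) == 0)
        xo_stop("many-to-one sources need at least one plainly mapped source",
                "invalid_config")
      target[m2o] <- target[sample(plain, n_m2o, replace = TRUE)]
    }
    structure(data.frame(source_id = features, target_symbol = target,
                         stringsAsFactors = FALSE),
              class = c("ortholog_map", "data.frame"))
  })
}

#' Simulate a prior edge list with controlled truth overlap
#'
#' Emulates a literature-derived prior network whose agreement with the
#' planted true network is controlled: exactly
#' `round(overlap_fraction * n_edges)` edges are sampled from the true
#' edge set and the remainder from directed non-true, non-self pairs,
#' without duplicates.
#'
#' @param genes character vector of node symbols.
#' @param n_edges number of prior edges to generate.
#' @param true_edges data.frame with columns `regulator`, `target`.
#' @param overlap_fraction fraction of prior edges drawn from
#'   `true_edges`.
#' @param seed integer seed.
#' @return data.frame with columns `regulator`, `target`, `source_tag`.
#' @export
simulate_prior_edges <- function(genes, n_edges, true_edges,
                                 overlap_fraction = 0, seed = 1L) {
  if (!is_count(n_edges)) xo_stop("n_edges must be a positive integer", "invalid_config")
  if (!is_fraction(overlap_fraction))
    xo_stop("overlap_fraction must lie in [0,1]", "invalid_config")
  n_true <- round(overlap_fraction * n_edges)
  if (n_true > nrow(true_edges))
    xo_stop("overlap_fraction * n_edges exceeds the number of true edges",
            "invalid_config")
  g <- length(genes)
  n_pairs <- g * (g - 1)
  if (n_edges > n_pairs)
    xo_stop("n_edges exceeds the number of distinct directed pairs",
            "invalid_config")
  true_key <- paste(true_edges$regulator, true_edges$target, sep = "\r")
  with_seed(seed, {
    take <- if (n_true > 0) sample.int(nrow(true_edges), n_true) else integer(0)
    reg <- true_edges$regulator[take]; tgt <- true_edges$target[take]
    n_false <- n_edges - n_true
    if (n_false > n_pairs - length(unique(true_key)))
      xo_stop("not enough non-true pairs to fill the prior", "invalid_config")
    seen <- character(0)
    while (n_false > 0) {
      i <- sample.int(g, 2 * n_false, replace = TRUE)
      j <- sample.int(g, 2 * n_false, replace = TRUE)
      ok <- i != j
      cand <- paste(genes[i[ok]], genes[j[ok]], sep = "\r")
      cand <- setdiff(unique(cand), c(true_key, seen))
      if (length(cand) > 0) {
        cand <- cand[seq_len(min(length(cand), n_false))]
        seen <- c(seen, cand)
        n_false <- n_false - length(cand)
      }
    }
    if (length(seen) > 0) {
      parts <- strsplit(seen, "\r", fixed = TRUE)
      reg <- c(reg, vapply(parts, `[`, "", 1))
      tgt <- c(tgt, vapply(parts, `[`, "", 2))
    }
    data.frame(regulator = reg, target = tgt,
               source_tag = "synthetic_prior", stringsAsFactors = FALSE)
  })
}
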