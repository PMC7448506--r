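# Prior-knowledge regulatory network assembly.
#
# The prior is built from two kinds of ingested tables: enrichment
# exports (regulator rows with a target list and a p-value, thresholded
# per source) and database edge lists (already regulator -> target). All
# symbols are compared uppercase; alias resolution is out of scope.

#' Ingest enrichment-export tables into an edge list
#'
#' Each entry of `sources` describes one exported enrichment table:
#' a data.frame with columns `regulator`, `targets` (comma- or
#' semicolon-separated target symbols) and the p-value columns it
#' provides (`p` and/or `p_adj`), plus the metadata `source_tag`,
#' `p_column` (`"p_adj"` or `"p"`) and `alpha`. Rows failing their
#' source's threshold are dropped; passing regulators are expanded to one
#' edge per listed target.
#'
#' The conventional thresholds for the two supported export styles are
#' adjusted p < `david_alpha` for transcription-factor-binding-site
#' enrichment tables (DAVID-style, tag `"DAVID"`) and raw p <
#' `ipa_alpha` for upstream-regulator tables (IPA-style, tag `"IPA"`);
#' entries that omit `p_column`/`alpha` inherit these by tag.
#'
#' @param sources list of entries as described above.
#' @param david_alpha default adjusted-p threshold for DAVID-style tags.
#' @param ipa_alpha default raw-p threshold for IPA-style tags.
#' @return data.frame with columns `regulator`, `target`, `source_tag`.
#' @export
ingest_enrichment_edges <- function(sources, david_alpha = 0.05,
                                    ipa_alpha = 0.001) {
  out <- list()
  for (s in sources) {
    tab <- s$table
    tag <- s$source_tag
    if (is.null(tag)) xo_stop("each source must declare a source_tag", "format_error")
    pcol <- s$p_column
    alpha <- s$alpha
    if (is.null(pcol)) pcol <- if (identical(tag, "IPA")) "p" else "p_adj"
    if (is.null(alpha)) alpha <- if (identical(tag, "IPA")) ipa_alpha else david_alpha
    if (is.null(tab) || nrow(tab) == 0) {
      warning("empty enrichment table for source ", tag)
      next
    }
    if (!pcol %in% names(tab))
      xo_stop(paste0("source ", tag, " lacks its declared p column '", pcol, "'"),
              "format_error")
    keep <- tab[is.finite(tab[[pcol]]) & tab[[pcol]] < alpha, , drop = FALSE]
    if (nrow(keep) == 0) next
    tgt <- strsplit(as.character(keep$targets), "[,;]\\s*")
    n <- lengths(tgt)
    out[[length(out) + 1]] <- data.frame(
      regulator = rep(toupper(keep$regulator), n),
      target = toupper(unlist(tgt)),
      source_tag = tag, stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(regulator = character(0), target = character(0),
                      source_tag = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Augment the DE gene set with enrichment-derived regulators
#'
#' Forms the union of the differentially expressed symbols and the
#' regulator symbols, reporting the overlap (regulators already present
#' among the DE genes).
#'
#' @param de_genes character vector of DE symbols.
#' @param regulators character vector of regulator symbols.
#' @return an `augmented_gene_set` list: `de_genes`, `regulators`,
#'   `union`, `overlap` (symbols in both), `n_union`.
#' @examples
#' augment_gene_set(c("A", "B", "C"), c("C", "D"))$n_union  # 4
#' @export
augment_gene_set <- function(de_genes, regulators) {
  if (length(de_genes) == 0) xo_stop("empty DE gene set", "invalid_input")
  de <- unique(toupper(de_genes)); rg <- unique(toupper(regulators))
  u <- union(de, rg)
  structure(list(de_genes = de, regulators = rg, union = u,
                 overlap = intersect(de, rg), n_union = length(u)),
            class = "augmented_gene_set")
}

#' @export
print.augmented_gene_set <- function(x, ...) {
  cat(sprintf("augmented_gene_set: %d DE + %d regulators (%d shared) -> %d symbols\n",
              length(x$de_genes), length(x$regulators), length(x$overlap),
              x$n_union))
  invisible(x)
}

#' Build the prior regulatory network
#'
#' Concatenates enrichment-derived edges with database edge lists,
#' restricts to edges whose regulator and target both belong to the
#' augmented gene set, drops self-loops, and deduplicates
#' (regulator, target) pairs across sources while retaining the multiset
#' of source tags per edge. A database marked undirected (attribute
#' `directed = FALSE` on its data.frame) is expanded to both
#' orientations.
#'
#' @param enrichment_edges data.frame from [ingest_enrichment_edges()].
#' @param database_edges list of data.frames (`regulator`, `target`,
#'   `source_tag`).
#' @param gene_set an `augmented_gene_set`.
#' @return a `prior_network` data.frame: `regulator`, `target`,
#'   `source_tags` (comma-joined, sorted, unique tags), `n_sources`.
#' @export
build_prior <- function(enrichment_edges, database_edges = list(), gene_set) {
  stopifnot(inherits(gene_set, "augmented_gene_set"))
  dfs <- c(list(enrichment_edges), database_edges)
  dfs <- lapply(dfs, function(d) {
    if (is.null(d) || nrow(d) == 0) return(NULL)
    if (!"source_tag" %in% names(d) && "source_tags" %in% names(d)) {
      # re-ingesting a built prior: unfold the joined tags (idempotence)
      tg <- strsplit(d$source_tags, ",", fixed = TRUE)
      d <- data.frame(regulator = rep(d$regulator, lengths(tg)),
                      target = rep(d$target, lengths(tg)),
                      source_tag = unlist(tg), stringsAsFactors = FALSE)
    }
    d$regulator <- toupper(d$regulator); d$target <- toupper(d$target)
    if (isFALSE(attr(d, "directed"))) {
      rev <- d; rev$regulator <- d$target; rev$target <- d$regulator
      d <- rbind(d, rev)
    }
    d
  })
  dfs <- Filter(Negate(is.null), dfs)
  if (length(dfs) == 0)
    return(empty_prior())
  for (d in dfs) {
    inset <- d$regulator %in% gene_set$union & d$target %in% gene_set$union
    if (nrow(d) > 0 && !any(inset))
      warning("a non-empty edge source contributed no edge within the gene set; ",
              "possible symbol-namespace mismatch (source: ",
              paste(unique(d$source_tag), collapse = ","), ")")
  }
  all <- do.call(rbind, lapply(dfs, function(d)
    d[, c("regulator", "target", "source_tag")]))
  all <- all[all$regulator %in% gene_set$union &
               all$target %in% gene_set$union &
               all$regulator != all$target, , drop = FALSE]
  if (nrow(all) == 0) return(empty_prior())
  key <- paste(all$regulator, all$target, sep = "\r")
  tags <- vapply(split(all$source_tag, key),
                 function(t) paste(sort(unique(t)), collapse = ","), "")
  nsrc <- vapply(split(all$source_tag, key), function(t) length(unique(t)), 0L)
  parts <- strsplit(names(tags), "\r", fixed = TRUE)
  out <- data.frame(regulator = vapply(parts, `[`, "", 1),
                    target = vapply(parts, `[`, "", 2),
                    source_tags = unname(tags), n_sources = unname(nsrc),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$regulator, out$target), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("prior_network", "data.frame")
  out
}

empty_prior <- function() {
  out <- data.frame(regulator = character(0), target = character(0),
                    source_tags = character(0), n_sources = integer(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("prior_network", "data.frame")
  out
}
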