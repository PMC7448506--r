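# Tab-separated readers and writers for the pipeline's on-disk formats.
# All tables are TSV with a header row; summaries are JSON.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write / read a paired count matrix
#'
#' The count matrix goes to `counts_path` (first column `feature_id`,
#' then one column per sample) and the pairing to a sidecar TSV with
#' columns `pair_id`, `control_sample`, `treated_sample`.
#'
#' @param x a [paired_counts()] object.
#' @param counts_path,pairs_path output TSV paths.
#' @return the input, invisibly.
#' @export
write_paired_counts <- function(x, counts_path, pairs_path) {
  stopifnot(inherits(x, "paired_counts"))
  df <- data.frame(feature_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, counts_path)
  write_tsv(x$pairs, pairs_path)
  invisible(x)
}

#' @rdname write_paired_counts
#' @export
read_paired_counts <- function(counts_path, pairs_path) {
  df <- read_tsv(counts_path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  paired_counts(m, read_tsv(pairs_path))
}

#' Write / read a time-course intensity table
#'
#' Columns are named `t<hours>_r<replicate>`; the annotation is rebuilt
#' from the names on read. Proteins with missing values in any column are
#' dropped on read with a message (no imputation).
#'
#' @param x a [timecourse_intensities()] object.
#' @param path TSV path.
#' @export
write_timecourse <- function(x, path) {
  stopifnot(inherits(x, "timecourse_intensities"))
  df <- data.frame(protein_id = rownames(x$intensities), x$intensities,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(x)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  bad <- rowSums(!is.finite(m) | m <= 0) > 0
  if (any(bad)) {
    message("dropping ", sum(bad), " protein(s) with missing or non-positive values")
    m <- m[!bad, , drop = FALSE]
  }
  cn <- colnames(m)
  mt <- regmatches(cn, regexec("^t([0-9.]+)_r([0-9]+)$", cn))
  if (any(lengths(mt) != 3))
    xo_stop("intensity columns must be named t<hours>_r<replicate>", "format_error")
  coldata <- data.frame(column = cn,
                        time = as.numeric(vapply(mt, `[`, "", 2)),
                        replicate = as.integer(vapply(mt, `[`, "", 3)),
                        stringsAsFactors = FALSE)
  timecourse_intensities(m, coldata)
}

#' Write / read an ortholog map (source_id, target_symbol; empty target
#' means unmapped)
#'
#' @param x an ortholog map data.frame.
#' @param path TSV path.
#' @export
write_ortholog_map <- function(x, path) {
  y <- x; y$target_symbol[is.na(y$target_symbol)] <- ""
  write_tsv(y, path)
  invisible(x)
}

#' @rdname write_ortholog_map
#' @export
read_ortholog_map <- function(path) {
  df <- read_tsv(path)
  df$target_symbol[df$target_symbol == ""] <- NA_character_
  if (anyDuplicated(df$source_id))
    xo_stop("duplicate source_id in ortholog map", "invalid_input")
  class(df) <- c("ortholog_map", "data.frame")
  df
}

#' Write / read an edge list (regulator, target, source_tag)
#'
#' @param x an edge data.frame.
#' @param path TSV path.
#' @export
write_edges <- function(x, path) write_tsv(x, path)

#' @rdname write_edges
#' @export
read_edges <- function(path) read_tsv(path)

#' Read a GMT gene-set file
#'
#' @param path GMT path.
#' @return named list of gene-symbol vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  stats::setNames(lapply(lines, function(l) l[-(1:2)]),
                  vapply(lines, `[`, "", 1))
}
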