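#' Simulate a paired-design RNA-seq count matrix with planted effects
#'
#' Draws negative-binomial counts for `n_pairs` paired (control, treated)
#' samples. Gene baseline abundances are lognormal; within a pair both
#' samples share a pair-specific (donor-like) baseline, so the treated vs
#' control contrast is affected only by the residual dispersion
#' `nb_dispersion`. A `de_fraction` of genes receives a planted effect:
#' the treated mean of every pair is scaled by `2^(+lfc_effect)` (up
#' genes) or `2^(-lfc_effect)` (down genes).
#'
#' @param config a [sim_config()] object.
#' @param direction optional integer vector (+1/0/-1, length `n_genes`)
#'   fixing the planted directions, e.g. to share truth with a proteome
#'   simulation; overrides `de_fraction`.
#' @return a list with components
#'   \describe{
#'     \item{counts}{a `paired_counts` object: integer matrix
#'       (genes x samples) plus a `pairs` data.frame.}
#'     \item{truth}{data.frame with `feature_id`, `direction`
#'       (+1/0/-1).}
#'   }
#' @examples
#' sim <- simulate_paired_counts(sim_config(n_genes = 100, seed = 1))
#' table(sim$truth$direction)
#' @export
simulate_paired_counts <- function(config, direction = NULL) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  g <- config$n_genes; np <- config$n_pairs
  with_seed(substream_seed(config$seed, 1L), {
    libs <- config$library_sizes
    if (is.null(libs))
      libs <- as.integer(round(150 * g * 2^stats::rnorm(2 * np, 0, 0.15)))
    gene_ids <- sprintf("G%04d", seq_len(g))
    if (is.null(direction)) {
      # planted directions: first half of DE genes up, second half down
      n_de <- round(config$de_fraction * g)
      direction <- integer(g)
      if (n_de > 0) {
        de_idx <- sample.int(g, n_de)
        n_up <- ceiling(n_de / 2)
        direction[de_idx[seq_len(n_up)]] <- 1L
        if (n_de > n_up) direction[de_idx[(n_up + 1):n_de]] <- -1L
      }
    } else stopifnot(length(direction) == g)
    # relative abundance: lognormal, renormalized to sum 1
    base_rel <- stats::rlnorm(g, meanlog = 0, sdlog = 1)
    fc <- 2^(direction * config$lfc_effect)
    counts <- matrix(0L, g, 2 * np)
    samples <- character(2 * np)
    pairs <- data.frame(pair_id = sprintf("P%d", seq_len(np)),
                        control_sample = sprintf("ctrl_%d", seq_len(np)),
                        treated_sample = sprintf("trt_%d", seq_len(np)),
                        stringsAsFactors = FALSE)
    size <- 1 / config$nb_dispersion
    for (p in seq_len(np)) {
      # pair-specific (donor) wobble shared by the two samples of the pair
      donor <- 2^stats::rnorm(g, 0, 0.3)
      rel <- base_rel * donor
      prop_c <- rel / sum(rel)
      # treated mean is exactly the control mean scaled by 2^(+/- lfc);
      # no compositional renormalization, so planted log2 effects are exact
      prop_t <- prop_c * fc
      ic <- 2 * p - 1; it <- 2 * p
      counts[, ic] <- stats::rnbinom(g, mu = libs[ic] * prop_c, size = size)
      counts[, it] <- stats::rnbinom(g, mu = libs[it] * prop_t, size = size)
      samples[c(ic, it)] <- c(pairs$control_sample[p], pairs$treated_sample[p])
    }
    dimnames(counts) <- list(gene_ids, samples)
    pc <- paired_counts(counts, pairs)
    # a zero effect size plants no true direction
    truth_dir <- if (config$lfc_effect == 0) integer(g) else direction
    truth <- data.frame(feature_id = gene_ids, direction = truth_dir,
                        stringsAsFactors = FALSE)
    list(counts = pc, truth = truth)
  })
}

#' Paired count matrix container
#'
#' Bundles an integer count matrix (features x samples) with the explicit
#' pairing of its columns into (control, treated) pairs.
#'
#' @param counts non-negative integer matrix with row and column names.
#' @param pairs data.frame with columns `pair_id`, `control_sample`,
#'   `treated_sample`; every column of `counts` must appear in exactly
#'   one pair.
#' @return an object of class `paired_counts`.
#' @export
paired_counts <- function(counts, pairs) {
  if (!is.matrix(counts) || any(counts < 0) || any(counts != floor(counts)))
    xo_stop("counts must be a non-negative integer matrix", "invalid_input")
  need <- c("pair_id", "control_sample", "treated_sample")
  if (!all(need %in% names(pairs)))
    xo_stop("pairs must have pair_id, control_sample, treated_sample", "invalid_input")
  used <- c(pairs$control_sample, pairs$treated_sample)
  if (anyDuplicated(used) || !setequal(used, colnames(counts)))
    xo_stop("every sample must appear in exactly one pair", "invalid_input")
  if (any(colSums(counts) == 0))
    xo_stop("zero library total in at least one sample", "degenerate_library")
  structure(list(counts = counts, pairs = pairs), class = "paired_counts")
}

#' @export
print.paired_counts <- function(x, ...) {
  cat(sprintf("paired_counts: %d features x %d samples (%d pairs)\n",
              nrow(x$counts), ncol(x$counts), nrow(x$pairs)))
  invisible(x)
}
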