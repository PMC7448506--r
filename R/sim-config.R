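#' Simulation configuration for the synthetic-data generators
#'
#' Collects every tunable of the synthetic-data module into a validated
#' configuration object. The defaults emulate the study design the package
#' targets: six paired (control, treated) RNA-seq samples and a proteome
#' time course of two independent replicate experiments at 0, 4, 16 and
#' 24 h, with a between-control log2-ratio standard deviation of 0.158
#' (the value implied by a 95% up-regulation cutoff of 1.24).
#'
#' @param n_genes number of simulated genes (RNA-seq) or proteins
#'   (proteome).
#' @param n_pairs number of paired (control, treated) RNA-seq samples.
#' @param de_fraction fraction of features with a planted differential
#'   effect, split evenly between up and down.
#' @param lfc_effect planted absolute log2 fold change for DE features.
#' @param nb_dispersion negative-binomial dispersion of counts around the
#'   pair-specific gene mean. Within a pair both samples share the donor
#'   baseline, so this is residual (technical plus treatment-response)
#'   dispersion, not the between-donor biological dispersion.
#' @param library_sizes integer vector of per-sample sequencing depths,
#'   length `2 * n_pairs` (controls first, then treated, interleaved by
#'   pair). `NULL` (default) draws depths around `150 * n_genes` with 10%
#'   lognormal jitter.
#' @param timepoints ordered exposure times in hours; the first must be 0
#'   (the control time point).
#' @param n_replicates number of independent replicate experiments in the
#'   proteome time course.
#' @param control_log2_sd standard deviation, in log2 units, of the ratio
#'   between the two control (time-0) measurements of a protein. Each
#'   individual intensity receives lognormal noise with log2 sd
#'   `control_log2_sd / sqrt(2)` so that the between-control ratio has the
#'   configured sd.
#' @param outlier_fraction fraction of proteins with inflated
#'   between-control-replicate discordance (and no treatment effect).
#' @param seed integer master seed; all generators derive substreams from
#'   it.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 500, seed = 1)
#' cfg$n_pairs
#' @export
sim_config <- function(n_genes = 2000,
                       n_pairs = 6,
                       de_fraction = 0.05,
                       lfc_effect = 2,
                       nb_dispersion = 0.05,
                       library_sizes = NULL,
                       timepoints = c(0, 4, 16, 24),
                       n_replicates = 2,
                       control_log2_sd = 0.158,
                       outlier_fraction = 0.055,
                       seed = 1L) {
  if (!is_count(n_genes)) xo_stop("n_genes must be a positive integer", "invalid_config")
  if (!is_count(n_pairs)) xo_stop("n_pairs must be a positive integer", "invalid_config")
  if (!is_fraction(de_fraction)) xo_stop("de_fraction must be in [0,1]", "invalid_config")
  if (!is_fraction(outlier_fraction)) xo_stop("outlier_fraction must be in [0,1]", "invalid_config")
  if (de_fraction + outlier_fraction > 1)
    xo_stop("de_fraction + outlier_fraction must be <= 1", "invalid_config")
  if (!is.numeric(lfc_effect) || lfc_effect < 0)
    xo_stop("lfc_effect must be a non-negative real", "invalid_config")
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0)
    xo_stop("nb_dispersion must be positive", "invalid_config")
  if (!is.numeric(timepoints) || length(timepoints) < 2 ||
      timepoints[1] != 0 || any(diff(timepoints) <= 0))
    xo_stop("timepoints must be strictly increasing and start at 0", "invalid_config")
  if (!is_count(n_replicates)) xo_stop("n_replicates must be a positive integer", "invalid_config")
  if (!is.numeric(control_log2_sd) || control_log2_sd < 0)
    xo_stop("control_log2_sd must be non-negative", "invalid_config")
  if (!is.null(library_sizes)) {
    if (length(library_sizes) != 2 * n_pairs || any(library_sizes <= 0) ||
        any(library_sizes != floor(library_sizes)))
      xo_stop("library_sizes must be 2*n_pairs positive integers", "invalid_config")
  }
  structure(list(
    n_genes = as.integer(n_genes), n_pairs = as.integer(n_pairs),
    de_fraction = de_fraction, lfc_effect = lfc_effect,
    nb_dispersion = nb_dispersion, library_sizes = library_sizes,
    timepoints = timepoints, n_replicates = as.integer(n_replicates),
    control_log2_sd = control_log2_sd, outlier_fraction = outlier_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  genes/proteins: %d;  RNA-seq pairs: %d\n", x$n_genes, x$n_pairs))
  cat(sprintf("  DE fraction: %.3f (|log2FC| = %.2f);  NB dispersion: %.3f\n",
              x$de_fraction, x$lfc_effect, x$nb_dispersion))
  cat(sprintf("  time points (h): %s;  replicates: %d\n",
              paste(x$timepoints, collapse = ", "), x$n_replicates))
  cat(sprintf("  control log2 ratio sd: %.3f;  outlier fraction: %.3f;  seed: %d\n",
              x$control_log2_sd, x$outlier_fraction, x$seed))
  invisible(x)
}
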