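#' Time-course intensity container
#'
#' Bundles a positive protein-by-sample intensity matrix with the time and
#' replicate annotation of its columns. Columns are named `t<hours>_r<rep>`;
#' the time-0 columns are the controls.
#'
#' @param intensities positive numeric matrix, proteins x columns.
#' @param coldata data.frame with columns `column`, `time`, `replicate`
#'   matching `colnames(intensities)`.
#' @return an object of class `timecourse_intensities`.
#' @export
timecourse_intensities <- function(intensities, coldata) {
  if (!is.matrix(intensities) || any(!is.finite(intensities)) || any(intensities <= 0))
    xo_stop("intensities must be a finite positive matrix", "invalid_input")
  need <- c("column", "time", "replicate")
  if (!all(need %in% names(coldata)) ||
      !identical(as.character(coldata$column), colnames(intensities)))
    xo_stop("coldata must describe every intensity column in order", "invalid_input")
  if (sum(coldata$time == 0) < 2)
    xo_stop("at least two control (time-0) columns are required", "invalid_input")
  structure(list(intensities = intensities, coldata = coldata),
            class = "timecourse_intensities")
}

#' @export
print.timecourse_intensities <- function(x, ...) {
  cat(sprintf("timecourse_intensities: %d proteins x %d columns (%d time points x %d replicates)\n",
              nrow(x$intensities), ncol(x$intensities),
              length(unique(x$coldata$time)), length(unique(x$coldata$replicate))))
  invisible(x)
}

#' Simulate a time-course proteome with planted responses
#'
#' Generates positive intensities for `n_genes` proteins over
#' `timepoints x n_replicates` columns as
#' `baseline x trajectory x 2^noise`, where the per-measurement lognormal
#' noise has log2 sd `control_log2_sd / sqrt(2)` (so the ratio between the
#' two time-0 controls of a protein has log2 sd `control_log2_sd`).
#'
#' Planted responders follow a piecewise-monotone multiplicative
#' trajectory: flat at 1 until a random post-zero onset time, then ramping
#' monotonically to the full effect `2^(+/- de_effect_log2)` at the last
#' time point, so early- and late-onset responders both occur and the
#' "any time point" calling rule is exercised. Planted outliers receive an
#' inflated discordance of `5 x control_log2_sd` (log2) between their two
#' time-0 controls, leaving all treatment columns untouched, so only the
#' control-ratio outlier filter (not the DE caller) can catch them.
#'
#' When `network` is supplied, regulator proteins get independent
#' standard-normal log2 deviations at every time point and each target
#' follows a lagged linear response to its regulators' previous-time-point
#' deviations plus `N(0, lag_noise_sd)` noise.
#'
#' @param config a [sim_config()] object.
#' @param network optional data.frame with columns `regulator`, `target`
#'   (protein ids) defining planted lagged regulation.
#' @param de_effect_log2 absolute log2 magnitude of the planted protein
#'   response (default 1, i.e. 2-fold).
#' @param lag_coef linear coefficient of the planted lagged response.
#' @param lag_noise_sd log2 sd of the residual noise on lagged targets.
#' @param direction optional integer vector (+1/0/-1, length `n_genes`)
#'   fixing the planted directions (e.g. to share truth with an RNA-seq
#'   simulation); outliers are then drawn among direction-0 proteins.
#' @return list with `intensities` (a [timecourse_intensities()] object)
#'   and `truth` (list with `features` data.frame: `protein_id`,
#'   `direction`, `outlier`; and `edges`, the planted network or NULL).
#' @examples
#' sim <- simulate_timecourse_proteome(sim_config(n_genes = 200, seed = 2))
#' table(sim$truth$features$direction)
#' @export
simulate_timecourse_proteome <- function(config, network = NULL,
                                         de_effect_log2 = 1,
                                         lag_coef = 1, lag_noise_sd = 0.1,
                                         direction = NULL) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  g <- config$n_genes
  tps <- config$timepoints; nr <- config$n_replicates
  ids <- sprintf("R%04d", seq_len(g))
  if (!is.null(network)) {
    nodes <- unique(c(network$regulator, network$target))
    if (!all(nodes %in% ids))
      xo_stop("network references proteins absent from the simulation", "reference_error")
  }
  nt <- length(tps)
  with_seed(substream_seed(config$seed, 2L), {
    n_out <- round(config$outlier_fraction * g)
    outlier <- logical(g)
    if (is.null(direction)) {
      n_de <- round(config$de_fraction * g)
      lab <- sample.int(g, n_de + n_out)
      direction <- integer(g)
      if (n_de > 0) {
        de_idx <- lab[seq_len(n_de)]
        n_up <- ceiling(n_de / 2)
        direction[de_idx[seq_len(n_up)]] <- 1L
        if (n_de > n_up) direction[de_idx[(n_up + 1):n_de]] <- -1L
      }
      if (n_out > 0) outlier[lab[(n_de + 1):(n_de + n_out)]] <- TRUE
    } else {
      stopifnot(length(direction) == g)
      direction <- as.integer(direction)
      if (n_out > 0) outlier[sample(which(direction == 0L), n_out)] <- TRUE
    }

    baseline <- stats::rlnorm(g, meanlog = log(1e5), sdlog = 1)
    # trajectory multipliers, proteins x timepoints
    traj <- matrix(1, g, nt)
    de_all <- which(direction != 0L)
    for (i in de_all) {
      onset <- sample(2:nt, 1)
      ramp <- rep(0, nt)
      ramp[onset:nt] <- seq_len(nt - onset + 1) / (nt - onset + 1)
      traj[i, ] <- 2^(direction[i] * de_effect_log2 * ramp)
    }

    # lagged network deviations (log2), per replicate
    dev <- array(0, dim = c(g, nt, nr))
    if (!is.null(network) && nrow(network) > 0) {
      regs <- unique(network$regulator)
      ri <- match(regs, ids)
      for (r in seq_len(nr))
        dev[ri, , r] <- stats::rnorm(length(ri) * nt)
      tgt_split <- split(match(network$regulator, ids), network$target)
      for (tg in names(tgt_split)) {
        ti <- match(tg, ids)
        for (r in seq_len(nr)) {
          for (k in 2:nt) {
            dev[ti, k, r] <- lag_coef * sum(dev[tgt_split[[tg]], k - 1, r]) +
              stats::rnorm(1, 0, lag_noise_sd)
          }
        }
      }
    }

    sigma <- config$control_log2_sd / sqrt(2)
    cols <- as.vector(outer(seq_len(nr), tps,
                            function(r, t) sprintf("t%g_r%d", t, r)))
    mat <- matrix(0, g, nt * nr)
    coldata <- data.frame(column = cols,
                          time = rep(tps, each = nr),
                          replicate = rep(seq_len(nr), nt),
                          stringsAsFactors = FALSE)
    for (j in seq_len(ncol(mat))) {
      k <- match(coldata$time[j], tps); r <- coldata$replicate[j]
      noise <- if (sigma > 0) stats::rnorm(g, 0, sigma) else numeric(g)
      mat[, j] <- baseline * traj[, k] * 2^(dev[, k, r] + noise)
    }
    # outliers: opposite half-shifts on the two time-0 controls only
    if (n_out > 0) {
      delta <- sample(c(-1, 1), g, replace = TRUE) * 5 * config$control_log2_sd
      j1 <- which(coldata$time == 0 & coldata$replicate == 1)
      j2 <- which(coldata$time == 0 & coldata$replicate == 2)
      mat[outlier, j1] <- mat[outlier, j1] * 2^(delta[outlier] / 2)
      mat[outlier, j2] <- mat[outlier, j2] * 2^(-delta[outlier] / 2)
    }
    dimnames(mat) <- list(ids, cols)
    if (de_effect_log2 == 0) direction <- integer(g)  # no realized effect
    list(intensities = timecourse_intensities(mat, coldata),
         truth = list(features = data.frame(protein_id = ids,
                                            direction = direction,
                                            outlier = outlier,
                                            stringsAsFactors = FALSE),
                      edges = network))
  })
}
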