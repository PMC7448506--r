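# Time-course proteome differential expression.
#
# Two-stage normalization of positive intensities, estimation of a 95%
# confidence-interval cutoff from the between-control ratio distribution,
# exclusion of control-discordant outlier proteins, and any-time-point
# differential-expression calling against the cutoffs.

#' Two-stage normalization of a time-course intensity table
#'
#' Stage 1 divides every intensity by the grand mean of all control
#' (time-0) intensities over all proteins, putting the table on a common
#' scale. Stage 2 divides each protein's post-zero values by that
#' protein's own control mean, producing per-column treated/control
#' ratios. The between-control ratio of each protein (first replicate
#' over second, orientation recorded but tested two-sided downstream) is
#' returned alongside.
#'
#' Stage 1 cancels exactly in the stage-2 ratios, so the ratio output is
#' invariant to global rescaling of the input table; the stage-1 constant
#' is kept for reporting.
#'
#' @param table a [timecourse_intensities()] object.
#' @return a `ratio_table` list: `ratios` (proteins x post-zero columns),
#'   `control_ratio` (named vector), `coldata` (post-zero column
#'   annotation), `stage1_constant`.
#' @examples
#' sim <- simulate_timecourse_proteome(sim_config(n_genes = 50, seed = 1))
#' rt <- normalize_timecourse(sim$intensities)
#' dim(rt$ratios)
#' @export
normalize_timecourse <- function(table) {
  stopifnot(inherits(table, "timecourse_intensities"))
  m <- table$intensities; cd <- table$coldata
  ctrl <- cd$time == 0
  grand <- mean(m[, ctrl])
  if (!is.finite(grand) || grand <= 0)
    xo_stop("degenerate control grand mean", "degenerate_control")
  m1 <- m / grand
  ctrl_mean <- rowMeans(m1[, ctrl, drop = FALSE])
  if (any(ctrl_mean <= 0))
    xo_stop("non-positive per-protein control mean", "degenerate_control")
  post <- !ctrl
  if (!any(post)) xo_stop("no post-zero columns", "invalid_input")
  ratios <- m1[, post, drop = FALSE] / ctrl_mean
  ctrl_cols <- which(ctrl)[order(cd$replicate[ctrl])]
  control_ratio <- m1[, ctrl_cols[1]] / m1[, ctrl_cols[2]]
  structure(list(ratios = ratios,
                 control_ratio = control_ratio,
                 coldata = cd[post, , drop = FALSE],
                 stage1_constant = grand),
            class = "ratio_table")
}

#' Estimate confidence-interval cutoffs from control ratios
#'
#' Assuming the log2 between-control ratios are normal, the two-sided
#' `z`-level cutoffs for up- and down-regulation are
#' `c_up = 2^(z * sigma)` and `c_down = 2^(-z * sigma)` where `sigma` is
#' the standard deviation of the log2 control ratios (estimated on all
#' proteins, outliers included - the cutoffs are what subsequently define
#' outliers). With the default `z = 1.96` the cutoffs delimit a 95%
#' confidence interval; an estimated `sigma` of 0.158 yields the
#' cutoff pair (1.24, 0.806).
#'
#' @param control_ratios positive vector of between-control ratios, or a
#'   single `sigma` via `sigma =`.
#' @param z normal quantile (default 1.96, the two-sided 95% level).
#' @param sigma optionally bypass estimation and supply the log2 sd
#'   directly (then `control_ratios` may be missing).
#' @return a `cutoff_spec` list: `sigma`, `z`, `c_up`, `c_down`,
#'   `n` (number of ratios used, 0 when `sigma` supplied).
#' @examples
#' estimate_control_cutoffs(sigma = log2(1.24) / 1.96)
#' @export
estimate_control_cutoffs <- function(control_ratios, z = 1.96, sigma = NULL) {
  if (is.null(sigma)) {
    if (length(control_ratios) < 2)
      xo_stop("at least two control ratios required", "invalid_input")
    if (any(!is.finite(control_ratios)) || any(control_ratios <= 0))
      xo_stop("control ratios must be positive", "invalid_input")
    sigma <- stats::sd(log2(control_ratios))
    n <- length(control_ratios)
  } else n <- 0L
  structure(list(sigma = sigma, z = z,
                 c_up = 2^(z * sigma), c_down = 2^(-z * sigma), n = n),
            class = "cutoff_spec")
}

#' @export
print.cutoff_spec <- function(x, ...) {
  cat(sprintf("cutoff_spec: sigma = %.4f (log2), z = %.2f -> up > %.3f, down < %.3f (n = %d)\n",
              x$sigma, x$z, x$c_up, x$c_down, x$n))
  invisible(x)
}

#' Flag control-discordant outlier proteins
#'
#' A protein is an outlier when the ratio between its two control
#' measurements falls outside the estimated confidence interval, i.e.
#' exceeds `c_up` or falls below `c_down`. Outliers are excluded from
#' differential-expression calling.
#'
#' @param ratios a `ratio_table` from [normalize_timecourse()].
#' @param cutoffs a `cutoff_spec` from [estimate_control_cutoffs()].
#' @return character vector of flagged protein identifiers.
#' @export
flag_outliers <- function(ratios, cutoffs) {
  stopifnot(inherits(ratios, "ratio_table"), inherits(cutoffs, "cutoff_spec"))
  cr <- ratios$control_ratio
  names(cr)[cr > cutoffs$c_up | cr < cutoffs$c_down]
}

#' Any-time-point differential-expression call for proteins
#'
#' A protein is called up-regulated (+1) when any post-zero ratio exceeds
#' `c_up` in at least one experiment, down-regulated (-1) when any ratio
#' falls below `c_down`. When both occur the call takes the sign of the
#' largest absolute log2 excursion and a conflict flag is set. Proteins
#' listed in `exclude` (typically the outlier flags) are removed before
#' calling.
#'
#' @param ratios a `ratio_table` from [normalize_timecourse()].
#' @param cutoffs a `cutoff_spec`.
#' @param exclude protein identifiers to drop (outliers).
#' @return a `de_table` data.frame: `feature_id`, `call`, `conflict`,
#'   `n_up_cross`, `n_down_cross`, `max_log2_excursion` (signed log2 of
#'   the most extreme ratio, usable as a ranking score).
#' @export
call_de_proteins <- function(ratios, cutoffs, exclude = character(0)) {
  stopifnot(inherits(ratios, "ratio_table"), inherits(cutoffs, "cutoff_spec"))
  r <- ratios$ratios
  if (ncol(r) == 0) xo_stop("no post-zero ratio columns", "invalid_input")
  keep <- !(rownames(r) %in% exclude)
  r <- r[keep, , drop = FALSE]
  lg <- log2(r)
  n_up <- rowSums(r > cutoffs$c_up)
  n_dn <- rowSums(r < cutoffs$c_down)
  imax <- max.col(abs(lg), ties.method = "first")
  excur <- lg[cbind(seq_len(nrow(lg)), imax)]
  call <- integer(nrow(r))
  call[n_up > 0 & n_dn == 0] <- 1L
  call[n_dn > 0 & n_up == 0] <- -1L
  conflict <- n_up > 0 & n_dn > 0
  call[conflict] <- as.integer(sign(excur[conflict]))
  out <- data.frame(feature_id = rownames(r),
                    call = call,
                    conflict = conflict,
                    n_up_cross = n_up,
                    n_down_cross = n_dn,
                    max_log2_excursion = excur,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "params") <- list(c_up = cutoffs$c_up, c_down = cutoffs$c_down,
                              z = cutoffs$z, sigma = cutoffs$sigma,
                              n_excluded = sum(!keep))
  class(out) <- c("de_table", "data.frame")
  out
}

#' Time-course proteome differential expression, end to end
#'
#' Normalization, cutoff estimation from the observed control ratios,
#' outlier exclusion, and any-time-point calling.
#'
#' @param table a [timecourse_intensities()] object.
#' @param z normal quantile for the confidence-interval cutoffs.
#' @return list with `ratios`, `cutoffs`, `outliers`, `de`.
#' @examples
#' sim <- simulate_timecourse_proteome(sim_config(n_genes = 300, seed = 1))
#' res <- proteome_de(sim$intensities)
#' res$cutoffs
#' @export
proteome_de <- function(table, z = 1.96) {
  rt <- normalize_timecourse(table)
  cut <- estimate_control_cutoffs(rt$control_ratio, z = z)
  out <- flag_outliers(rt, cut)
  de <- call_de_proteins(rt, cut, exclude = out)
  list(ratios = rt, cutoffs = cut, outliers = out, de = de)
}
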