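# Random-forest gene-regulatory-network inference.
#
# Per-target regression forests score candidate regulators by their
# impurity importance (total decrease in residual sum of squares from
# splits on the variable, averaged over trees), in the spirit of GENIE3.
# Two designs are supported: a directed, one-step-lagged time-course
# design (target = feature values at post-zero observations, predictors =
# all other features one time step earlier) and an undirected fold-change
# design whose per-pair scores are symmetrized by the maximum of the two
# directions. Edge p-values come from a permutation null (per-feature
# independent shuffling of observations), and edges are kept when
# p < p_strict, or p < p_prior if the edge is present in the prior
# network.

#' Random-forest inference configuration
#'
#' @param n_trees trees per forest (default 20000; use a few hundred for
#'   quick runs - scores stabilize early at these problem sizes).
#' @param mtry candidate predictors per split; default `floor(p / 3)`
#'   where `p` is the number of predictors of the design at hand.
#' @param seed integer master seed; per-target and per-permutation
#'   substreams are derived from it.
#' @param n_permutations permutations for the null (default 100).
#' @param p_strict selection threshold without prior support.
#' @param p_prior relaxed threshold for edges present in the prior.
#' @return an `rf_config` list.
#' @export
rf_config <- function(n_trees = 20000L, mtry = NULL, seed = 1L,
                      n_permutations = 100L, p_strict = 0.001,
                      p_prior = 0.05) {
  if (!is_count(n_trees)) xo_stop("n_trees must be a positive integer", "invalid_config")
  if (!is.null(mtry) && !is_count(mtry)) xo_stop("mtry must be a positive integer", "invalid_config")
  if (!is_count(n_permutations)) xo_stop("n_permutations must be >= 1", "invalid_config")
  if (!is_fraction(p_strict) || !is_fraction(p_prior) || p_strict > p_prior ||
      p_strict <= 0 || p_prior >= 1)
    xo_stop("need 0 < p_strict <= p_prior < 1", "invalid_config")
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 seed = as.integer(seed),
                 n_permutations = as.integer(n_permutations),
                 p_strict = p_strict, p_prior = p_prior),
            class = "rf_config")
}

scale_log2_by_sd <- function(mat, take_log2 = TRUE) {
  m <- if (take_log2) log2(mat) else mat
  sds <- apply(m, 1, stats::sd)
  drop <- !is.finite(sds) | sds == 0
  if (any(drop))
    message("dropping ", sum(drop), " zero-variance feature(s): ",
            paste(utils::head(rownames(m)[drop], 5), collapse = ", "))
  m[!drop, , drop = FALSE] / sds[!drop]
}

#' Build the directed, lagged time-course design
#'
#' Log2-transforms the intensity matrix, scales each feature by its own
#' standard deviation, and pairs every post-zero observation with the
#' observation one time step earlier in the same replicate: for time
#' points (0, 4, 16, 24) and two replicates the target observations are
#' 4h#1, 4h#2, 16h#1, 16h#2, 24h#1, 24h#2 and the predictors the same
#' columns shifted one step back. Unequal spacing is treated as
#' consecutive steps.
#'
#' @param table a [timecourse_intensities()] object (or a positive
#'   matrix plus `coldata`).
#' @param coldata required when `table` is a bare matrix.
#' @return an `expression_design` (mode `directed_lagged`).
#' @export
design_lagged <- function(table, coldata = NULL) {
  if (inherits(table, "timecourse_intensities")) {
    m <- table$intensities; cd <- table$coldata
  } else { m <- table; cd <- coldata }
  X <- scale_log2_by_sd(m)
  tps <- sort(unique(cd$time)); reps <- sort(unique(cd$replicate))
  tgt <- integer(0); prd <- integer(0)
  for (r in reps) for (k in 2:length(tps)) {
    jt <- which(cd$time == tps[k] & cd$replicate == r)
    jp <- which(cd$time == tps[k - 1] & cd$replicate == r)
    stopifnot(length(jt) == 1, length(jp) == 1)
    tgt <- c(tgt, jt); prd <- c(prd, jp)
  }
  structure(list(mode = "directed_lagged", X = X,
                 target_idx = tgt, pred_idx = prd,
                 target_labels = colnames(m)[tgt],
                 pred_labels = colnames(m)[prd]),
            class = "expression_design")
}

#' Build the undirected fold-change design
#'
#' @param fc a features x observations matrix of per-pair fold changes
#'   (ratios; log2 is applied here) or already-log2 values with
#'   `take_log2 = FALSE`. Each feature is scaled by its own standard
#'   deviation.
#' @param take_log2 whether to log2-transform first.
#' @return an `expression_design` (mode `undirected`).
#' @export
design_undirected <- function(fc, take_log2 = TRUE) {
  X <- scale_log2_by_sd(fc, take_log2 = take_log2)
  if (ncol(X) < 3) xo_stop("undirected design needs >= 3 observations", "degenerate_design")
  structure(list(mode = "undirected", X = X,
                 target_idx = seq_len(ncol(X)), pred_idx = seq_len(ncol(X))),
            class = "expression_design")
}

#' Per-pair fold changes from floored RPKM values
#'
#' Clips expression below `floor` (default 0.1 RPKM), forms per-pair
#' treated/control fold changes, log2-transforms and scales each gene by
#' its own standard deviation across pairs; zero-variance genes are
#' dropped with a message.
#'
#' @param rpkm_control,rpkm_treated genes x pairs matrices, columns
#'   aligned by pair.
#' @param floor minimum expression value.
#' @return an `expression_design` (mode `undirected`).
#' @export
preprocess_rnaseq_fc <- function(rpkm_control, rpkm_treated, floor = 0.1) {
  stopifnot(identical(dim(rpkm_control), dim(rpkm_treated)))
  fc <- pmax(rpkm_treated, floor) / pmax(rpkm_control, floor)
  design_undirected(fc)
}

#' Random-forest importance of candidate regulators for one target
#'
#' Fits a regression forest predicting the target feature's values at the
#' design's target observations from all other features' values at the
#' predictor observations, and returns each candidate's impurity
#' importance (mean total RSS decrease over trees). A constant target
#' yields all-zero importances.
#'
#' @param design an `expression_design`.
#' @param target_feature feature (row) name.
#' @param config an [rf_config()].
#' @param seed optional integer seed for this forest (defaults to a
#'   substream of `config$seed`).
#' @return named numeric vector of importances over candidate regulators.
#' @export
rf_importance <- function(design, target_feature, config = rf_config(),
                          seed = NULL) {
  stopifnot(inherits(design, "expression_design"))
  feats <- rownames(design$X)
  ti <- match(target_feature, feats)
  if (is.na(ti)) xo_stop("target feature not in design", "invalid_input")
  if (length(design$target_idx) < 2)
    xo_stop("fewer than 2 observations", "degenerate_design")
  if (length(feats) < 3) xo_stop("need >= 2 candidate predictors", "invalid_input")
  y <- design$X[ti, design$target_idx]
  Xp <- t(design$X[-ti, design$pred_idx, drop = FALSE])
  p <- ncol(Xp)
  mtry <- if (is.null(config$mtry)) max(1L, p %/% 3L) else min(config$mtry, p)
  if (stats::sd(y) == 0)
    return(stats::setNames(numeric(p), colnames(Xp)))
  if (is.null(seed)) seed <- substream_seed(config$seed, ti)
  imp <- with_seed(seed, {
    rf <- randomForest::randomForest(x = Xp, y = y, ntree = config$n_trees,
                                     mtry = mtry, importance = FALSE)
    rf$importance[, "IncNodePurity"]
  })
  stats::setNames(as.numeric(imp), rownames(design$X)[-ti])
}

#' Score every directed edge of a design
#'
#' Runs [rf_importance()] with each feature as target and assembles the
#' full score matrix (rows: regulators, columns: targets; diagonal NA).
#'
#' @param design an `expression_design`.
#' @param config an [rf_config()].
#' @return numeric matrix of importances.
#' @export
score_all_targets <- function(design, config = rf_config()) {
  feats <- rownames(design$X)
  S <- matrix(NA_real_, length(feats), length(feats),
              dimnames = list(feats, feats))
  for (t in seq_along(feats)) {
    imp <- rf_importance(design, feats[t], config,
                         seed = substream_seed(config$seed, t))
    S[names(imp), t] <- imp
  }
  S
}

#' Symmetrize a directed score matrix by the maximum
#'
#' For the undirected design the regulation score between two features is
#' the maximum of the two scores obtained when each is taken as target;
#' the result is reported on the upper triangle.
#'
#' @param score_matrix square matrix (diagonal ignored).
#' @return upper-triangular matrix of symmetrized scores.
#' @export
symmetrize_undirected <- function(score_matrix) {
  if (!is.matrix(score_matrix) || nrow(score_matrix) != ncol(score_matrix))
    xo_stop("score matrix must be square", "invalid_input")
  s <- pmax(score_matrix, t(score_matrix), na.rm = TRUE)
  s[lower.tri(s, diag = TRUE)] <- NA_real_
  s
}

edges_from_scores <- function(S, mode) {
  if (mode == "undirected") {
    U <- symmetrize_undirected(S)
    idx <- which(upper.tri(U), arr.ind = TRUE)
  } else {
    idx <- which(row(S) != col(S), arr.ind = TRUE)
    U <- S
  }
  data.frame(regulator = rownames(S)[idx[, 1]],
             target = colnames(S)[idx[, 2]],
             score = U[idx], stringsAsFactors = FALSE)
}

#' Infer a scored edge list from a design
#'
#' @param design an `expression_design`.
#' @param config an [rf_config()].
#' @return data.frame `regulator`, `target`, `score` (undirected designs
#'   report each unordered pair once, max-symmetrized).
#' @export
infer_network <- function(design, config = rf_config()) {
  edges_from_scores(score_all_targets(design, config), design$mode)
}

#' Permutation null distribution of regulation scores
#'
#' For each permutation the observation values of every feature are
#' shuffled independently (destroying cross-feature association while
#' preserving marginals), the identical inference is rerun, and all
#' resulting edge scores are pooled into one null sample. Substream seeds
#' make each permutation reproducible.
#'
#' @param design an `expression_design`.
#' @param config an [rf_config()]; `n_permutations` controls the size.
#' @return numeric vector of pooled null scores (length
#'   `n_edges x n_permutations`).
#' @export
permutation_null <- function(design, config = rf_config()) {
  stopifnot(inherits(design, "expression_design"))
  out <- vector("list", config$n_permutations)
  for (b in seq_len(config$n_permutations)) {
    Xp <- with_seed(substream_seed(config$seed, 100000L + b), {
      t(apply(design$X, 1, sample))
    })
    dimnames(Xp) <- dimnames(design$X)
    d2 <- design; d2$X <- Xp
    cfg2 <- config; cfg2$seed <- substream_seed(config$seed, 200000L + b)
    out[[b]] <- infer_network(d2, cfg2)$score
  }
  unlist(out)
}

#' Empirical edge p-values against a null score sample
#'
#' `p = (1 + #\{null >= observed\}) / (1 + n_null)`; the add-one
#' correction makes p = 0 impossible at finite permutation counts.
#'
#' @param observed numeric vector of observed scores.
#' @param null pooled null scores from [permutation_null()].
#' @return numeric vector of p-values, same order as `observed`.
#' @export
edge_pvalues <- function(observed, null) {
  if (length(null) == 0) xo_stop("empty null sample", "invalid_input")
  srt <- sort(null)
  n_lt <- findInterval(observed, srt, left.open = TRUE)  # #\{null < obs\}
  (1 + length(null) - n_lt) / (1 + length(null))
}

#' Two-tier edge selection against the prior
#'
#' An edge is kept when `p < p_strict`, or when `p < p_prior` and the
#' edge is present in the prior network (either orientation for
#' undirected edges). Inequalities are strict.
#'
#' @param edges data.frame with `regulator`, `target`, `p`.
#' @param prior a prior edge data.frame (`regulator`, `target`) or NULL.
#' @param config an [rf_config()].
#' @param directed whether `edges` are directed (prior matched in the
#'   given orientation only) or undirected (either orientation).
#' @return `edges` with added logical columns `in_prior`, `selected`.
#' @export
select_edges <- function(edges, prior, config = rf_config(), directed = TRUE) {
  key <- function(a, b) paste(a, b, sep = "\r")
  if (is.null(prior) || nrow(prior) == 0) {
    in_prior <- rep(FALSE, nrow(edges))
  } else {
    pk <- key(prior$regulator, prior$target)
    in_prior <- key(edges$regulator, edges$target) %in% pk
    if (!directed)
      in_prior <- in_prior | key(edges$target, edges$regulator) %in% pk
  }
  edges$in_prior <- in_prior
  edges$selected <- edges$p < config$p_strict |
    (edges$p < config$p_prior & in_prior)
  edges
}

#' Full single-platform network inference route
#'
#' Scores all edges, builds the permutation null, attaches empirical
#' p-values, and applies the two-tier selection rule.
#'
#' @param design an `expression_design`.
#' @param prior prior edge data.frame or NULL.
#' @param config an [rf_config()].
#' @param provenance label stored on every edge (`"rnaseq"` or
#'   `"proteome"`).
#' @return a `scored_network` data.frame: `regulator`, `target`,
#'   `score`, `p`, `in_prior`, `selected`, `provenance`, with the null
#'   sample size in `attr(, "n_null")`.
#' @export
score_network <- function(design, prior = NULL, config = rf_config(),
                          provenance = "proteome") {
  edges <- infer_network(design, config)
  null <- permutation_null(design, config)
  edges$p <- edge_pvalues(edges$score, null)
  edges <- select_edges(edges, prior, config,
                        directed = design$mode == "directed_lagged")
  edges$provenance <- provenance
  attr(edges, "n_null") <- length(null)
  attr(edges, "mode") <- design$mode
  class(edges) <- c("scored_network", "data.frame")
  edges
}

#' Merge two selected networks with provenance labels
#'
#' Takes the selected edges of each platform and unions them. Edges
#' present in both networks (matched as unordered pairs, since the
#' RNA-seq network is undirected) get provenance `"both"` and keep the
#' directed orientation. Per-edge prior membership is re-flagged against
#' `prior`, and a provenance x prior breakdown is attached.
#'
#' @param net_rnaseq,net_proteome `scored_network` objects.
#' @param prior prior edge data.frame or NULL.
#' @return a `scored_network` of the merged selected edges with a
#'   `summary` attribute (counts by provenance and prior membership, and
#'   node count).
#' @export
merge_networks <- function(net_rnaseq, net_proteome, prior = NULL) {
  a <- net_rnaseq[net_rnaseq$selected, , drop = FALSE]
  b <- net_proteome[net_proteome$selected, , drop = FALSE]
  ukey <- function(r, t) paste(pmin(r, t), pmax(r, t), sep = "\r")
  ka <- ukey(a$regulator, a$target); kb <- ukey(b$regulator, b$target)
  shared <- intersect(ka, kb)
  cols <- c("regulator", "target", "score", "p")
  both <- b[kb %in% shared, cols, drop = FALSE]
  both$provenance <- rep("both", nrow(both))
  only_a <- a[!ka %in% shared, cols, drop = FALSE]
  only_a$provenance <- rep("rnaseq", nrow(only_a))
  only_b <- b[!kb %in% shared, cols, drop = FALSE]
  only_b$provenance <- rep("proteome", nrow(only_b))
  m <- rbind(both, only_a, only_b)
  rownames(m) <- NULL
  if (is.null(prior) || nrow(prior) == 0) {
    m$in_prior <- rep(FALSE, nrow(m))
  } else {
    # either orientation counts: merged edges mix directed and undirected
    pk <- c(paste(prior$regulator, prior$target, sep = "\r"),
            paste(prior$target, prior$regulator, sep = "\r"))
    m$in_prior <- paste(m$regulator, m$target, sep = "\r") %in% pk
  }
  m$selected <- TRUE
  nodes <- unique(c(m$regulator, m$target))
  attr(m, "summary") <- list(
    n_edges = nrow(m), n_nodes = length(nodes),
    by_provenance = table(factor(m$provenance,
                                 levels = c("rnaseq", "proteome", "both"))),
    by_provenance_prior = table(factor(m$provenance,
                                       levels = c("rnaseq", "proteome", "both")),
                                m$in_prior))
  class(m) <- c("scored_network", "data.frame")
  m
}

#' @export
print.scored_network <- function(x, ...) {
  cat(sprintf("scored_network: %d edges (%d selected)\n",
              nrow(x), sum(x$selected)))
  s <- attr(x, "summary")
  if (!is.null(s)) {
    cat(sprintf("  merged: %d edges, %d nodes; provenance: %s\n",
                s$n_edges, s$n_nodes,
                paste(names(s$by_provenance), as.integer(s$by_provenance),
                      sep = "=", collapse = ", ")))
  }
  invisible(x)
}
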