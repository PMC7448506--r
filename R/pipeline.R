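# End-to-end pipeline orchestration over synthetic inputs.
#
# One configuration object drives simulate -> RNA-seq DE -> proteome DE
# -> cross-omics intersection -> RRHO -> prior assembly -> network
# inference -> merge, writing every tabular output as TSV and summaries
# as JSON, and returning a machine-readable run report. All randomness
# derives from the single global seed, so two runs with the same
# configuration produce byte-identical outputs.

#' Pipeline configuration
#'
#' Per-stage parameter blocks with the calling constants surfaced as
#' named, defaulted parameters. `stages` toggles individual stages;
#' downstream stages that need a disabled stage's output are skipped with
#' a note in the report.
#'
#' @param seed global integer seed.
#' @param stages character vector of stages to run, in dependency order.
#' @param sim list of [sim_config()] overrides (the pipeline default
#'   scales the gene count down to 120 so a full run stays interactive;
#'   study-scale analyses pass `n_genes` explicitly).
#' @param rnaseq list: `alpha`, `min_same`, `max_opposite`,
#'   `use_adjusted`.
#' @param proteome list: `z`.
#' @param map list: `unmapped_fraction`.
#' @param rrho list: `step` (NULL for automatic).
#' @param prior list: `n_edges`, `overlap_fraction` of the planted true
#'   network.
#' @param grn list: `n_trees`, `n_permutations`, `p_strict`, `p_prior`,
#'   `n_true_edges` (planted lagged regulations), `max_features`
#'   (features entering inference, for run-time control).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c("simulate", "rnaseq_de", "proteome_de",
                                       "cross", "rrho", "prior", "infer",
                                       "merge"),
                            sim = list(),
                            rnaseq = list(alpha = 0.05, min_same = 4L,
                                          max_opposite = 1L,
                                          use_adjusted = TRUE),
                            proteome = list(z = 1.96),
                            map = list(unmapped_fraction = 0.05),
                            rrho = list(step = NULL),
                            prior = list(n_edges = 60L,
                                         overlap_fraction = 0.25),
                            grn = list(n_trees = 200L, n_permutations = 20L,
                                       p_strict = 0.001, p_prior = 0.05,
                                       n_true_edges = 15L,
                                       max_features = 60L)) {
  sim_defaults <- list(n_genes = 120L, seed = seed)
  sim <- utils::modifyList(sim_defaults, sim)
  sim$seed <- seed
  structure(list(seed = as.integer(seed), stages = stages, sim = sim,
                 rnaseq = rnaseq, proteome = proteome, map = map,
                 rrho = rrho, prior = prior, grn = grn),
            class = "pipeline_config")
}

#' Run the full synthetic-data pipeline
#'
#' Executes the enabled stages in dependency order against a synthetic
#' dataset with shared planted truth across platforms, writes all outputs
#' under `out_dir`, and returns (and writes) a run report listing, per
#' stage, the parameters, output files and headline counts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return a `run_report` list, invisibly written to
#'   `<out_dir>/run_report.json`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(pipeline_config(seed = 7), tempfile("xomics_run"))
#' names(rep$stages)
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(out_dir, paste0(...))
  report <- list(seed = config$seed, stages = list())
  note <- function(stage, params, files, counts) {
    report$stages[[stage]] <<- list(status = "completed", parameters = params,
                                    outputs = files, counts = counts)
  }
  on_stage <- function(s) s %in% config$stages
  env <- new.env()

  if (on_stage("simulate")) {
    scfg <- do.call(sim_config, config$sim)
    g <- scfg$n_genes
    # one shared truth drives both platforms so the cross-omics overlap
    # is genuinely enriched
    direction <- with_seed(substream_seed(config$seed, 11L), {
      n_de <- round(scfg$de_fraction * g)
      d <- integer(g)
      if (n_de > 0) {
        idx <- sample.int(g, n_de)
        d[idx[seq_len(ceiling(n_de / 2))]] <- 1L
        if (n_de > 1) d[idx[(ceiling(n_de / 2) + 1):n_de]] <- -1L
      }
      d
    })
    env$counts_sim <- simulate_paired_counts(scfg, direction = direction)
    prot_ids <- sprintf("R%04d", seq_len(g))
    env$true_net <- with_seed(substream_seed(config$seed, 12L), {
      n_e <- min(config$grn$n_true_edges,
                 config$grn$max_features * (config$grn$max_features - 1))
      pool <- prot_ids[seq_len(min(config$grn$max_features, g))]
      reg <- sample(pool, n_e, replace = TRUE)
      tgt <- vapply(reg, function(r) sample(setdiff(pool, r), 1), "")
      unique(data.frame(regulator = reg, target = unname(tgt),
                        stringsAsFactors = FALSE))
    })
    env$prot_sim <- simulate_timecourse_proteome(scfg, network = env$true_net,
                                                 direction = direction)
    env$map <- simulate_ortholog_map(
      prot_ids, unmapped_fraction = config$map$unmapped_fraction,
      seed = substream_seed(config$seed, 13L),
      targets = sprintf("G%04d", seq_len(g)))
    env$scfg <- scfg
    write_paired_counts(env$counts_sim$counts, path("counts.tsv"), path("pairs.tsv"))
    write_timecourse(env$prot_sim$intensities, path("intensities.tsv"))
    write_ortholog_map(env$map, path("ortholog_map.tsv"))
    write_edges(env$true_net, path("true_network.tsv"))
    jsonlite::write_json(list(direction = direction,
                              outlier = env$prot_sim$truth$features$outlier),
                         path("truth.json"), auto_unbox = TRUE)
    note("simulate", config$sim,
         c("counts.tsv", "pairs.tsv", "intensities.tsv", "ortholog_map.tsv",
           "true_network.tsv", "truth.json"),
         list(n_genes = g, n_de = sum(direction != 0)))
  }

  if (on_stage("rnaseq_de") && !is.null(env$counts_sim)) {
    r <- do.call(rnaseq_de, c(list(env$counts_sim$counts), config$rnaseq))
    env$rna_de <- r$de
    write_tsv(r$pairwise, path("rnaseq_pairwise.tsv"))
    write_tsv(r$de, path("rnaseq_de.tsv"))
    note("rnaseq_de", config$rnaseq, c("rnaseq_pairwise.tsv", "rnaseq_de.tsv"),
         list(n_up = sum(r$de$call == 1), n_down = sum(r$de$call == -1),
              n_unchanged = sum(r$de$call == 0)))
  }

  if (on_stage("proteome_de") && !is.null(env$prot_sim)) {
    p <- proteome_de(env$prot_sim$intensities, z = config$proteome$z)
    env$prot_res <- p
    write_tsv(data.frame(protein_id = rownames(p$ratios$ratios),
                         p$ratios$ratios, check.names = FALSE),
              path("proteome_ratios.tsv"))
    jsonlite::write_json(list(sigma = p$cutoffs$sigma, z = p$cutoffs$z,
                              c_up = p$cutoffs$c_up, c_down = p$cutoffs$c_down),
                         path("proteome_cutoffs.json"), auto_unbox = TRUE,
                         digits = NA)
    writeLines(p$outliers, path("proteome_outliers.txt"))
    write_tsv(p$de, path("proteome_de.tsv"))
    note("proteome_de", config$proteome,
         c("proteome_ratios.tsv", "proteome_cutoffs.json",
           "proteome_outliers.txt", "proteome_de.tsv"),
         list(n_up = sum(p$de$call == 1), n_down = sum(p$de$call == -1),
              n_unchanged = sum(p$de$call == 0),
              n_outliers = length(p$outliers)))
  }

  if (on_stage("cross") && !is.null(env$prot_res) && !is.null(env$rna_de)) {
    mr <- map_and_restrict(env$prot_res$de, env$rna_de, env$map)
    ov <- direction_consistent_intersection(mr$rnaseq, mr$proteome, mr$universe)
    env$cross <- list(mr = mr, ov = ov)
    jsonlite::write_json(ov[c("N", "A_up", "A_down", "B_up", "B_down",
                              "k_up", "k_down", "p_up", "p_down", "p_combined")],
                         path("overlap.json"), auto_unbox = TRUE, digits = NA)
    writeLines(ov$genes_up, path("intersect_up.txt"))
    writeLines(ov$genes_down, path("intersect_down.txt"))
    note("cross", config$map,
         c("overlap.json", "intersect_up.txt", "intersect_down.txt"),
         list(universe = ov$N, k_up = ov$k_up, k_down = ov$k_down))
  }

  if (on_stage("rrho") && !is.null(env$rna_de) && !is.null(env$prot_res)) {
    sym <- env$map$target_symbol[match(env$prot_res$de$feature_id,
                                       env$map$source_id)]
    ok <- !is.na(sym) & !duplicated(sym)
    lb <- rank_by_lfc(stats::setNames(env$prot_res$de$max_log2_excursion[ok],
                                      sym[ok]))
    la <- rank_by_lfc(stats::setNames(env$rna_de$mean_log2fc,
                                      env$rna_de$feature_id))
    m <- by_adjust_map(rrho_map(la, lb, step = config$rrho$step))
    q <- summarize_quadrants(m)
    utils::write.table(m$signed_logp, path("rrho_map.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    utils::write.table(m$corrected_logp, path("rrho_map_corrected.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    jsonlite::write_json(lapply(q, function(e)
      list(min_p = e$min_p, i = e$coords$i[1], j = e$coords$j[1],
           n_minima = nrow(e$coords))),
      path("rrho_summary.json"), auto_unbox = TRUE, digits = NA)
    env$rrho <- m
    note("rrho", config$rrho,
         c("rrho_map.tsv", "rrho_map_corrected.tsv", "rrho_summary.json"),
         list(grid = paste(dim(m$signed_logp), collapse = "x"), N = m$N))
  }

  if (on_stage("prior") && !is.null(env$true_net)) {
    # symbol-space truth for the prior (the prior lives in gene symbols)
    sym_of <- function(id) sprintf("G%s", substring(id, 2))
    true_sym <- data.frame(regulator = sym_of(env$true_net$regulator),
                           target = sym_of(env$true_net$target),
                           stringsAsFactors = FALSE)
    genes <- sprintf("G%04d", seq_len(env$scfg$n_genes))
    pe <- simulate_prior_edges(genes, config$prior$n_edges, true_sym,
                               overlap_fraction = config$prior$overlap_fraction,
                               seed = substream_seed(config$seed, 14L))
    de_syms <- if (!is.null(env$cross))
      c(env$cross$ov$genes_up, env$cross$ov$genes_down) else genes[1:10]
    regs <- unique(pe$regulator)
    gs <- augment_gene_set(if (length(de_syms)) de_syms else genes[1:10], regs)
    gs_all <- augment_gene_set(genes, regs)   # inference runs genome-wide here
    env$prior_net <- build_prior(
      data.frame(regulator = character(0), target = character(0),
                 source_tag = character(0)),
      list(pe), gs_all)
    write_edges(env$prior_net, path("prior_network.tsv"))
    jsonlite::write_json(list(n_edges = nrow(env$prior_net),
                              n_de = length(gs$de_genes),
                              n_regulators = length(gs$regulators),
                              n_union = gs$n_union,
                              n_overlap = length(gs$overlap)),
                         path("prior_provenance.json"), auto_unbox = TRUE)
    note("prior", config$prior, c("prior_network.tsv", "prior_provenance.json"),
         list(n_edges = nrow(env$prior_net), n_union = gs$n_union))
  }

  if (on_stage("infer") && !is.null(env$prot_sim) && !is.null(env$counts_sim)) {
    nf <- min(config$grn$max_features, env$scfg$n_genes)
    keep_p <- sprintf("R%04d", seq_len(nf))
    keep_g <- sprintf("G%04d", seq_len(nf))
    cfg_rf <- rf_config(n_trees = config$grn$n_trees,
                        seed = substream_seed(config$seed, 15L),
                        n_permutations = config$grn$n_permutations,
                        p_strict = config$grn$p_strict,
                        p_prior = config$grn$p_prior)
    # prior in each platform's namespace
    prior_sym <- env$prior_net
    prior_prot <- NULL
    if (!is.null(prior_sym) && nrow(prior_sym) > 0)
      prior_prot <- data.frame(regulator = sub("^G", "R", prior_sym$regulator),
                               target = sub("^G", "R", prior_sym$target))
    tc <- env$prot_sim$intensities
    sel <- rownames(tc$intensities) %in% keep_p
    dl <- design_lagged(tc$intensities[sel, , drop = FALSE], tc$coldata)
    env$net_prot <- score_network(dl, prior_prot, cfg_rf, "proteome")
    cm <- env$counts_sim$counts$counts
    cpm <- sweep(cm, 2, colSums(cm), "/") * 1e6
    pr <- env$counts_sim$counts$pairs
    du <- preprocess_rnaseq_fc(cpm[keep_g, pr$control_sample, drop = FALSE],
                               cpm[keep_g, pr$treated_sample, drop = FALSE])
    cfg_rf2 <- cfg_rf; cfg_rf2$seed <- substream_seed(config$seed, 16L)
    env$net_rna <- score_network(du, prior_sym, cfg_rf2, "rnaseq")
    write_tsv(env$net_prot, path("network_proteome.tsv"))
    write_tsv(env$net_rna, path("network_rnaseq.tsv"))
    note("infer", config$grn, c("network_proteome.tsv", "network_rnaseq.tsv"),
         list(selected_proteome = sum(env$net_prot$selected),
              selected_rnaseq = sum(env$net_rna$selected)))
  }

  if (on_stage("merge") && !is.null(env$net_prot)) {
    # put both nets in symbol space before merging
    np <- env$net_prot
    np$regulator <- sub("^R", "G", np$regulator)
    np$target <- sub("^R", "G", np$target)
    merged <- merge_networks(env$net_rna, np, env$prior_net)
    write_tsv(merged, path("network_merged.tsv"))
    s <- attr(merged, "summary")
    jsonlite::write_json(list(n_edges = s$n_edges, n_nodes = s$n_nodes,
                              by_provenance = as.list(s$by_provenance)),
                         path("network_summary.json"), auto_unbox = TRUE)
    note("merge", list(), c("network_merged.tsv", "network_summary.json"),
         list(n_edges = s$n_edges, n_nodes = s$n_nodes))
  }

  report$versions <- list(xomics = as.character(utils::packageVersion("xomics")),
                          R = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  class(report) <- "run_report"
  invisible(report)
}

#' Validate an on-disk input file against its expected schema
#'
#' Structural checks per file kind: column naming, types, positivity or
#' integrality where applicable, duplicate identifiers, and (for counts)
#' pairing completeness against the sidecar pairing file. Each violation
#' is reported with its coordinate.
#'
#' @param path file to check.
#' @param kind one of `"counts"`, `"intensities"`, `"map"`, `"edges"`,
#'   `"gmt"`, `"ranked"`.
#' @param pairs_path sidecar pairing TSV (only for `kind = "counts"`).
#' @return data.frame with columns `row`, `column`, `message`; zero rows
#'   when the file is valid.
#' @export
validate_formats <- function(path, kind = c("counts", "intensities", "map",
                                            "edges", "gmt", "ranked"),
                             pairs_path = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) xo_stop("file not found", "io_error")
  v <- list()
  bad <- function(row, col, msg) v[[length(v) + 1]] <<-
    data.frame(row = row, column = col, message = msg, stringsAsFactors = FALSE)
  if (kind == "gmt") {
    lines <- strsplit(readLines(path), "\t", fixed = TRUE)
    for (i in seq_along(lines))
      if (length(lines[[i]]) < 3)
        bad(i, NA, "GMT line needs name, description and >= 1 gene")
    nms <- vapply(lines, `[`, "", 1)
    for (d in which(duplicated(nms))) bad(d, 1, "duplicate gene-set name")
  } else {
    df <- read_tsv(path)
    if (kind == "counts") {
      if (names(df)[1] != "feature_id") bad(0, 1, "first column must be feature_id")
      for (d in which(duplicated(df[[1]]))) bad(d, 1, "duplicate feature_id")
      m <- df[, -1, drop = FALSE]
      for (j in seq_along(m)) {
        x <- m[[j]]
        w <- which(!is.finite(x) | x < 0 | x != floor(x))
        for (i in w) bad(i, j + 1, "counts must be non-negative integers")
      }
      if (!is.null(pairs_path)) {
        pr <- read_tsv(pairs_path)
        need <- c("pair_id", "control_sample", "treated_sample")
        if (!all(need %in% names(pr))) {
          bad(0, NA, "pairing file must have pair_id, control_sample, treated_sample")
        } else {
          used <- c(pr$control_sample, pr$treated_sample)
          for (d in which(duplicated(used))) bad(d, NA, "sample in more than one pair")
          miss <- setdiff(names(m), used)
          for (s in miss) bad(0, which(names(df) == s), "sample not covered by any pair")
          extra <- setdiff(used, names(m))
          for (s in extra) bad(0, NA, paste0("paired sample absent from counts: ", s))
        }
      }
    } else if (kind == "intensities") {
      if (!grepl("_id$", names(df)[1])) bad(0, 1, "first column must be an id column")
      for (d in which(duplicated(df[[1]]))) bad(d, 1, "duplicate protein_id")
      cn <- names(df)[-1]
      w <- which(!grepl("^t[0-9.]+_r[0-9]+$", cn))
      for (j in w) bad(0, j + 1, "column name must match t<hours>_r<replicate>")
      for (j in seq_along(df)[-1]) {
        x <- suppressWarnings(as.numeric(df[[j]]))
        for (i in which(!is.finite(x) | x <= 0))
          bad(i, j, "intensities must be positive")
      }
    } else if (kind == "map") {
      if (!all(c("source_id", "target_symbol") %in% names(df)))
        bad(0, NA, "map needs source_id and target_symbol columns")
      else for (d in which(duplicated(df$source_id)))
        bad(d, which(names(df) == "source_id"), "duplicate source_id")
    } else if (kind == "edges") {
      if (!all(c("regulator", "target") %in% names(df)))
        bad(0, NA, "edge list needs regulator and target columns")
      else {
        key <- paste(df$regulator, df$target,
                     if ("source_tag" %in% names(df)) df$source_tag else "",
                     sep = "\r")
        for (d in which(duplicated(key))) bad(d, NA, "duplicate edge")
      }
    } else if (kind == "ranked") {
      if (!all(c("symbol", "score") %in% names(df)))
        bad(0, NA, "ranked list needs symbol and score columns")
      else {
        for (d in which(duplicated(df$symbol)))
          bad(d, which(names(df) == "symbol"), "duplicate symbol")
        sc <- suppressWarnings(as.numeric(df$score))
        for (i in which(!is.finite(sc)))
          bad(i, which(names(df) == "score"), "score must be finite")
      }
    }
  }
  if (length(v) == 0)
    data.frame(row = integer(0), column = integer(0),
               message = character(0), stringsAsFactors = FALSE)
  else do.call(rbind, v)
}
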