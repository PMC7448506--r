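# Synthetic-data generators: reproducibility, planted-effect realization,
# and the deterministic bookkeeping of maps and prior edge lists.

test_that("identical configuration reproduces byte-identical outputs", {
  cfg <- sim_config(n_genes = 150, seed = 42)
  a <- simulate_paired_counts(cfg)
  b <- simulate_paired_counts(cfg)
  expect_identical(a, b)
  pa <- simulate_timecourse_proteome(cfg)
  pb <- simulate_timecourse_proteome(cfg)
  expect_identical(pa, pb)
})

test_that("no planted effect means all-null truth and unit mean ratios", {
  s0 <- simulate_paired_counts(sim_config(n_genes = 200, de_fraction = 0, seed = 1))
  expect_true(all(s0$truth$direction == 0L))
  # zero effect size: planted 'DE' genes have treated/control mean ratio 1,
  # so at matched library sizes the count distributions are exchangeable
  libs <- rep(300000L, 12)
  s1 <- simulate_paired_counts(sim_config(n_genes = 400, de_fraction = 0.1,
                                          lfc_effect = 0, library_sizes = libs,
                                          seed = 2))
  expect_true(all(s1$truth$direction == 0L))  # lfc 0 cannot define a direction
  m <- s1$counts$counts
  pr <- s1$counts$pairs
  lr <- log2((rowMeans(m[, pr$treated_sample]) + 0.5) /
               (rowMeans(m[, pr$control_sample]) + 0.5))
  expect_lt(abs(mean(lr)), 0.05)
})

test_that("planted log2 effects are realized at the configured magnitude", {
  s <- simulate_paired_counts(sim_config(n_genes = 2000, de_fraction = 0.05,
                                         lfc_effect = 2, nb_dispersion = 0.1,
                                         seed = 7))
  up <- s$truth$direction == 1L
  expect_gte(sum(up), 50)
  m <- s$counts$counts; pr <- s$counts$pairs
  lib <- colSums(m)
  lr <- sapply(seq_len(nrow(pr)), function(i) {
    log2(((m[, pr$treated_sample[i]] + 0.5) / lib[pr$treated_sample[i]]) /
           ((m[, pr$control_sample[i]] + 0.5) / lib[pr$control_sample[i]]))
  })
  expect_lt(abs(mean(rowMeans(lr)[up]) - 2), 0.15)
  dn <- s$truth$direction == -1L
  expect_lt(abs(mean(rowMeans(lr)[dn]) + 2), 0.15)
})

test_that("library-size scaling leaves planted log2 effects unchanged", {
  base <- rep(300000L, 12)
  s1 <- simulate_paired_counts(sim_config(n_genes = 2000, library_sizes = base,
                                          seed = 3))
  s2 <- simulate_paired_counts(sim_config(n_genes = 2000,
                                          library_sizes = 3L * base, seed = 3))
  expect_identical(s1$truth, s2$truth)
  # restrict to genes the shallower run covers well, so pseudo-count bias
  # does not masquerade as a depth effect
  covered <- rowMeans(s1$counts$counts) >= 20
  mean_lfc <- function(s) {
    m <- s$counts$counts; pr <- s$counts$pairs; lib <- colSums(m)
    up <- s$truth$direction == 1L & covered
    lr <- sapply(seq_len(nrow(pr)), function(i)
      log2(((m[, pr$treated_sample[i]] + 0.5) / lib[pr$treated_sample[i]]) /
             ((m[, pr$control_sample[i]] + 0.5) / lib[pr$control_sample[i]])))
    mean(rowMeans(lr)[up])
  }
  expect_lt(abs(mean_lfc(s1) - mean_lfc(s2)), 0.1)
})

test_that("zero control noise makes the two time-0 replicates identical", {
  s <- simulate_timecourse_proteome(sim_config(n_genes = 50, control_log2_sd = 0,
                                               outlier_fraction = 0,
                                               de_fraction = 0, seed = 4))
  m <- s$intensities$intensities; cd <- s$intensities$coldata
  c1 <- m[, cd$time == 0 & cd$replicate == 1]
  c2 <- m[, cd$time == 0 & cd$replicate == 2]
  expect_equal(c1, c2, ignore_attr = TRUE)
  expect_false(any(s$truth$features$outlier))
})

test_that("planted responders cross the CI cutoff at some post-zero time point", {
  cfg <- sim_config(n_genes = 400, de_fraction = 0.1, outlier_fraction = 0,
                    control_log2_sd = 0.158, seed = 5)
  s <- simulate_timecourse_proteome(cfg)
  rt <- normalize_timecourse(s$intensities)
  cut <- estimate_control_cutoffs(rt$control_ratio)
  up <- s$truth$features$direction == 1L
  crossed <- rowSums(rt$ratios[up, , drop = FALSE] > cut$c_up) > 0
  expect_gte(mean(crossed), 0.95)
})

test_that("a planted lagged regulation shows up as lag-1 correlation", {
  cfg <- sim_config(n_genes = 10, de_fraction = 0, outlier_fraction = 0,
                    timepoints = seq(0, 28, by = 4), n_replicates = 50,
                    control_log2_sd = 0.01, seed = 6)
  net <- data.frame(regulator = "R0001", target = "R0002")
  s <- simulate_timecourse_proteome(cfg, network = net, lag_coef = 1,
                                    lag_noise_sd = 0.01)
  m <- log2(s$intensities$intensities); cd <- s$intensities$coldata
  tps <- sort(unique(cd$time))
  a <- c(); b <- c()
  for (r in unique(cd$replicate)) for (k in 2:length(tps)) {
    a <- c(a, m["R0001", cd$time == tps[k - 1] & cd$replicate == r])
    b <- c(b, m["R0002", cd$time == tps[k] & cd$replicate == r])
  }
  expect_gt(cor(a, b), 0.9)
})

test_that("proteome generator rejects networks over unknown proteins", {
  cfg <- sim_config(n_genes = 10, seed = 1)
  bad <- data.frame(regulator = "R9999", target = "R0001")
  expect_error(simulate_timecourse_proteome(cfg, network = bad),
               class = "reference_error")
})

test_that("ortholog map realizes the configured fractions exactly", {
  feats <- sprintf("R%03d", 1:100)
  bij <- simulate_ortholog_map(feats, 0, 0, seed = 1)
  expect_false(any(is.na(bij$target_symbol)))
  expect_equal(anyDuplicated(bij$target_symbol), 0L)
  m <- simulate_ortholog_map(feats, unmapped_fraction = 0.1, seed = 2)
  expect_identical(sum(is.na(m$target_symbol)), 10L)
  m2 <- simulate_ortholog_map(feats, many_to_one_fraction = 0.2, seed = 3)
  expect_gte(max(table(m2$target_symbol)), 2L)
  expect_error(simulate_ortholog_map(c("a", "a")), class = "invalid_input")
})

test_that("prior edge lists realize the configured truth overlap exactly", {
  genes <- sprintf("G%02d", 1:30)
  truth <- data.frame(regulator = rep(genes[1:5], each = 5),
                      target = rep(genes[6:10], 5))
  key <- function(d) paste(d$regulator, d$target)
  all_true <- simulate_prior_edges(genes, 10L, truth, 1, seed = 1)
  expect_true(all(key(all_true) %in% key(truth)))
  none <- simulate_prior_edges(genes, 40L, truth, 0, seed = 2)
  expect_length(intersect(key(none), key(truth)), 0)
  mix <- simulate_prior_edges(genes, 50L, truth, 0.4, seed = 3)
  expect_length(intersect(key(mix), key(truth)), 20)
  expect_equal(anyDuplicated(key(mix)), 0L)
  expect_error(simulate_prior_edges(genes, 30L * 29L + 1L, truth, 0, seed = 1),
               class = "invalid_config")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_genes = 0), class = "invalid_config")
  expect_error(sim_config(n_pairs = -1), class = "invalid_config")
  expect_error(sim_config(de_fraction = 0.7, outlier_fraction = 0.5),
               class = "invalid_config")
  expect_error(sim_config(timepoints = c(4, 16)), class = "invalid_config")
  expect_error(sim_config(timepoints = c(0, 16, 8)), class = "invalid_config")
})
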