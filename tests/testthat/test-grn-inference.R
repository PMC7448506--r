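# Random-forest network inference: designs, importances, permutation
# null, empirical p-values, selection and merging.

test_that("fold-change preprocessing floors, logs and sd-scales", {
  ctrl <- matrix(c(0.02, 1, 2, 4, 1, 1,
                   2, 2, 2, 2, 2, 2,
                   1, 2, 4, 8, 16, 32), 3, 6, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"), NULL))
  trt <- matrix(c(0.05, 2, 4, 2, 0.5, 3,
                  2, 2, 2, 2, 2, 2,
                  2, 8, 4, 4, 64, 32), 3, 6, byrow = TRUE,
                dimnames = list(c("g1", "g2", "g3"), NULL))
  expect_message(d <- preprocess_rnaseq_fc(ctrl, trt), "zero-variance")
  expect_false("g2" %in% rownames(d$X))           # constant fold change
  # hand computation for g3: fc = (2, 4, 1, 0.5, 4, 1), log2 then / sd
  l <- log2(c(2, 4, 1, 0.5, 4, 1))
  expect_equal(unname(d$X["g3", ]), l / sd(l), tolerance = 1e-12)
  # the floor applies to both sides: g1's first pair becomes 0.1/0.1 = 1
  l1 <- log2(c(1, 2, 2, 0.5, 0.5, 3))
  expect_equal(unname(d$X["g1", ]), l1 / sd(l1), tolerance = 1e-12)
})

test_that("the lagged design pairs each observation with one step earlier", {
  sim <- simulate_timecourse_proteome(sim_config(n_genes = 10, seed = 61))
  d <- design_lagged(sim$intensities)
  expect_equal(d$mode, "directed_lagged")
  cd <- sim$intensities$coldata
  expect_equal(cd$time[d$target_idx], c(4, 16, 24, 4, 16, 24))
  expect_equal(cd$time[d$pred_idx], c(0, 4, 16, 0, 4, 16))
  # every (target, predictor) pair is one step apart in the same replicate
  tps <- sort(unique(cd$time))
  expect_true(all(match(cd$time[d$target_idx], tps) -
                    match(cd$time[d$pred_idx], tps) == 1))
  expect_true(all(cd$replicate[d$target_idx] == cd$replicate[d$pred_idx]))
})

test_that("a planted linear signal dominates the importances", {
  set.seed(62)
  hits <- 0
  for (r in 1:40) {
    n <- 30
    X <- matrix(rnorm(21 * n), 21, n,
                dimnames = list(c("x1", sprintf("d%02d", 1:20)), NULL))
    y <- 2 * X["x1", ] + rnorm(n, 0, 0.05)
    Xall <- rbind(y = y, X)
    d <- structure(list(mode = "undirected", X = Xall,
                        target_idx = seq_len(n), pred_idx = seq_len(n)),
                   class = "expression_design")
    imp <- rf_importance(d, "y", rf_config(n_trees = 300, seed = r))
    if (names(which.max(imp)) == "x1") hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})

test_that("a constant target yields all-zero importances", {
  X <- matrix(rnorm(30), 3, 10, dimnames = list(c("a", "b", "c"), NULL))
  X["a", ] <- 5
  d <- structure(list(mode = "undirected", X = X,
                      target_idx = 1:10, pred_idx = 1:10),
                 class = "expression_design")
  # note: sd-scaling upstream would drop such a feature; rf_importance
  # itself must still behave
  expect_equal(unname(rf_importance(d, "a", rf_config(n_trees = 50))),
               c(0, 0))
})

test_that("max-symmetrization reduces to the element-wise maximum", {
  s <- matrix(c(NA, 0.1, 0.4, NA, 0.3, 0.2, 0.05, 0.7, NA), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  u <- symmetrize_undirected(s)
  expect_equal(u["a", "b"], max(s["a", "b"], s["b", "a"], na.rm = TRUE))
  set.seed(63)
  m <- matrix(runif(16), 4, 4)
  u2 <- symmetrize_undirected(m)
  ref <- pmax(m, t(m))
  expect_equal(u2[upper.tri(u2)], ref[upper.tri(ref)])
  expect_error(symmetrize_undirected(matrix(1, 2, 3)), class = "invalid_input")
})

test_that("the permutation null has the right size and is seed-reproducible", {
  sim <- simulate_timecourse_proteome(sim_config(n_genes = 8, seed = 64,
                                                 de_fraction = 0,
                                                 outlier_fraction = 0))
  d <- design_lagged(sim$intensities)
  cfg <- rf_config(n_trees = 50, seed = 9, n_permutations = 3)
  n1 <- permutation_null(d, cfg)
  expect_length(n1, 8 * 7 * 3)    # edges per inference x permutations
  expect_identical(n1, permutation_null(d, cfg))
})

test_that("empirical p-values equal brute-force counting with add-one", {
  null <- c(5, 3, 8, 1, 9, 2, 7, 4, 6, 10, 2, 2, 3, 5, 8, 1, 4, 6, 9, 7)
  obs <- c(11, 5, 0, 8, 2.5)
  want <- vapply(obs, function(o) (1 + sum(null >= o)) / (1 + length(null)), 0)
  expect_equal(edge_pvalues(obs, null), want, tolerance = 1e-12)
  expect_equal(edge_pvalues(100, rep(0, 999)), 1 / 1000)
  expect_error(edge_pvalues(1, numeric(0)), class = "invalid_input")
})

test_that("edge selection applies the strict-or-prior rule with strict inequalities", {
  prior <- data.frame(regulator = c("A", "C"), target = c("B", "D"))
  e <- data.frame(regulator = c("A", "A", "X", "C", "B"),
                  target = c("B", "C", "Y", "D", "A"),
                  p = c(0.01, 0.01, 0.0005, 0.2, 0.04))
  cfg <- rf_config(p_strict = 0.001, p_prior = 0.05)
  got <- select_edges(e, prior, cfg, directed = TRUE)
  expect_equal(got$selected, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  # undirected matching accepts either orientation (B-A matches prior A->B)
  got_u <- select_edges(e, prior, cfg, directed = FALSE)
  expect_true(got_u$selected[5])
  # boundary: p exactly at a threshold is not selected
  eb <- data.frame(regulator = "A", target = "B", p = 0.05)
  expect_false(select_edges(eb, prior, cfg)$selected)
})

test_that("merging unions selected edges with provenance and node counts", {
  mk_net <- function(reg, tgt, sel = TRUE) {
    d <- data.frame(regulator = reg, target = tgt, score = 1,
                    p = 0.0001, in_prior = FALSE, selected = sel,
                    provenance = "x")
    class(d) <- c("scored_network", "data.frame"); d
  }
  a <- mk_net(c("A", "B", "C"), c("B", "C", "D"))
  b <- mk_net(c("E", "F", "G", "H"), c("F", "G", "H", "E"))
  m <- merge_networks(a, b, NULL)
  expect_equal(nrow(m), 7)
  expect_false(any(m$provenance == "both"))
  s <- attr(m, "summary")
  expect_equal(s$n_nodes, length(unique(c(m$regulator, m$target))))
  # one shared edge (matched as unordered pair) becomes provenance "both"
  b2 <- mk_net(c("B", "E"), c("A", "F"))
  m2 <- merge_networks(a, b2, NULL)
  expect_equal(sum(m2$provenance == "both"), 1)
  expect_equal(nrow(m2), 4)
  # unselected edges never enter the merge
  a2 <- mk_net("Z", "Q", sel = FALSE)
  expect_equal(nrow(merge_networks(a2, b2, NULL)), 2)
})

test_that("adding true edges to the prior never shrinks the selected set", {
  set.seed(65)
  e <- data.frame(regulator = sprintf("r%02d", 1:40),
                  target = sprintf("t%02d", 1:40),
                  p = runif(40, 0, 0.2))
  cfg <- rf_config(p_strict = 0.001, p_prior = 0.05)
  none <- select_edges(e, NULL, cfg)
  grow <- select_edges(e, e[e$p < 0.05, c("regulator", "target")], cfg)
  expect_gte(sum(grow$selected), sum(none$selected))
  expect_gt(sum(grow$selected), sum(none$selected))  # some p in (0.001, 0.05)
})
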