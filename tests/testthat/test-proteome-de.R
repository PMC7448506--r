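# Time-course proteome normalization, cutoff estimation, outlier
# exclusion and any-time-point calling.

tc_from_matrix <- function(m) {
  cn <- colnames(m)
  mt <- regmatches(cn, regexec("^t([0-9.]+)_r([0-9]+)$", cn))
  timecourse_intensities(m, data.frame(
    column = cn,
    time = as.numeric(vapply(mt, `[`, "", 2)),
    replicate = as.integer(vapply(mt, `[`, "", 3))))
}

toy_table <- function(vals) {
  m <- matrix(vals, nrow = length(vals) / 8, byrow = TRUE)
  colnames(m) <- c("t0_r1", "t0_r2", "t4_r1", "t4_r2",
                   "t16_r1", "t16_r2", "t24_r1", "t24_r2")
  rownames(m) <- sprintf("p%d", seq_len(nrow(m)))
  tc_from_matrix(m)
}

test_that("normalization yields unit ratios for flat proteins and is scale invariant", {
  tc <- toy_table(c(rep(10, 8), rep(3, 8)))
  rt <- normalize_timecourse(tc)
  expect_equal(unname(rt$ratios), matrix(1, 2, 6), tolerance = 1e-12)
  tc7 <- tc
  tc7$intensities <- tc$intensities * 7
  rt7 <- normalize_timecourse(tc7)
  expect_equal(rt$ratios, rt7$ratios, tolerance = 1e-12)
  expect_equal(rt$control_ratio, rt7$control_ratio, tolerance = 1e-12)
})

test_that("stage-1 global scaling cancels in the per-protein stage-2 ratios", {
  # protein A controls (10, 10) then 20 everywhere; protein B controls (20, 20)
  tc <- toy_table(c(10, 10, 20, 20, 20, 20, 20, 20,
                    20, 20, 20, 20, 20, 20, 20, 20))
  rt <- normalize_timecourse(tc)
  expect_equal(unname(rt$ratios["p1", ]), rep(2, 6), tolerance = 1e-12)
  expect_equal(unname(rt$ratios["p2", ]), rep(1, 6), tolerance = 1e-12)
})

test_that("cutoffs follow the CI formula and are reciprocal", {
  s <- log2(1.24) / 1.96
  cs <- estimate_control_cutoffs(sigma = s)
  expect_equal(cs$c_up, 1.24, tolerance = 1e-12)
  expect_equal(round(cs$c_down, 1), 0.8)
  expect_equal(cs$c_up * cs$c_down, 1, tolerance = 1e-12)
  # degenerate: identical controls give unit cutoffs
  cs0 <- estimate_control_cutoffs(rep(1, 10))
  expect_equal(c(cs0$c_up, cs0$c_down), c(1, 1))
  expect_error(estimate_control_cutoffs(c(1, -2)), class = "invalid_input")
})

test_that("sigma is recovered from sampled control ratios", {
  set.seed(21)
  cr <- 2^rnorm(5000, 0, 0.2)
  cs <- estimate_control_cutoffs(cr)
  expect_lt(abs(cs$sigma - 0.2), 0.01)
})

test_that("outlier flagging applies the CI rule and excludes from calling", {
  cut <- estimate_control_cutoffs(sigma = log2(1.24) / 1.96)
  rt <- structure(list(
    ratios = matrix(1, 3, 2, dimnames = list(c("a", "b", "c"), c("t4_r1", "t4_r2"))),
    control_ratio = c(a = 1.0, b = 1.30, c = 0.75),
    coldata = data.frame(column = c("t4_r1", "t4_r2"), time = 4, replicate = 1:2)),
    class = "ratio_table")
  out <- flag_outliers(rt, cut)
  expect_setequal(out, c("b", "c"))
  de <- call_de_proteins(rt, cut, exclude = out)
  expect_false(any(out %in% de$feature_id))
})

test_that("any-time-point rule and conflict resolution follow the cutoffs", {
  cut <- estimate_control_cutoffs(sigma = log2(1.24) / 1.96)
  mk <- function(r) structure(list(
    ratios = matrix(r, 1, 3, dimnames = list("x", c("t4_r1", "t16_r1", "t24_r1"))),
    control_ratio = c(x = 1),
    coldata = data.frame(column = c("t4_r1", "t16_r1", "t24_r1"),
                         time = c(4, 16, 24), replicate = 1L)),
    class = "ratio_table")
  expect_identical(call_de_proteins(mk(c(1.05, 1.10, 1.20)), cut)$call, 0L)
  expect_identical(call_de_proteins(mk(c(1.0, 1.30, 1.10)), cut)$call, 1L)
  # both directions crossed: direction of the largest |log2| excursion
  cf <- call_de_proteins(mk(c(0.70, 1.0, 1.30)), cut)
  expect_true(cf$conflict)
  expect_identical(cf$call, -1L)
})

test_that("enlarging sigma never increases the number of calls", {
  sim <- simulate_timecourse_proteome(sim_config(n_genes = 300, seed = 22))
  rt <- normalize_timecourse(sim$intensities)
  sig <- estimate_control_cutoffs(rt$control_ratio)$sigma
  n_calls <- vapply(c(0.5, 1, 2, 4) * sig, function(s) {
    cut <- estimate_control_cutoffs(sigma = s)
    sum(call_de_proteins(rt, cut)$call != 0L)
  }, 0)
  expect_true(all(diff(n_calls) <= 0))
})

test_that("planted responders and outliers are recovered on synthetic data", {
  sim <- simulate_timecourse_proteome(sim_config(n_genes = 800,
                                                 control_log2_sd = 0.158,
                                                 seed = 23))
  res <- proteome_de(sim$intensities)
  tr <- sim$truth$features
  expect_gte(mean(tr$protein_id[tr$outlier] %in% res$outliers), 0.9)
  m <- merge(tr, res$de, by.x = "protein_id", by.y = "feature_id")
  expect_gte(mean(m$call[m$direction != 0] == m$direction[m$direction != 0]), 0.9)
  expect_gte(mean(m$call[m$direction == 0] == 0), 0.9)
})
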