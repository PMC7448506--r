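# Ortholog mapping, universe restriction, and the direction-consistent
# hypergeometric intersection.

de_tab <- function(ids, calls) data.frame(feature_id = ids, call = calls,
                                          stringsAsFactors = FALSE)

test_that("bijective maps keep DE counts; unmapped sources drop out", {
  ids <- sprintf("R%02d", 1:10)
  syms <- sprintf("G%02d", 1:10)
  map <- data.frame(source_id = ids, target_symbol = syms)
  prot <- de_tab(ids, c(1, 1, -1, 0, 0, 0, 0, 0, 0, 1))
  rna <- de_tab(syms, c(1, 0, -1, 0, 1, 0, 0, 0, 0, 1))
  mr <- map_and_restrict(prot, rna, map)
  expect_setequal(mr$universe, syms)
  expect_equal(sum(mr$proteome$call == 1), 3)
  map$target_symbol[c(2, 5)] <- NA
  mr2 <- map_and_restrict(prot, rna, map)
  expect_equal(mr2$report$unmapped, 2)
  expect_false(any(c("G02", "G05") %in% mr2$universe))
})

test_that("many-to-one collisions resolve by any-evidence with conflicts zeroed", {
  map <- data.frame(source_id = c("Ra", "Rb", "Rc", "Rd"),
                    target_symbol = c("G1", "G1", "G2", "G2"))
  rna <- de_tab(c("G1", "G2"), c(0, 0))
  prot <- de_tab(c("Ra", "Rb", "Rc", "Rd"), c(1, 0, 1, -1))
  mr <- map_and_restrict(prot, rna, map)
  expect_identical(mr$proteome$call[mr$proteome$feature_id == "G1"], 1L)
  expect_identical(mr$proteome$call[mr$proteome$feature_id == "G2"], 0L)
  expect_equal(mr$report$conflicted_symbols, 1)
  expect_error(map_and_restrict(prot, de_tab("ZZZ", 0), map),
               class = "empty_universe")
})

test_that("hypergeometric tails are exact against full enumeration", {
  # frozen values
  expect_equal(hypergeom_overlap_p(5, 5, 5, 10, "over"), 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(hypergeom_overlap_p(0, 5, 5, 10, "over"), 1)
  expect_equal(hypergeom_overlap_p(3, 4, 6, 12, "over"), 3 / 11,
               tolerance = 1e-12)
  # every (K, n, k) for a few universes, against the draw-enumeration oracle
  for (N in c(6, 9, 12)) {
    for (K in 0:N) for (n in 1:N) {
      o <- oracle_hyper_tails(N, K, n)
      for (idx in seq_along(o$ks)) {
        k <- o$ks[idx]
        if (k < max(0, K + n - N)) next
        expect_equal(hypergeom_overlap_p(k, K, n, N, "over"), o$over[idx],
                     tolerance = 1e-10)
        expect_equal(hypergeom_overlap_p(k, K, n, N, "under"), o$under[idx],
                     tolerance = 1e-10)
      }
    }
  }
  expect_error(hypergeom_overlap_p(6, 5, 5, 10), class = "invalid_input")
})

test_that("the over-tail is monotone decreasing in the overlap", {
  p <- vapply(0:10, function(k) hypergeom_overlap_p(k, 10, 20, 100, "over"), 0)
  expect_true(all(diff(p) <= 0))
})

test_that("over-tail p-values are super-uniform under independent calls", {
  set.seed(31)
  N <- 60; A <- 12; B <- 15
  p <- replicate(1000, {
    a <- sample(N, A); b <- sample(N, B)
    hypergeom_overlap_p(length(intersect(a, b)), A, B, N, "over")
  })
  for (alpha in c(0.01, 0.05, 0.1, 0.25))
    expect_lte(mean(p <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / 1000))
})

test_that("the direction-consistent intersection counts and tests per direction", {
  u <- sprintf("g%03d", 1:1000)
  set.seed(32)
  common_up <- sample(u, 30)
  a_call <- b_call <- setNames(integer(1000), u)
  a_call[common_up] <- 1L; b_call[common_up] <- 1L
  a_call[sample(names(a_call)[a_call == 0], 70)] <- 1L
  b_call[sample(names(b_call)[b_call == 0], 50)] <- 1L
  ov <- direction_consistent_intersection(de_tab(u, unname(a_call)),
                                          de_tab(u, unname(b_call)), u)
  expect_gte(ov$k_up, 30)
  expect_lt(ov$p_up, 1e-6)
  expect_equal(ov$p_combined, ov$p_up * ov$p_down, tolerance = 1e-12)
  # all-zero second table: empty overlap, unit p
  ov0 <- direction_consistent_intersection(de_tab(u, unname(a_call)),
                                           de_tab(u, integer(1000)), u)
  expect_equal(c(ov0$k_up, ov0$k_down), c(0, 0))
  expect_equal(c(ov0$p_up, ov0$p_down), c(1, 1))
  # identical tables: overlap saturates the margins
  ovi <- direction_consistent_intersection(de_tab(u, unname(a_call)),
                                           de_tab(u, unname(a_call)), u)
  expect_equal(ovi$k_up, ovi$A_up)
})
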