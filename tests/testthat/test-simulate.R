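test_that("random trees are seed-deterministic with the right shape", {
  t1 <- random_tree(12, seed = 5)
  t2 <- random_tree(12, seed = 5)
  expect_identical(canonical_newick(t1), canonical_newick(t2))
  expect_equal(length(bipartitions(random_tree(33, seed = 1))), 30)
})

test_that("sequential addition samples 4-leaf topologies uniformly", {
  # 3 possible topologies; chi-square over 3000 draws
  set.seed(1234)
  keys <- vapply(1:3000, function(i) canonical_newick(random_tree(4)), "")
  tab <- table(keys)
  expect_equal(length(tab), 3)
  expect_true(all(abs(tab / 3000 - 1 / 3) < 0.03))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 1e-4)
})

test_that("simulated datasets honour their configuration and bookkeeping", {
  sim0 <- simulate_matrix(n_taxa = 8, n_chars = 10, change_rate = 0, seed = 2)
  expect_true(all(apply(sim0$matrix$cells, 2, function(col)
    length(unique(col[col %in% as.character(0:9)])) == 1)))
  expect_equal(tree_length(sim0$true_tree, sim0$matrix), 0)
  sim <- simulate_matrix(n_taxa = 10, n_chars = 30, change_rate = 2, seed = 3,
                         missing_fraction = 0.05, inapplicable_fraction = 0.05)
  expect_equal(dim(sim$matrix$cells), c(10, 30))
  expect_gt(sum(sim$matrix$cells == "?"), 0)
  expect_gt(sum(sim$matrix$cells == "-"), 0)
  # parsimony never needs more steps than the simulation actually used
  clean <- simulate_matrix(n_taxa = 10, n_chars = 30, change_rate = 2, seed = 3,
                           missing_fraction = 0, inapplicable_fraction = 0)
  expect_lte(tree_length(clean$true_tree, clean$matrix), nrow(clean$true_changes))
  # determinism
  rep2 <- simulate_matrix(n_taxa = 10, n_chars = 30, change_rate = 2, seed = 3,
                          missing_fraction = 0.05, inapplicable_fraction = 0.05)
  expect_identical(rep2$matrix$cells, sim$matrix$cells)
})

test_that("generated matrices round-trip through the matrix formats", {
  sim <- simulate_matrix(n_taxa = 9, n_chars = 12, change_rate = 1.5, seed = 11,
                         missing_fraction = 0.05, inapplicable_fraction = 0.05)
  for (fmt in c("tnt", "nexus", "table"))
    expect_identical(read_matrix(write_matrix(sim$matrix, fmt), fmt)$cells,
                     sim$matrix$cells)
})

test_that("search recovers the generating tree from low-homoplasy data", {
  hits <- 0
  for (s in 1:10) {
    sim <- simulate_matrix(n_taxa = 10, n_chars = 200, change_rate = 1, seed = s,
                           missing_fraction = 0, inapplicable_fraction = 0)
    res <- heuristic_search(sim$matrix, n_replicates = 3, seed = s)
    cons <- strict_consensus(res$trees)
    if (rf_distance(cons, sim$true_tree) == 0) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("recovery error shrinks as characters are added", {
  rf_at <- function(nc) {
    mean(vapply(1:6, function(s) {
      sim <- simulate_matrix(n_taxa = 12, n_chars = nc, change_rate = 1,
                             seed = 100 + s, missing_fraction = 0,
                             inapplicable_fraction = 0)
      res <- heuristic_search(sim$matrix, n_replicates = 2, seed = s)
      rf_distance(strict_consensus(res$trees), sim$true_tree)
    }, 0))
  }
  r <- c(rf_at(20), rf_at(50), rf_at(200))
  expect_lte(r[3], r[1])
  expect_lte(r[3], r[2])
  expect_lt(r[3], 1)
})

test_that("ensemble CI falls as the simulated change rate rises", {
  ci_at <- function(rate) {
    mean(vapply(1:8, function(s) {
      sim <- simulate_matrix(n_taxa = 10, n_chars = 40, change_rate = rate,
                             seed = 200 + s, missing_fraction = 0,
                             inapplicable_fraction = 0)
      ir <- index_report(sim$true_tree, sim$matrix)
      ci <- ir$ensemble$CI[ir$ensemble$convention == "all"]
      if (is.na(ci)) 1 else ci
    }, 0))
  }
  cis <- vapply(c(0.5, 1, 2, 4), ci_at, 0)
  expect_true(all(diff(cis) < 0))
})

test_that("two-signal construction behaves as designed", {
  clean <- two_signal_matrix(9, 8, 0, seed = 41)
  res <- heuristic_search(clean$matrix, n_replicates = 4, seed = 1)
  cons <- strict_consensus(res$trees)
  expect_true(all(names(bipartitions(cons)) %in%
                    names(bipartitions(clean$true_tree))))
  mix <- two_signal_matrix(9, 8, 2, seed = 43)
  expect_equal(mix$conflict_characters, 9:10)
  expect_equal(n_chars(mix$matrix), 10)
})
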