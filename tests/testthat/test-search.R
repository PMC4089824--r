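test_that("Wagner addition groups compatible taxa and is replayable", {
  m <- read_matrix("A 0\nB 0\nC 1\nD 1", "table")
  tr <- wagner_build(m, order = c("A", "B", "C", "D"))
  expect_true("A|B" %in% names(bipartitions(tr)) ||
              "C|D" %in% names(bipartitions(tr)))
  t1 <- wagner_build(fixture_cached()$matrix, seed = 99)
  t2 <- wagner_build(fixture_cached()$matrix, seed = 99)
  expect_identical(canonical_newick(t1), canonical_newick(t2))
})

test_that("Wagner length is never below the optimum and attains it on clean data", {
  set.seed(61)
  for (i in 1:10) {
    n <- sample(5:8, 1)
    mm <- random_small_matrix(n, 6, 3)
    opt <- exhaustive_search(mm)$best_length
    expect_gte(tree_length(wagner_build(mm, seed = i), mm), opt)
    clean <- two_signal_matrix(n, 5, 0, seed = i)
    expect_equal(tree_length(wagner_build(clean$matrix, seed = i), clean$matrix),
                 exhaustive_search(clean$matrix)$best_length)
  }
})

test_that("exhaustive search enumerates (2n-5)!! topologies", {
  m4 <- random_small_matrix(4, 2, 2)
  expect_equal(exhaustive_search(m4)$n_topologies, 3)
  m7 <- random_small_matrix(7, 2, 2)
  expect_equal(exhaustive_search(m7)$n_topologies, 945)
  expect_error(exhaustive_search(random_small_matrix(11, 2, 2)), "at most 10")
})

test_that("TBR from any start reaches the global optimum on small instances", {
  set.seed(67)
  for (i in 1:60) {
    n <- 7
    mm <- random_small_matrix(n, sample(4:8, 1), sample(2:3, 1))
    opt <- exhaustive_search(mm)$best_length
    start <- random_tree(n, labels = mm$taxa)
    res <- tbr_swap(start, mm, hold = 10)
    expect_equal(res$best_length, opt, label = sprintf("instance %d", i))
  }
})

test_that("TBR on an already optimal unique tree returns it unchanged", {
  # one clean binary character per split of the generating tree makes it
  # the unique most parsimonious tree
  tr <- random_tree(7, seed = 3)
  cells <- vapply(bipartitions(tr), function(side)
    as.character(as.integer(tr$tip.label %in% side)), character(7))
  m <- char_matrix(cells, taxa = tr$tip.label)
  res <- tbr_swap(tr, m, hold = 10)
  expect_equal(length(res$trees), 1)
  expect_true(trees_equal(res$trees[[1]], tr))
})

test_that("heuristic search equals exhaustive search and is seed-deterministic", {
  set.seed(71)
  for (i in 1:12) {
    n <- sample(6:9, 1)
    mm <- random_small_matrix(n, sample(4:7, 1), sample(2:3, 1), missing_p = 0.1)
    ex <- exhaustive_search(mm)
    hs <- heuristic_search(mm, n_replicates = 3, hold = 10, max_trees = 200, seed = i)
    expect_equal(hs$best_length, ex$best_length)
  }
  fx <- fixture_cached()
  a <- heuristic_search(fx$matrix, n_replicates = 3, seed = 7)
  b <- heuristic_search(fx$matrix, n_replicates = 3, seed = 7)
  expect_identical(a$replicate_log, b$replicate_log)
  expect_identical(lapply(a$trees, canonical_newick), lapply(b$trees, canonical_newick))
})

test_that("best length never worsens as replicates are added (same seed stream)", {
  fx <- fixture_cached()
  few <- heuristic_search(fx$matrix, n_replicates = 2, seed = 19, final_sweep = FALSE)
  more <- heuristic_search(fx$matrix, n_replicates = 6, seed = 19, final_sweep = FALSE)
  expect_lte(more$best_length, few$best_length)
})

test_that("clean synthetic data yield the generating tree as single MPT", {
  sim <- two_signal_matrix(10, 8, 0, seed = 23)
  res <- heuristic_search(sim$matrix, n_replicates = 5, seed = 1)
  expect_equal(length(res$trees), 1)
  # collapsed MPT must refine-match the generating tree on supported splits
  expect_true(all(names(bipartitions(res$trees[[1]])) %in%
                    names(bipartitions(sim$true_tree))))
})

test_that("ambiguous-branch collapsing removes exactly the unforced branches", {
  # t1..t5 with one character 1,1,0,0,? : the placement of t5 is arbitrary,
  # so resolutions around it collapse
  m <- char_matrix(cbind(c("1", "1", "0", "0", "?")), taxa = paste0("t", 1:5))
  tr <- parse_newick("((t1,(t2,t5)),(t3,t4));")
  col <- collapse_ambiguous(tr, m)
  expect_lt(length(bipartitions(col)), length(bipartitions(tr)))
  # a branch bearing an unambiguous change is retained
  expect_true("t3|t4" %in% names(bipartitions(col)) ||
              "t1|t2|t5" %in% names(bipartitions(col)))
  # idempotent
  expect_true(trees_equal(collapse_ambiguous(col, m), col))
  # collapsing never reduces the polytomy-general length
  set.seed(73)
  for (i in 1:10) {
    mm <- random_small_matrix(7, 5, 3)
    tr <- random_tree(7, labels = mm$taxa)
    expect_gte(tree_length(collapse_ambiguous(tr, mm), mm), tree_length(tr, mm))
  }
})

test_that("verbatim published settings recover the published search summary", {
  res <- fixture_search_cached()
  expect_equal(res$best_length, 301)
  expect_equal(length(res$trees), 12)
})
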