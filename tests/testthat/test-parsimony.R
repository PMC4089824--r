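test_that("degenerate columns score zero and star trees attain g", {
  m <- char_matrix(matrix("1", 6, 3), taxa = paste0("t", 1:6))
  tr <- random_tree(6, seed = 3)
  expect_equal(tree_length(tr, m), 0)
  star <- ape::read.tree(text = paste0("(", paste(paste0("t", 1:6), collapse = ","), ");"))
  set.seed(11)
  for (i in 1:20) {
    mm <- random_small_matrix(6, 4, sample(2:4, 1), missing_p = 0.15)
    b <- step_bounds(mm)
    expect_equal(unname(character_length(star, mm)), b$g)
  }
})

test_that("Hartigan lengths equal the uniform-cost Sankoff oracle", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(5:8, 1)
    mm <- random_small_matrix(n, sample(2:5, 1), sample(2:4, 1), missing_p = 0.1)
    tr <- random_tree(n)
    expect_equal(tree_length(tr, mm), sankoff_tree_length(tr, mm))
    # polytomous version: collapse a random internal edge set
    bp <- bipartitions(tr)
    if (length(bp) >= 2) {
      drop <- which(tr$edge[, 2] > n)[1]
      poly <- collapse_tree_edges(tr, drop)
      expect_equal(tree_length(poly, mm), sankoff_tree_length(poly, mm))
    }
  }
})

test_that("binary-tree lengths also agree with an independent Fitch implementation", {
  fx <- fixture_cached()
  cells <- fx$matrix$cells
  cells[cells == "-"] <- "?"
  pd <- phangorn::phyDat(cells, type = "USER",
                         levels = as.character(0:9), ambiguity = "?")
  set.seed(31)
  for (i in 1:5) {
    tr <- wagner_build(fx$matrix, seed = i)
    expect_equal(tree_length(tr, fx$matrix),
                 phangorn::parsimony(tr, pd, method = "fitch"))
  }
})

test_that("step bounds follow their closed forms and bracket every tree", {
  m <- char_matrix(cbind(c(rep("0", 5), rep("1", 5))), taxa = paste0("t", 1:10))
  b <- step_bounds(m)
  expect_equal(b$m, 1); expect_equal(b$g, 5)
  m1 <- char_matrix(cbind(c("2", rep("?", 5))), taxa = paste0("t", 1:6))
  expect_equal(step_bounds(m1)$m, 0)
  expect_equal(step_bounds(m1)$g, 0)
  m0 <- char_matrix(cbind(rep("?", 6)), taxa = paste0("t", 1:6))
  expect_equal(step_bounds(m0)$m, 0L)
  expect_equal(step_bounds(m0)$g, 0L)
  # min and max of s over all trees equal m and g (6-taxon exhaustion)
  set.seed(41)
  tops <- all_topologies(paste0("t", 1:6))
  for (i in 1:5) {
    mm <- random_small_matrix(6, 3, 3, missing_p = 0.1)
    b <- step_bounds(mm)
    s_all <- vapply(tops, function(tp) character_length(tp, mm), integer(n_chars(mm)))
    expect_equal(unname(apply(s_all, 1, min)), b$m)
    expect_equal(unname(apply(s_all, 1, max)), b$g)
  }
})

test_that("length is invariant under re-rooting and leaf permutation", {
  set.seed(47)
  mm <- random_small_matrix(8, 6, 3, missing_p = 0.1)
  tr <- random_tree(8)
  L <- tree_length(tr, mm)
  for (leaf in sample(tr$tip.label, 3))
    expect_equal(tree_length(root_display(tr, leaf), mm), L)
  perm <- sample(seq_len(8))
  mm2 <- char_matrix(mm$cells[perm, ], taxa = mm$taxa[perm])
  expect_equal(tree_length(tr, mm2), L)
})

test_that("index reports: clean data give CI = RI = 1; conventions recorded", {
  sim <- two_signal_matrix(8, 6, 0, seed = 5)
  ir <- index_report(sim$true_tree, sim$matrix)
  e <- ir$ensemble
  expect_equal(e$CI[e$convention == "all"], 1)
  expect_equal(e$RI[e$convention == "all"], 1)
  expect_true(all(c("all", "informative") %in% e$convention))
  # per-character undefined cases are NA, not inflated
  m <- char_matrix(cbind(rep("0", 5), c("1", rep("0", 4))), taxa = paste0("t", 1:5))
  ir2 <- index_report(random_tree(5, seed = 2, labels = paste0("t", 1:5)), m)
  expect_true(is.na(ir2$per_character$ci[1]))   # constant: s = 0
  expect_true(is.na(ir2$per_character$ri[2]))   # autapomorphy: g = m
})

test_that("consensus scoring is polytomy-general: L(consensus) >= L(MPT)", {
  set.seed(53)
  for (i in 1:5) {
    sim <- simulate_matrix(n_taxa = 10, n_chars = 12, change_rate = 3, seed = i)
    res <- heuristic_search(sim$matrix, n_replicates = 3, seed = i)
    cons <- strict_consensus(res$trees)
    expect_gte(tree_length(cons, sim$matrix), res$best_length)
  }
})

test_that("reconstruction flags unambiguous changes exactly", {
  # single derived leaf: one forced change on its pendant branch
  m <- char_matrix(cbind(c("1", rep("0", 4))), taxa = paste0("t", 1:5))
  tr <- parse_newick("((t1,t2),(t3,(t4,t5)));")
  rec <- reconstruct(tr, m, 1, root_taxon = "t5")
  forced <- rec$changes[rec$changes$forced, ]
  expect_equal(nrow(forced), 1)
  expect_equal(rec$tree$tip.label[forced$child], "t1")
  expect_equal(forced$derived_state, 1L)
  # sister pair sharing a derived state: one change on the stem
  m2 <- char_matrix(cbind(c("1", "1", rep("0", 3))), taxa = paste0("t", 1:5))
  rec2 <- reconstruct(tr, m2, 1, root_taxon = "t5")
  forced2 <- rec2$changes[rec2$changes$forced, ]
  expect_equal(nrow(forced2), 1)
  expect_true(forced2$child > 5)  # internal stem branch
  expect_equal(forced2$derived_state, 1L)
})

test_that("forced/derived flags match brute-force MPR enumeration", {
  set.seed(59)
  for (i in 1:30) {
    n <- sample(5:7, 1)
    ns <- sample(2:3, 1)
    tip_states <- sample(0:(ns - 1), n, TRUE)
    if (length(unique(tip_states)) == 1) next
    m <- char_matrix(cbind(as.character(tip_states)), taxa = paste0("t", 1:n))
    tr <- root_display(random_tree(n), "t1")
    rec <- reconstruct(tr, m, 1, root_taxon = "t1")
    states_in_tree_order <- tip_states[match(rec$tree$tip.label, paste0("t", 1:n))]
    oracle <- enumerate_mprs(rec$tree, states_in_tree_order, ns)
    expect_equal(rec$s, oracle$s)
    for (e in seq_len(nrow(rec$tree$edge))) {
      expect_equal(rec$changes$forced[e], oracle$per_edge[[e]]$forced,
                   label = sprintf("edge %d forced (case %d)", e, i))
      if (oracle$per_edge[[e]]$forced)
        expect_equal(sort(rec$changes$derived[[e]]), oracle$per_edge[[e]]$derived)
    }
  }
})
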