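test_that("single-MPT mapping equals that tree's unambiguous changes", {
  sim <- two_signal_matrix(8, 7, 0, seed = 17)
  res <- heuristic_search(sim$matrix, n_replicates = 4, seed = 1)
  cons <- strict_consensus(res$trees)
  root <- sim$matrix$taxa[1]
  sm <- common_synapomorphies(cons, res$trees, sim$matrix, root)
  if (length(res$trees) == 1) {
    direct <- morphoclad:::unambiguous_changes(res$trees[[1]], sim$matrix, root)
    expect_setequal(paste(sm$map$split, sm$map$character, sm$map$derived_state),
                    paste(direct$split, direct$character, direct$derived_state))
  }
  expect_error(common_synapomorphies(res$trees[[1]], list(res$trees[[1]],
                                                          random_tree(8, labels = sim$matrix$taxa)),
                                     sim$matrix, root),
               "not the strict consensus")
})

test_that("a clean clade character maps on the clade stem as unique", {
  tr <- parse_newick("((a,b),((c,d),(e,f)));")
  # char 1: derived state shared by the c,d clade; char 2: constant noise
  cells <- cbind(c("0", "0", "1", "1", "0", "0"), rep("0", 6),
                 c("0", "1", "0", "1", "0", "1"))
  m <- char_matrix(cells, taxa = letters[1:6])
  sm <- common_synapomorphies(tr, list(tr), m, "a")
  row <- sm$map[sm$map$character == 1, ]
  expect_equal(nrow(row), 1)
  expect_equal(row$split, "c|d")
  expect_equal(row$derived_state, 1L)
  expect_true(row$unique)
})

test_that("every mapped transformation is realized in each tree's MPR set", {
  set.seed(97)
  for (i in 1:10) {
    sim <- simulate_matrix(n_taxa = 7, n_chars = 10, change_rate = 1.5, seed = i,
                           missing_fraction = 0, inapplicable_fraction = 0)
    res <- heuristic_search(sim$matrix, n_replicates = 3, seed = i)
    cons <- strict_consensus(res$trees)
    root <- sim$matrix$taxa[1]
    sm <- common_synapomorphies(cons, res$trees, sim$matrix, root)
    if (nrow(sm$map) == 0) next
    for (tr in res$trees) {
      rooted <- root_display(tr, root)
      for (r in seq_len(nrow(sm$map))) {
        ch <- sm$map$character[r]
        col <- sim$matrix$cells[match(rooted$tip.label, sim$matrix$taxa), ch]
        if (any(!col %in% as.character(0:9))) next
        ns <- max(as.integer(col)) + 1
        oracle <- enumerate_mprs(rooted, as.integer(col), max(2, ns))
        # find the matching branch by split key
        keys <- vapply(seq_len(nrow(rooted$edge)), function(e) {
          v <- rooted$edge[e, 2]
          if (v <= 7) rooted$tip.label[v]
          else morphoclad:::node_split_key(rooted, v) %||% NA_character_
        }, "")
        e <- which(keys == sm$map$split[r])
        expect_equal(length(e), 1)
        expect_true(oracle$per_edge[[e]]$forced)
        expect_equal(oracle$per_edge[[e]]$derived, sm$map$derived_state[r])
      }
    }
  }
})

test_that("unique transformations have ci = ri = 1 on the consensus", {
  res <- fixture_search_cached()
  fx <- fixture_cached()
  cons <- strict_consensus(res$trees)
  sm <- common_synapomorphies(cons, res$trees, fx$matrix, "Uloma_mexicana")
  ir <- index_report(res$trees, fx$matrix, tree = cons)
  uq <- unique(sm$map$character[sm$map$unique])
  expect_gt(length(uq), 0)
  expect_true(all(ir$per_character$ci[uq] == 1))
  expect_true(all(ir$per_character$ri[uq] == 1, na.rm = TRUE))
})

test_that("reports regenerate byte-identically and tolerate missing support", {
  sim <- two_signal_matrix(8, 7, 0, seed = 29)
  res <- heuristic_search(sim$matrix, n_replicates = 4, seed = 1)
  cons <- strict_consensus(res$trees)
  root <- sim$matrix$taxa[1]
  ir <- index_report(res$trees, sim$matrix, tree = cons)
  sm <- common_synapomorphies(cons, res$trees, sim$matrix, root)
  r1 <- render_report(res, cons, ir, sm, support = NULL, root_taxon = root)
  r2 <- render_report(res, cons, ir, sm, support = NULL, root_taxon = root)
  expect_identical(r1, r2)
  expect_false(any(grepl("support", strsplit(r1[grep("branch", r1)[1]], "\t")[[1]][2])))
  bs <- bootstrap_support(sim$matrix, n_replicates = 30, seed = 1, reference = cons)
  r3 <- render_report(res, cons, ir, sm, support = bs, root_taxon = root)
  expect_true(any(grepl("support", r3)))
})
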