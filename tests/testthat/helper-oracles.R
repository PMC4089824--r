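# Independent oracles used across the suite.  These deliberately avoid the
# package's C engine: lengths come from a plain-R uniform-cost Sankoff dynamic
# program, and ambiguity flags from brute-force enumeration of all internal
# labelings on small trees.

# uniform-cost Sankoff length of one character on a rooted tree.
# states_list: per-tip integer vector of allowed states (0-based).
sankoff_length <- function(tree, states_list, n_states) {
  edge <- tree$edge
  nt <- length(tree$tip.label)
  kids <- split(edge[, 2], edge[, 1])
  rec <- function(v) {
    if (v <= nt) {
      c0 <- rep(1e9, n_states)
      c0[states_list[[v]] + 1] <- 0
      return(c0)
    }
    tot <- rep(0, n_states)
    for (k in kids[[as.character(v)]]) {
      ck <- rec(k)
      tot <- tot + pmin(ck, min(ck) + 1)
    }
    tot
  }
  root <- setdiff(edge[, 1], edge[, 2])[1]
  min(rec(root))
}

# Sankoff length for a whole char_matrix on a tree (sum over columns),
# honoring the package's missing/inapplicable convention.
sankoff_tree_length <- function(tree, x) {
  nt <- n_taxa(x)
  perm <- match(tree$tip.label, x$taxa)
  total <- 0
  for (j in seq_len(n_chars(x))) {
    col <- x$cells[perm, j]
    obs <- sort(unique(as.integer(col[col %in% as.character(0:9)])))
    if (length(obs) == 0) next
    ns <- max(obs) + 1
    states_list <- lapply(col, function(cc)
      if (cc %in% as.character(0:9)) as.integer(cc) else obs)
    total <- total + sankoff_length(tree, states_list, ns)
  }
  total
}

# Brute-force: enumerate every internal-node labeling of a rooted tree for a
# fully scored character; returns per-edge summaries over the minimal set.
enumerate_mprs <- function(tree, tip_states, n_states) {
  edge <- tree$edge
  nt <- length(tree$tip.label)
  internal <- sort(unique(as.vector(edge)))
  internal <- internal[internal > nt]
  grid <- as.matrix(expand.grid(rep(list(0:(n_states - 1)), length(internal))))
  state_of <- function(assign, v) if (v <= nt) tip_states[v] else assign[match(v, internal)]
  costs <- apply(grid, 1, function(a)
    sum(vapply(seq_len(nrow(edge)), function(i)
      state_of(a, edge[i, 1]) != state_of(a, edge[i, 2]), TRUE)))
  best <- min(costs)
  mins <- grid[costs == best, , drop = FALSE]
  per_edge <- lapply(seq_len(nrow(edge)), function(i) {
    ps <- apply(mins, 1, state_of, v = edge[i, 1])
    cs <- apply(mins, 1, state_of, v = edge[i, 2])
    changed <- ps != cs
    list(forced = all(changed),
         derived = sort(unique(cs[changed])),
         zero_possible = any(!changed))
  })
  list(s = best, per_edge = per_edge)
}

# random fully-scored test matrix (no masking) as a char_matrix
random_small_matrix <- function(n_taxa, n_chars, n_states, missing_p = 0) {
  cells <- matrix(as.character(sample(0:(n_states - 1), n_taxa * n_chars, TRUE)),
                  n_taxa, n_chars)
  if (missing_p > 0) {
    hit <- runif(length(cells)) < missing_p
    cells[hit] <- sample(c("?", "-"), sum(hit), TRUE)
  }
  char_matrix(cells, taxa = paste0("t", seq_len(n_taxa)))
}

# all unrooted binary topologies over n labelled leaves (as phylo list),
# generated by stepwise insertion; used for small-n identities
all_topologies <- function(labels) {
  n <- length(labels)
  mat <- char_matrix(matrix("0", n, 1), taxa = labels)
  # a constant matrix makes every topology optimal, so the exhaustive
  # search enumerates and returns them all
  exhaustive_search(mat, keep_max = 1e6)$trees
}

expect_same_topology <- function(a, b) {
  testthat::expect_true(trees_equal(a, b))
}

fixture_cached <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- load_helopini_fixture()
    fx
  }
})

# one shared modest-effort search on the fixture for non-acceptance tests
fixture_search_cached <- local({
  res <- NULL
  function() {
    if (is.null(res))
      res <<- heuristic_search(fixture_cached()$matrix, n_replicates = 12,
                               hold = 20, max_trees = 10000, seed = 42)
    res
  }
})
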