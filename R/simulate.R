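#' Random unrooted binary tree
#'
#' Uniform over unrooted binary topologies: leaves are attached one at a
#' time on an edge drawn uniformly at random (sequential addition), which
#' yields every topology with probability `1 / (2n-5)!!`.
#'
#' @param n_taxa number of leaves (>= 4).
#' @param seed RNG seed.
#' @param labels optional leaf labels (default `t1`, `t2`, ...).
#' @return an unrooted binary [ape::phylo].
#' @export
random_tree <- function(n_taxa, seed = NULL, labels = NULL) {
  if (n_taxa < 4) stop("need at least 4 taxa")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) labels <- paste0("t", seq_len(n_taxa))
  stopifnot(length(labels) == n_taxa, !anyDuplicated(labels))
  # edges as two-column matrix over ids: tips 1..n, internals n+1..2n-2
  n <- n_taxa
  edges <- rbind(c(n + 1, 1), c(n + 1, 2), c(n + 1, 3))
  next_int <- n + 2
  for (k in 4:n) {
    e <- sample.int(nrow(edges), 1)
    a <- edges[e, 1]; b <- edges[e, 2]
    edges <- edges[-e, , drop = FALSE]
    edges <- rbind(edges, c(a, next_int), c(next_int, b), c(next_int, k))
    next_int <- next_int + 1
  }
  # orient from the basal node
  tr <- edge_to_phylo(orient_edges(edges, n), labels)
  tr
}

# orient an arbitrary undirected edge list into an ape parent->child
# matrix rooted at the internal node adjacent to tip 1
orient_edges <- function(edges, n_tip) {
  adj <- list()
  add <- function(a, b) adj[[as.character(a)]] <<- c(adj[[as.character(a)]], b)
  for (i in seq_len(nrow(edges))) { add(edges[i, 1], edges[i, 2]); add(edges[i, 2], edges[i, 1]) }
  root <- adj[["1"]][1]
  out <- matrix(0L, nrow(edges), 2)
  seen <- c(root)
  stack <- list(c(NA, root))
  row <- 0
  # renumber internals in preorder as ape expects
  remap <- setNames(seq_len(n_tip), as.character(seq_len(n_tip)))
  next_id <- n_tip + 1
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    par <- cur[1]; v <- cur[2]
    if (v > n_tip) { remap[as.character(v)] <- next_id; next_id <- next_id + 1 }
    if (!is.na(par)) {
      row <- row + 1
      out[row, ] <- c(remap[as.character(par)], remap[as.character(v)])
    }
    nb <- adj[[as.character(v)]]
    for (u in rev(setdiff(nb, seen))) {
      seen <- c(seen, u)
      stack[[length(stack) + 1]] <- c(v, u)
    }
  }
  out
}

#' Simulate discrete characters on a known tree
#'
#' Characters evolve by explicit change placement rather than a
#' continuous-time model: each character receives a Poisson
#' (`change_rate`) number of state changes on branches drawn uniformly,
#' the new state being drawn uniformly among the other states.  This
#' gives direct control of homoplasy and exact bookkeeping of the true
#' history.  Cells are then masked to missing / inapplicable at the
#' requested rates (inapplicable masking is random, since the engine
#' treats `-` exactly like `?`).
#'
#' Defaults mirror the scale of the packaged Helopini study matrix
#' (33 taxa, 67 characters, up to 4 states, ~1% missing, ~3%
#' inapplicable).
#'
#' @param n_taxa,n_chars matrix dimensions.
#' @param n_states number of states (2-4).
#' @param change_rate expected changes per character (homoplasy dial).
#' @param missing_fraction,inapplicable_fraction masking proportions.
#' @param seed RNG seed.
#' @param tree optional fixed generating tree (default: random).
#' @return an object of class `simulated_dataset`: list with `matrix`
#'   (a [char_matrix]), `true_tree`, `true_changes` (data.frame:
#'   `character`, `edge`, `from`, `to`), `realized_homoplasy` (logical
#'   per character: leaf pattern needs more steps than its minimum).
#' @examples
#' sim <- simulate_matrix(n_taxa = 8, n_chars = 30, change_rate = 1, seed = 1)
#' tree_length(sim$true_tree, sim$matrix)
#' @export
simulate_matrix <- function(n_taxa = 33, n_chars = 67, n_states = 3,
                            change_rate = 2, missing_fraction = 0.01,
                            inapplicable_fraction = 0.03, seed = NULL,
                            tree = NULL) {
  stopifnot(n_states >= 2, n_states <= 10, n_taxa >= 4,
            missing_fraction + inapplicable_fraction < 1, change_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tree)) tree <- random_tree(n_taxa, labels = paste0("t", seq_len(n_taxa)))
  labels <- tree$tip.label
  stopifnot(length(labels) == n_taxa)
  edge <- tree$edge
  n_edge <- nrow(edge)
  root <- setdiff(edge[, 1], edge[, 2])[1]
  # preorder edge sequence for state propagation
  pre <- order_edges_preorder(edge, root)
  cells <- matrix("", n_taxa, n_chars)
  changes <- list()
  homo <- logical(n_chars)
  for (ch in seq_len(n_chars)) {
    k <- rpois(1, change_rate)
    on_edge <- if (k > 0) sample.int(n_edge, k, replace = TRUE) else integer(0)
    state <- integer(max(edge))
    state[root] <- sample.int(n_states, 1) - 1L
    rec <- list()
    for (i in pre) {
      p <- edge[i, 1]; v <- edge[i, 2]
      s <- state[p]
      for (hit in seq_len(sum(on_edge == i))) {
        new <- sample(setdiff(0:(n_states - 1), s), 1)
        rec[[length(rec) + 1]] <- data.frame(character = ch, edge = i,
                                             from = s, to = new)
        s <- new
      }
      state[v] <- s
    }
    cells[, ch] <- as.character(state[seq_len(n_taxa)])
    changes <- c(changes, rec)
  }
  mat_clean <- char_matrix(cells, taxa = labels)
  s_true <- character_length(tree, mat_clean)
  b <- step_bounds(mat_clean)
  homo <- s_true > b$m
  # masking
  n_cells <- n_taxa * n_chars
  idx <- sample.int(n_cells, round((missing_fraction + inapplicable_fraction) * n_cells))
  n_miss <- round(missing_fraction * n_cells)
  cells[idx[seq_len(min(n_miss, length(idx)))]] <- "?"
  if (length(idx) > n_miss) cells[idx[(n_miss + 1):length(idx)]] <- "-"
  structure(list(matrix = char_matrix(cells, taxa = labels), true_tree = tree,
                 true_changes = if (length(changes)) do.call(rbind, changes)
                                else data.frame(character = integer(0), edge = integer(0),
                                                from = integer(0), to = integer(0)),
                 realized_homoplasy = homo),
            class = "simulated_dataset")
}

order_edges_preorder <- function(edge, root) {
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  out <- integer(0)
  stack <- kids[[as.character(root)]]
  while (length(stack)) {
    i <- stack[1]; stack <- stack[-1]
    out <- c(out, i)
    v <- edge[i, 2]
    k <- kids[[as.character(v)]]
    if (!is.null(k)) stack <- c(k, stack)
  }
  out
}

#' Two-signal matrix for conflict experiments
#'
#' Builds a matrix whose characters split into a majority block of clean
#' binary synapomorphies consistent with tree A and a minority block
#' consistent with a conflicting tree B (a label-reshuffled copy of A).
#' Used to validate the character-removal analysis: removing a conflict
#' character should improve consensus resolution.
#'
#' @param n_taxa leaves.
#' @param n_main,n_conflict character counts (`n_main > n_conflict >= 0`).
#' @param seed RNG seed.
#' @return a `simulated_dataset` (with `conflict_characters` attribute
#'   and `tree_b` component; `true_tree` is tree A).
#' @export
two_signal_matrix <- function(n_taxa, n_main, n_conflict, seed = NULL) {
  stopifnot(n_main > n_conflict, n_conflict >= 0)
  if (!is.null(seed)) set.seed(seed)
  tree_a <- random_tree(n_taxa)
  labels <- tree_a$tip.label
  tree_b <- tree_a
  tree_b$tip.label <- sample(labels)
  clade_chars <- function(tree, n) {
    bp <- bipartitions(tree)
    vapply(seq_len(n), function(i) {
      side <- bp[[sample.int(length(bp), 1)]]
      as.character(as.integer(labels %in% side))
    }, character(n_taxa))
  }
  cells <- cbind(clade_chars(tree_a, n_main),
                 if (n_conflict > 0) clade_chars(tree_b, n_conflict))
  structure(list(matrix = char_matrix(cells, taxa = labels),
                 true_tree = tree_a, tree_b = tree_b,
                 conflict_characters = if (n_conflict > 0)
                   (n_main + 1):(n_main + n_conflict) else integer(0)),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d taxa x %d characters\n",
              n_taxa(x$matrix), n_chars(x$matrix)))
  if (!is.null(x$realized_homoplasy))
    cat(sprintf("  %d characters with realized homoplasy\n",
                sum(x$realized_homoplasy)))
  invisible(x)
}
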