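#' Wagner tree by stepwise addition
#'
#' Builds a starting tree by adding taxa one at a time at the branch
#' that minimises total parsimony length; ties keep the first branch in
#' a deterministic traversal, so a given addition order always yields
#' the same tree.
#'
#' @param x a [char_matrix] with at least 4 taxa.
#' @param order optional addition order: a permutation of taxon labels
#'   or of indices.  Default: random, drawn after `set.seed(seed)`.
#' @param seed RNG seed for the default random order.
#' @param weights optional integer character weights.
#' @return an unrooted binary [ape::phylo].
#' @export
wagner_build <- function(x, order = NULL, seed = NULL, weights = NULL) {
  if (n_taxa(x) < 4) stop("need at least 4 taxa")
  if (is.null(order)) {
    if (!is.null(seed)) set.seed(seed)
    order <- sample.int(n_taxa(x))
  } else if (is.character(order)) {
    order <- match(order, x$taxa)
    if (anyNA(order)) stop("unknown taxon in addition order")
  }
  stopifnot(setequal(order, seq_len(n_taxa(x))))
  pd <- pars_data(x, weights)
  edge <- c_wagner(pd$masks, pd$weights, as.integer(order) - 1L, pd$n_states)
  edge_to_phylo(edge, x$taxa)
}

edge_to_phylo <- function(edge, labels) {
  nt <- length(labels)
  tr <- structure(list(edge = edge, tip.label = labels,
                       Nnode = max(edge) - nt), class = "phylo")
  attr(tr, "order") <- NULL
  tr
}

#' TBR branch swapping from one starting tree
#'
#' Explores all tree bisections and reconnection pairs; strictly shorter
#' neighbours are accepted immediately (and the sweep restarts from
#' them); when no neighbour improves, equal-length distinct topologies
#' are collected up to `hold` and swapped in turn until closure.
#' Neighbour evaluation order is deterministic, so results are
#' replayable.
#'
#' @param tree binary unrooted starting tree.
#' @param x a [char_matrix].
#' @param hold maximum number of equal-length trees retained.
#' @param weights optional integer character weights.
#' @return list with `best_length`, `trees` (list of [ape::phylo]),
#'   `hit_hold` (flag: equal-length trees were discarded).
#' @export
tbr_swap <- function(tree, x, hold = 20, weights = NULL) {
  pd <- pars_data(x, weights)
  res <- c_tbr_search(list(tree_edge_for(tree, x$taxa)), n_taxa(x), pd$masks,
                      pd$weights, as.integer(hold), pd$n_states, 1e7)
  list(best_length = res$best_length,
       trees = lapply(res$trees, edge_to_phylo, labels = x$taxa),
       hit_hold = res$hit_cap)
}

#' Heuristic maximum-parsimony search
#'
#' The classic NONA-style strategy: `n_replicates` independent
#' random-addition Wagner trees, each TBR-swapped holding up to
#' `hold` equal-length trees, best trees pooled, then (optionally) a
#' final TBR sweep to completion over the pooled trees capped at
#' `max_trees`.  Ambiguously supported branches - branches on which no
#' character change is forced in every most-parsimonious reconstruction
#' - are then collapsed and duplicate topologies removed.
#'
#' Replicate `i` derives its addition order from a seeded RNG stream, so
#' the same `seed` reproduces the identical result, including the
#' replicate log.
#'
#' @param x a [char_matrix].
#' @param n_replicates number of random-addition replicates.
#' @param hold equal-length trees held per replicate.
#' @param max_trees cap on trees retained in the final sweep.
#' @param seed RNG seed.
#' @param collapse `"ambiguous"` (default) or `"none"`.
#' @param final_sweep swap the pooled best trees to completion.
#' @param weights optional integer character weights.
#' @param verbose print per-replicate progress.
#' @return an object of class `mp_search`: list with `best_length`,
#'   `trees` (collapsed, deduplicated most parsimonious trees),
#'   `binary_trees` (the uncollapsed pool), `replicate_log`
#'   (data.frame), `hit_max_trees`, `config`.
#' @examples
#' fx <- load_helopini_fixture()
#' res <- heuristic_search(fx$matrix, n_replicates = 5, seed = 1)
#' res$best_length
#' @export
heuristic_search <- function(x, n_replicates = 1000, hold = 20, max_trees = 10000,
                             seed = NULL, collapse = c("ambiguous", "none"),
                             final_sweep = TRUE, weights = NULL, verbose = FALSE) {
  collapse <- match.arg(collapse)
  stopifnot(n_replicates >= 1, hold >= 1, max_trees >= hold)
  if (!is.null(seed)) set.seed(seed)
  nt <- n_taxa(x)
  pd <- pars_data(x, weights)
  orders <- lapply(seq_len(n_replicates), function(i) sample.int(nt))

  best <- Inf
  pool <- list()
  log <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    w_edge <- c_wagner(pd$masks, pd$weights, as.integer(orders[[i]]) - 1L, pd$n_states)
    res <- c_tbr_search(list(w_edge), nt, pd$masks, pd$weights,
                        as.integer(hold), pd$n_states, 1e7)
    log[[i]] <- data.frame(replicate = i, best_length = res$best_length,
                           n_trees = length(res$trees))
    if (res$best_length < best - 1e-9) {
      best <- res$best_length
      pool <- res$trees
    } else if (res$best_length < best + 1e-9) {
      pool <- c(pool, res$trees)
    }
    if (verbose && i %% 20 == 0)
      message(sprintf("replicate %d/%d: best %g", i, n_replicates, best))
  }
  hit_cap <- FALSE
  if (final_sweep) {
    fin <- c_tbr_search(pool, nt, pd$masks, pd$weights,
                        as.integer(max_trees), pd$n_states, 1e7)
    best <- fin$best_length
    pool <- fin$trees
    hit_cap <- fin$hit_cap
  }
  binary <- dedup_trees(lapply(pool, edge_to_phylo, labels = x$taxa))
  trees <- binary
  if (collapse == "ambiguous")
    trees <- dedup_trees(lapply(binary, collapse_ambiguous, x = x))
  structure(list(best_length = best, trees = trees, binary_trees = binary,
                 replicate_log = do.call(rbind, log), hit_max_trees = hit_cap,
                 config = list(n_replicates = n_replicates, hold = hold,
                               max_trees = max_trees, seed = seed,
                               collapse = collapse, final_sweep = final_sweep)),
            class = "mp_search")
}

#' @export
print.mp_search <- function(x, ...) {
  cat(sprintf("Heuristic parsimony search: best length %g\n", x$best_length))
  cat(sprintf("  %d distinct tree%s after '%s' collapsing (%d binary trees pooled)\n",
              length(x$trees), if (length(x$trees) > 1) "s" else "",
              x$config$collapse, length(x$binary_trees)))
  cat(sprintf("  %d replicates (hold %d, max_trees %d%s)\n",
              x$config$n_replicates, x$config$hold, x$config$max_trees,
              if (x$hit_max_trees) ", tree cap hit" else ""))
  invisible(x)
}

#' Collapse ambiguously supported branches
#'
#' Removes every internal branch whose minimum length over all
#' most-parsimonious reconstructions is zero, i.e. on which no character
#' unambiguously changes (the NONA "amb-" rule).  Idempotent.
#'
#' @param tree an [ape::phylo].
#' @param x a [char_matrix].
#' @return a possibly multifurcating [ape::phylo].
#' @export
collapse_ambiguous <- function(tree, x) {
  pd <- pars_data(x)
  edge <- tree_edge_for(tree, x$taxa)
  ea <- c_edge_analysis(edge, n_taxa(x), pd$masks, pd$n_states)
  forced_any <- rowSums(ea$forced) > 0
  internal <- tree$edge[, 2] > n_taxa(x)
  collapse_tree_edges(tree, which(internal & !forced_any))
}

#' Exhaustive search over all unrooted binary topologies
#'
#' Enumerates every topology by stepwise leaf insertion (3 x 5 x ... x
#' (2n-5) trees) and returns all optimal trees.  Intended as a small-n
#' oracle; refuses more than 10 taxa.
#'
#' @param x a [char_matrix] with 4-10 taxa.
#' @param keep_max cap on the number of optimal trees returned.
#' @param weights optional integer character weights.
#' @return list with `best_length`, `trees`, `n_topologies`.
#' @export
exhaustive_search <- function(x, keep_max = 1000, weights = NULL) {
  if (n_taxa(x) > 10) stop("exhaustive search supports at most 10 taxa")
  pd <- pars_data(x, weights)
  res <- c_exhaustive(pd$masks, pd$weights, pd$n_states, as.integer(keep_max))
  list(best_length = res$best_length,
       trees = lapply(res$trees, edge_to_phylo, labels = x$taxa),
       n_topologies = res$n_topologies)
}
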