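#' Strict and majority-rule consensus
#'
#' `strict_consensus` retains exactly the bipartitions present in every
#' input tree; `majority_consensus` retains those occurring in more than
#' `cutoff` percent of the trees (compatible by pigeonhole for
#' `cutoff >= 50`).
#'
#' @param trees a non-empty list (or `multiPhylo`) of trees over the
#'   same leaf set.
#' @return an [ape::phylo], in general multifurcating.
#' @export
strict_consensus <- function(trees) {
  trees <- as_tree_list(trees)
  keysets <- lapply(trees, bipartitions)
  common <- Reduce(intersect, lapply(keysets, names))
  build_from_splits(trees[[1]]$tip.label, keysets[[1]][common])
}

#' @rdname strict_consensus
#' @param cutoff percentage in `[50, 100]`; a split is kept when its
#'   frequency strictly exceeds it.
#' @export
majority_consensus <- function(trees, cutoff = 50) {
  trees <- as_tree_list(trees)
  if (cutoff < 50 || cutoff > 100) stop("cutoff must be in [50, 100]")
  keysets <- lapply(trees, bipartitions)
  tab <- table(unlist(lapply(keysets, names)))
  keep <- names(tab)[100 * tab / length(trees) > cutoff]
  splits <- list()
  for (k in keep) for (ks in keysets) if (k %in% names(ks)) { splits[[k]] <- ks[[k]]; break }
  build_from_splits(trees[[1]]$tip.label, splits)
}

as_tree_list <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) == 0) stop("need at least one tree")
  labs <- trees[[1]]$tip.label
  for (t in trees)
    if (!setequal(t$tip.label, labs)) stop("trees have different leaf sets")
  trees
}

# Build a (multifurcating) unrooted tree from pairwise-compatible splits.
# Splits are clades relative to a reference leaf (the side excluding the
# alphabetically smallest label); containment nesting gives the topology.
build_from_splits <- function(labels, splits) {
  ref <- sort(labels)[1]
  splits <- lapply(splits, function(s) setdiff(s, character(0)))
  splits <- splits[order(-lengths(splits))]
  n <- length(splits)
  newick_of <- function(members, idx) {
    # idx: indices of splits fully inside `members` not yet consumed
    parts <- character(0)
    left <- members
    while (length(idx) > 0) {
      top <- idx[1]
      idx <- idx[-1]
      if (!all(splits[[top]] %in% left)) next
      sub <- idx[vapply(idx, function(j) all(splits[[j]] %in% splits[[top]]), TRUE)]
      parts <- c(parts, newick_of(splits[[top]], sub))
      left <- setdiff(left, splits[[top]])
      idx <- setdiff(idx, sub)
    }
    parts <- c(parts, sort(left))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  inner <- setdiff(labels, ref)
  txt <- paste0("(", ref, ",", newick_of(inner, seq_len(n)), ");")
  tr <- ape::read.tree(text = txt)
  tr <- ape::collapse.singles(tr)
  if (ape::is.rooted(tr) && length(labels) > 2) tr <- ape::unroot(tr)
  tr
}

#' Nonparametric bootstrap clade support
#'
#' Each replicate resamples the characters with replacement (kept as
#' integer column weights), runs a reduced heuristic search, and votes
#' once per bipartition of the replicate's strict consensus of
#' equally-best trees (`vote = "consensus"`, the default, prevents a
#' replicate with many ties from over-voting) or once per bipartition
#' averaged over the replicate's trees (`vote = "per_tree"`).
#' Frequencies at or above `threshold` are attached to the reference
#' tree's matching branches.
#'
#' @param x a [char_matrix].
#' @param n_replicates bootstrap replicates.
#' @param inner_replicates,hold,max_trees effort of the per-replicate
#'   search.  The classic protocol for matrices of this size used 100
#'   random-addition replicates holding 20 trees (cap 1000); a few
#'   replicates per resample recover the same support structure at a
#'   small fraction of the cost, and too-weak settings (a single
#'   replicate) are known to inflate apparent support - see the methods
#'   vignette.
#' @param seed RNG seed.
#' @param threshold report percentage threshold.
#' @param vote `"consensus"` or `"per_tree"`.
#' @param inner_final_sweep run the pooled final TBR sweep inside each
#'   replicate (slower, marginally more thorough).
#' @param reference tree on which supported splits are annotated;
#'   default: strict consensus of a full-effort search is *not* run -
#'   the majority-rule consensus of the bootstrap splits is used.
#' @return an object of class `support_report`: list with
#'   `frequencies` (data.frame `split`, `freq`), `annotated_tree`
#'   (reference with `node.label` percentages where `freq >= threshold`),
#'   `n_effective` (replicates that completed), `config`.
#' @export
bootstrap_support <- function(x, n_replicates = 1000, inner_replicates = 3,
                              hold = 10, max_trees = 50, seed = NULL,
                              threshold = 50, vote = c("consensus", "per_tree"),
                              reference = NULL, inner_final_sweep = FALSE) {
  vote <- match.arg(vote)
  stopifnot(n_replicates >= 1, threshold >= 0, threshold <= 100)
  if (!is.null(seed)) set.seed(seed)
  nc <- n_chars(x)
  counts <- list()
  n_ok <- 0
  for (r in seq_len(n_replicates)) {
    w <- tabulate(sample.int(nc, nc, replace = TRUE), nbins = nc)
    res <- try(heuristic_search(x, n_replicates = inner_replicates, hold = hold,
                                max_trees = max_trees, collapse = "none",
                                final_sweep = inner_final_sweep, weights = w),
               silent = TRUE)
    if (inherits(res, "try-error")) next
    n_ok <- n_ok + 1
    if (vote == "consensus") {
      ks <- names(bipartitions(strict_consensus(res$trees)))
      for (k in ks) counts[[k]] <- (counts[[k]] %||% 0) + 1
    } else {
      tally <- table(unlist(lapply(res$trees, split_keys)))
      for (k in names(tally))
        counts[[k]] <- (counts[[k]] %||% 0) + tally[[k]] / length(res$trees)
    }
  }
  if (n_ok == 0) stop("all bootstrap replicates failed")
  freq <- data.frame(split = names(counts),
                     freq = 100 * unlist(counts, use.names = FALSE) / n_ok)
  freq <- freq[order(-freq$freq), , drop = FALSE]
  rownames(freq) <- NULL
  if (is.null(reference)) {
    splits <- lapply(strsplit(freq$split[freq$freq > 50], "\\|"), identity)
    names(splits) <- freq$split[freq$freq > 50]
    reference <- build_from_splits(x$taxa, splits)
  }
  annotated <- annotate_support(reference, freq, threshold)
  structure(list(frequencies = freq, annotated_tree = annotated,
                 n_effective = n_ok,
                 config = list(n_replicates = n_replicates,
                               inner_replicates = inner_replicates, hold = hold,
                               max_trees = max_trees, seed = seed,
                               threshold = threshold, vote = vote)),
            class = "support_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

annotate_support <- function(tree, freq, threshold) {
  nt <- length(tree$tip.label)
  labs <- rep("", tree$Nnode)
  bp <- bipartitions(tree)
  edge <- tree$edge
  # recompute child clade key per internal node
  for (i in which(edge[, 2] > nt)) {
    key <- node_split_key(tree, edge[i, 2])
    if (!is.null(key) && key %in% freq$split) {
      f <- freq$freq[freq$split == key]
      if (f >= threshold) labs[edge[i, 2] - nt] <- sprintf("%d", round(f))
    }
  }
  tree$node.label <- labs
  tree
}

node_split_key <- function(tree, node) {
  labs <- tree$tip.label
  nt <- length(labs)
  ref <- sort(labs)[1]
  desc <- tips_below(tree, node)
  side <- labs[desc]
  if (ref %in% side) side <- setdiff(labs, side)
  if (length(side) < 2 || length(side) > nt - 2) return(NULL)
  paste(sort(side), collapse = "|")
}

tips_below <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_below, tree = tree))
}

#' @export
print.support_report <- function(x, ...) {
  th <- x$config$threshold
  above <- x$frequencies[x$frequencies$freq >= th, , drop = FALSE]
  cat(sprintf("Bootstrap support: %d effective replicates\n", x$n_effective))
  cat(sprintf("  %d clade%s at or above %g%%\n", nrow(above),
              if (nrow(above) != 1) "s" else "", th))
  for (i in seq_len(min(10, nrow(above))))
    cat(sprintf("  %3.0f%%  %s\n", above$freq[i],
                paste(strsplit(above$split[i], "\\|")[[1]], collapse = " ")))
  invisible(x)
}
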