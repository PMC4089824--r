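#' Parse and write newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that
#' enforce the package's conventions: trees are unrooted leaf-labelled
#' topologies (branch lengths are ignored), labels must be unique, and
#' rooting is applied only when writing, as a display choice.
#'
#' @param text newick string.
#' @return `parse_newick` returns an [ape::phylo]; `write_newick` a string.
#' @export
parse_newick <- function(text) {
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("malformed newick string")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label: ", tr$tip.label[duplicated(tr$tip.label)][1])
  tr$edge.length <- NULL
  tr$node.label <- NULL
  if (ape::is.rooted(tr) && length(tr$tip.label) > 2) tr <- ape::unroot(tr)
  tr
}

#' @rdname parse_newick
#' @param tree an [ape::phylo].
#' @param rooted_at optional leaf label; the tree is written rooted on
#'   that leaf's pendant edge, so the leaf appears as the first-diverging
#'   terminal (outgroup display rooting).
#' @export
write_newick <- function(tree, rooted_at = NULL) {
  if (!is.null(rooted_at)) tree <- root_display(tree, rooted_at)
  ape::write.tree(tree)
}

#' Root a tree on a leaf's pendant edge for display
#' @inheritParams write_newick
#' @param taxon leaf label to root on.
#' @export
root_display <- function(tree, taxon) {
  if (!taxon %in% tree$tip.label) stop("unknown leaf label: ", taxon)
  ape::root(tree, outgroup = taxon, resolve.root = TRUE)
}

#' Informative bipartitions of a tree
#'
#' Each internal branch of an unrooted tree splits the leaves in two;
#' the split is canonicalised as the sorted side that does not contain
#' the alphabetically smallest label.  Trivial splits (single leaf or
#' all-but-one) are excluded.  The set is invariant under re-rooting.
#'
#' @param tree an [ape::phylo] (rooted input is treated as unrooted).
#' @return a named list of character vectors (names are `|`-joined keys).
#' @export
bipartitions <- function(tree) {
  labs <- tree$tip.label
  nt <- length(labs)
  ref <- sort(labs)[1]
  edge <- tree$edge
  n_node <- max(edge)
  below <- vector("list", n_node)
  for (i in seq_len(nt)) below[[i]] <- labs[i]
  o <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(o)))
    below[[o[i, 1]]] <- c(below[[o[i, 1]]], below[[o[i, 2]]])
  sides <- list()
  internal_child <- edge[, 2] > nt
  for (i in which(internal_child)) {
    side <- below[[edge[i, 2]]]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) >= 2 && length(side) <= nt - 2)
      sides[[paste(sort(side), collapse = "|")]] <- sort(side)
  }
  if (length(sides) == 0) return(setNames(list(), character(0)))
  sides[order(names(sides))]
}

split_keys <- function(tree) names(bipartitions(tree))

#' Robinson-Foulds distance between two unrooted trees
#'
#' The number of informative bipartitions present in exactly one of the
#' two trees (symmetric-difference count).
#'
#' @param tree_a,tree_b [ape::phylo] objects over the same leaf set.
#' @return a non-negative integer.
#' @export
rf_distance <- function(tree_a, tree_b) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label))
    stop("trees have different leaf sets")
  a <- split_keys(tree_a)
  b <- split_keys(tree_b)
  length(setdiff(a, b)) + length(setdiff(b, a))
}

#' Topological identity of unrooted trees
#'
#' Two trees are considered identical when their leaf sets and
#' informative bipartition sets coincide (newick string equality is not
#' required).
#' @inheritParams rf_distance
#' @export
trees_equal <- function(tree_a, tree_b) {
  setequal(tree_a$tip.label, tree_b$tip.label) &&
    setequal(split_keys(tree_a), split_keys(tree_b))
}

#' Canonical newick form
#'
#' Writes the tree rooted on the pendant edge of the alphabetically
#' smallest leaf, with children everywhere ordered by their smallest
#' descendant label.  Topologically identical unrooted trees yield
#' byte-identical strings.
#'
#' @param tree an [ape::phylo].
#' @return a newick string.
#' @export
canonical_newick <- function(tree) {
  labs <- tree$tip.label
  ref <- sort(labs)[1]
  tr <- root_display(tree, ref)
  edge <- tr$edge
  nt <- length(labs)
  kids <- split(edge[, 2], edge[, 1])
  build <- function(v) {
    if (v <= nt) return(list(str = labs[v], min = labs[v]))
    parts <- lapply(kids[[as.character(v)]], build)
    parts <- parts[order(vapply(parts, `[[`, "", "min"))]
    list(str = paste0("(", paste(vapply(parts, `[[`, "", "str"), collapse = ","), ")"),
         min = parts[[1]]$min)
  }
  root <- setdiff(edge[, 1], edge[, 2])[1]
  paste0(build(root)$str, ";")
}

# internal: strict dedup of a list of trees by bipartition sets
dedup_trees <- function(trees) {
  keys <- vapply(trees, function(t) paste(split_keys(t), collapse = ";"), "")
  trees[!duplicated(keys)]
}

# internal: ape phylo (binary unrooted or rooted) -> validated edge matrix
# reordered so tip i matches taxa[i] of the matrix
tree_edge_for <- function(tree, taxa) {
  if (!setequal(tree$tip.label, taxa))
    stop("tree leaves do not match matrix taxa")
  perm <- match(tree$tip.label, taxa)
  edge <- tree$edge
  tip <- edge[, 2] <= length(taxa)
  edge[tip, 2] <- perm[edge[tip, 2]]
  edge
}

# internal: multifurcating collapse of selected internal edges
collapse_tree_edges <- function(tree, drop_edges) {
  if (length(drop_edges) == 0) return(tree)
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree$edge.length[drop_edges] <- 0
  out <- ape::di2multi(tree, tol = 0.5)
  out$edge.length <- NULL
  out
}
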