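#' Parsimony length of a tree
#'
#' Minimum number of unordered (Fitch) state changes over all characters,
#' computed with a degree-general most-parsimonious assignment (Hartigan
#' pass) so that multifurcating trees - e.g. strict consensus trees - are
#' scored exactly.  Missing (`?`) and inapplicable (`-`) cells are
#' optimization-neutral.  The length is invariant under re-rooting.
#'
#' @param tree an [ape::phylo] whose leaves match the matrix taxa.
#' @param x a [char_matrix].
#' @param weights optional non-negative integer character weights
#'   (used by bootstrap resampling); default all 1.
#' @return `tree_length`: total steps (numeric); `character_length`: an
#'   integer vector of per-character steps named by character number.
#' @examples
#' fx <- load_helopini_fixture()
#' tr <- wagner_build(fx$matrix, seed = 1)
#' tree_length(tr, fx$matrix)
#' @export
tree_length <- function(tree, x, weights = NULL) {
  pd <- pars_data(x, weights)
  c_hartigan(tree_edge_for(tree, x$taxa), n_taxa(x), pd$masks, pd$weights,
             pd$n_states)$total
}

#' @rdname tree_length
#' @export
character_length <- function(tree, x) {
  pd <- pars_data(x)
  s <- c_hartigan(tree_edge_for(tree, x$taxa), n_taxa(x), pd$masks, pd$weights,
                  pd$n_states)$per_char
  setNames(as.integer(s), seq_len(n_chars(x)))
}

pars_data <- function(x, weights = NULL) {
  sm <- state_masks(x)
  if (is.null(weights)) weights <- rep(1L, n_chars(x))
  stopifnot(length(weights) == n_chars(x), all(weights >= 0))
  list(masks = sm$masks, n_states = sm$n_states, weights = as.integer(weights))
}

#' Per-character step bounds
#'
#' For each character: `m`, the minimum conceivable steps on any tree
#' (number of observed states minus one), and `g`, the maximum steps,
#' attained on the completely unresolved star tree (scored taxa minus
#' the count of the most frequent state).  Missing and inapplicable
#' cells are excluded from both terms.
#'
#' @param x a [char_matrix].
#' @return data.frame with columns `character`, `m`, `g`, `n_scored`,
#'   `informative` (`TRUE` when at least two states occur in two or more
#'   scored taxa each, i.e. the character can exceed `m` steps).
#' @export
step_bounds <- function(x) {
  res <- t(apply(x$cells, 2, function(col) {
    sc <- col[col %in% as.character(0:9)]
    if (length(sc) == 0) return(c(0L, 0L, 0L, 0L))
    tab <- table(sc)
    c(length(tab) - 1L, length(sc) - max(tab), length(sc), sum(tab >= 2) >= 2)
  }))
  data.frame(character = seq_len(n_chars(x)), m = as.integer(res[, 1]),
             g = as.integer(res[, 2]), n_scored = as.integer(res[, 3]),
             informative = as.logical(res[, 4]))
}

# Display conventions for index values.  The classic cladistics programs
# (NONA, WinClada) print ci/ri truncated - not rounded - to two decimals;
# `index_trunc` reproduces that so summaries are comparable with published
# tables.  `round_half_up` is the conventional alternative, kept for
# callers that want arithmetic rounding.
index_trunc <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 1e-9) / p
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Consistency and retention indices
#'
#' Per-character `ci = m/s` and `ri = (g - s)/(g - m)` plus the ensemble
#' indices `CI = sum(m)/sum(s)` and `RI = (sum(g) - sum(s))/(sum(g) - sum(m))`
#' on a reference tree.  Two ensemble conventions are reported side by
#' side: over all characters and over parsimony-informative characters
#' only (software differs in whether uninformative characters are
#' included; both are retained so either printed convention can be
#' matched, and the reference tree's summary records which is in use).
#'
#' Per-character `ci` is undefined (NA) for characters with `s = 0`, and
#' `ri` is undefined when `g = m`.
#'
#' @param trees a single [ape::phylo] or a list/`multiPhylo` of trees;
#'   for a set, indices are computed on `tree` (default: the strict
#'   consensus of the set).
#' @param x a [char_matrix].
#' @param tree optional designated reference tree.
#' @return an object of class `index_report`: list with `per_character`
#'   (data.frame), `ensemble` (data.frame with rows `all` and
#'   `informative`), `tree_count`, `reference`.
#' @examples
#' fx <- load_helopini_fixture()
#' tr <- wagner_build(fx$matrix, seed = 1)
#' index_report(tr, fx$matrix)
#' @export
index_report <- function(trees, x, tree = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0) stop("need at least one tree")
  if (is.null(tree))
    tree <- if (length(trees) == 1) trees[[1]] else strict_consensus(trees)
  s <- character_length(tree, x)
  b <- step_bounds(x)
  per <- data.frame(character = b$character, s = as.integer(s), m = b$m, g = b$g)
  per$ci <- ifelse(per$s > 0, per$m / per$s, NA_real_)
  per$ri <- ifelse(per$g > per$m, (per$g - per$s) / (per$g - per$m), NA_real_)
  ens <- function(idx) {
    S <- sum(per$s[idx]); M <- sum(per$m[idx]); G <- sum(per$g[idx])
    data.frame(S = S, M = M, G = G,
               CI = if (S > 0) M / S else NA_real_,
               RI = if (G > M) (G - S) / (G - M) else NA_real_)
  }
  ensemble <- rbind(all = ens(rep(TRUE, nrow(per))), informative = ens(b$informative))
  ensemble <- cbind(convention = rownames(ensemble), ensemble)
  rownames(ensemble) <- NULL
  structure(list(per_character = per, ensemble = ensemble,
                 tree_count = length(trees), reference = tree),
            class = "index_report")
}

#' @export
print.index_report <- function(x, ...) {
  e <- x$ensemble
  cat(sprintf("Parsimony index report (%d tree%s; reference tree length %d)\n",
              x$tree_count, if (x$tree_count > 1) "s" else "", e$S[1]))
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %-12s S=%-4d M=%-4d G=%-4d CI=%.2f RI=%.2f\n",
                e$convention[i], e$S[i], e$M[i], e$G[i],
                index_trunc(e$CI[i]), index_trunc(e$RI[i])))
  homo <- sum(x$per_character$s > x$per_character$m)
  cat(sprintf("  %d of %d characters show homoplasy (s > m) on the reference tree\n",
              homo, nrow(x$per_character)))
  invisible(x)
}

#' Serialize an index report as a tab-delimited table
#' @param report an [index_report()].
#' @param file optional path.
#' @export
write_index_report <- function(report, file = NULL) {
  per <- report$per_character
  lines <- c("character\ts\tm\tg\tci\tri",
             sprintf("%d\t%d\t%d\t%d\t%s\t%s", per$character, per$s, per$m, per$g,
                     ifelse(is.na(per$ci), "-", sprintf("%.2f", index_trunc(per$ci))),
                     ifelse(is.na(per$ri), "-", sprintf("%.2f", index_trunc(per$ri)))))
  if (is.null(file)) return(paste(lines, collapse = "\n"))
  writeLines(lines, file)
  invisible(lines)
}

#' Ancestral state-set reconstruction for one character
#'
#' Computes, for every vertex, the set of states assigned by at least
#' one most-parsimonious reconstruction (MPR), and for every branch the
#' possible change records.  A branch change is *unambiguous* when every
#' MPR places a change on that branch and all MPRs agree on the derived
#' state; this exact criterion is computed from a uniform-cost dynamic
#' program over rootings rather than from accelerated/delayed heuristics.
#'
#' @param tree an [ape::phylo]; polytomies allowed.  When `root_taxon`
#'   is given the tree is rooted there first so that change direction
#'   ("derived" = state of the vertex away from the root) is meaningful.
#' @param x a [char_matrix].
#' @param char 1-based character number.
#' @param root_taxon optional leaf label for directional rooting.
#' @return list with `s` (steps), `node_states` (list of state vectors,
#'   indexed like tree nodes), and `changes` (data.frame: one row per
#'   branch with `forced`, `derived`, `from`, `unambiguous`,
#'   `derived_state`).
#' @export
reconstruct <- function(tree, x, char, root_taxon = NULL) {
  if (char < 1 || char > n_chars(x)) stop("character id out of range")
  if (!is.null(root_taxon)) tree <- root_display(tree, root_taxon)
  pd <- pars_data(x)
  edge <- tree_edge_for(tree, x$taxa)
  ea <- c_edge_analysis(edge, n_taxa(x), pd$masks[, char, drop = FALSE], pd$n_states)
  unmask <- function(m) which(bitwAnd(m, bitwShiftL(1L, 0:9)) > 0) - 1L
  node_states <- lapply(ea$node_sets[, 1], unmask)
  ch <- data.frame(parent = tree$edge[, 1], child = tree$edge[, 2],
                   forced = ea$forced[, 1] == 1)
  ch$derived <- lapply(ea$derived[, 1], unmask)
  ch$from <- lapply(ea$from[, 1], unmask)
  ch$unambiguous <- ch$forced & lengths(ch$derived) == 1
  ch$derived_state <- ifelse(ch$unambiguous, vapply(ch$derived, function(d)
    if (length(d) == 1) d else NA_integer_, integer(1)), NA_integer_)
  list(s = ea$per_char[1], node_states = node_states, changes = ch, tree = tree)
}
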