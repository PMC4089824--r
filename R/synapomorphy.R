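#' Map common unambiguous synapomorphies onto a consensus
#'
#' A character-state transformation is mapped onto a consensus branch
#' only when (i) its optimization on the consensus is unambiguous -
#' every most-parsimonious reconstruction changes on that branch to the
#' same derived state - and (ii) the identical transformation (same
#' bipartition, same derived state) is unambiguous in every one of the
#' most parsimonious trees.  Transformations are classified *unique*
#' (non-homoplasious: the character's steps on the consensus equal its
#' minimum, so ci = ri = 1) versus homoplasious.  Characters whose
#' unambiguous changes exist but never agree on a common branch across
#' all trees are returned in the orphan list.
#'
#' @param consensus the strict consensus of `mpts`.
#' @param mpts list of most parsimonious trees.
#' @param x a [char_matrix].
#' @param root_taxon leaf used to orient changes (derived = away from
#'   this leaf).
#' @return an object of class `synapomorphy_map`: list with `map`
#'   (data.frame: `split`, `character`, `derived_state`, `unique`),
#'   `orphans` (character ids), `consensus`.
#' @export
common_synapomorphies <- function(consensus, mpts, x, root_taxon) {
  mpts <- as_tree_list(mpts)
  if (!trees_equal(consensus, strict_consensus(mpts)))
    stop("`consensus` is not the strict consensus of `mpts`")
  cons_ch <- unambiguous_changes(consensus, x, root_taxon)
  mpt_ch <- lapply(mpts, unambiguous_changes, x = x, root_taxon = root_taxon)
  common <- cons_ch
  if (nrow(common)) {
    keep <- vapply(seq_len(nrow(common)), function(i) {
      all(vapply(mpt_ch, function(m)
        any(m$split == common$split[i] & m$character == common$character[i] &
              m$derived_state == common$derived_state[i]), TRUE))
    }, TRUE)
    common <- common[keep, , drop = FALSE]
  }
  b <- step_bounds(x)
  s_cons <- character_length(consensus, x)
  if (nrow(common)) {
    common$unique <- s_cons[common$character] == b$m[common$character] &
      b$m[common$character] > 0
  } else common$unique <- logical(0)
  rownames(common) <- NULL
  has_unamb <- sort(unique(unlist(lapply(mpt_ch, function(m) m$character))))
  orphans <- setdiff(has_unamb, common$character)
  structure(list(map = common, orphans = orphans, consensus = consensus),
            class = "synapomorphy_map")
}

# all unambiguous (forced, single derived state) changes of a tree,
# keyed by unrooted bipartition, including pendant branches keyed by the
# single tip label
unambiguous_changes <- function(tree, x, root_taxon) {
  rooted <- root_display(tree, root_taxon)
  pd <- pars_data(x)
  edge <- tree_edge_for(rooted, x$taxa)
  ea <- c_edge_analysis(edge, n_taxa(x), pd$masks, pd$n_states)
  nt <- n_taxa(x)
  keys <- vapply(seq_len(nrow(rooted$edge)), function(i) {
    child <- rooted$edge[i, 2]
    if (child <= nt) rooted$tip.label[child]
    else node_split_key(rooted, child) %||% NA_character_
  }, "")
  single_state <- function(m) {
    s <- which(bitwAnd(m, bitwShiftL(1L, 0:9)) > 0) - 1L
    if (length(s) == 1) s else NA_integer_
  }
  rows <- which(ea$forced == 1, arr.ind = TRUE)
  if (nrow(rows) == 0)
    return(data.frame(split = character(0), character = integer(0),
                      derived_state = integer(0)))
  out <- data.frame(split = keys[rows[, 1]], character = as.integer(rows[, 2]),
                    derived_state = vapply(seq_len(nrow(rows)), function(j)
                      single_state(ea$derived[rows[j, 1], rows[j, 2]]), integer(1)))
  out <- out[!is.na(out$derived_state) & !is.na(out$split), , drop = FALSE]
  out
}

#' @export
print.synapomorphy_map <- function(x, ...) {
  m <- x$map
  cat(sprintf("Common unambiguous transformations: %d on %d branches\n",
              nrow(m), length(unique(m$split))))
  uq <- unique(m$character[m$unique])
  cat(sprintf("  unique (ci = ri = 1) synapomorphies: %d character%s%s\n",
              length(uq), if (length(uq) != 1) "s" else "",
              if (length(uq)) paste0(" (", paste(sort(uq), collapse = ", "), ")") else ""))
  if (length(x$orphans))
    cat("  characters without a common branch:", paste(x$orphans, collapse = ", "), "\n")
  invisible(x)
}

#' Render a plain-text analysis report
#'
#' Combines the search result, consensus, index report, bootstrap
#' support and synapomorphy map of one analysis into a report: a
#' summary block, the per-character index table, a branch table (support
#' and transformations), and the annotated consensus newick rooted at
#' the display root.  Deterministic given fixed inputs.
#'
#' @param result an [heuristic_search()] result.
#' @param consensus the strict consensus tree.
#' @param indices an [index_report()] computed on `consensus`.
#' @param map a [common_synapomorphies()] result.
#' @param support optional [bootstrap_support()] report.
#' @param root_taxon leaf used for display rooting.
#' @param file optional output path.
#' @return the report lines, invisibly when written to `file`.
#' @export
render_report <- function(result, consensus, indices, map, support = NULL,
                          root_taxon, file = NULL) {
  e <- indices$ensemble
  lines <- c(
    "== Maximum-parsimony analysis ==",
    sprintf("Most parsimonious trees: %d (length %g)",
            length(result$trees), result$best_length),
    sprintf("Strict consensus: L = %g; CI = %.2f; RI = %.2f (all characters)",
            e$S[e$convention == "all"],
            index_trunc(e$CI[e$convention == "all"]),
            index_trunc(e$RI[e$convention == "all"])),
    sprintf("                  CI = %.2f; RI = %.2f (informative characters only)",
            index_trunc(e$CI[e$convention == "informative"]),
            index_trunc(e$RI[e$convention == "informative"])),
    "",
    "== Per-character indices (consensus) ==",
    write_index_report(indices),
    "",
    "== Branch table ==",
    branch_table(map, support),
    "",
    "== Annotated consensus (newick) ==",
    write_newick(if (is.null(support)) consensus else support$annotated_tree,
                 rooted_at = root_taxon))
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

branch_table <- function(map, support = NULL) {
  m <- map$map
  splits <- unique(m$split)
  hdr <- if (is.null(support)) "branch\ttransformations"
         else "branch\tsupport\ttransformations"
  rows <- vapply(splits, function(s) {
    rs <- m[m$split == s, , drop = FALSE]
    tr <- paste(sprintf("%d:%d%s", rs$character, rs$derived_state,
                        ifelse(rs$unique, "*", "")), collapse = " ")
    lab <- paste(strsplit(s, "\\|")[[1]], collapse = ",")
    if (is.null(support)) sprintf("%s\t%s", lab, tr)
    else {
      f <- support$frequencies
      sv <- if (s %in% f$split) sprintf("%.0f", f$freq[f$split == s]) else "-"
      sv <- if (sv != "-" && as.numeric(sv) < support$config$threshold) "-" else sv
      sprintf("%s\t%s\t%s", lab, sv, tr)
    }
  }, "")
  paste(c(hdr, rows), collapse = "\n")
}
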