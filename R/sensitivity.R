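#' Sequential character-removal sensitivity analysis
#'
#' For every character, the matrix lacking that single character is
#' re-searched, the strict consensus of the resulting most parsimonious
#' trees is built, and its polytomy-general parsimony length, resolved
#' bipartition count and tree count are compared against the full-matrix
#' baseline.  Characters whose removal drops the consensus length by
#' more than `threshold` steps are flagged as conflict-inducing: a drop
#' that large exceeds any single character's own step contribution and
#' signals a substantial topology shift once the character's conflicting
#' signal is gone.
#'
#' Each of the `n_chars` sub-searches is an independent leave-one-out
#' run ("sequential" = iterating over characters, not cumulative
#' deletion).  Sub-searches default to a reduced replicate count;
#' increase `n_replicates` to match a full-effort published protocol.
#'
#' @param x a [char_matrix].
#' @param threshold length-delta cutoff in steps for flagging.
#' @param n_replicates,hold,max_trees per-search effort (see
#'   [heuristic_search()]).
#' @param seed RNG seed (each sub-search derives its own stream).
#' @param verbose print progress.
#' @return an object of class `removal_profile`: data.frame with one row
#'   per character (`character`, `consensus_length`, `delta_length`,
#'   `delta_resolved`, `delta_mpts`, `flagged`, `failed`) carrying the
#'   baseline as an attribute.
#' @export
removal_analysis <- function(x, threshold = 30, n_replicates = 20, hold = 20,
                             max_trees = 500, seed = NULL, verbose = FALSE) {
  stopifnot(threshold >= -1)
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_chars(x) + 1)
  summarise <- function(mat, sd) {
    res <- heuristic_search(mat, n_replicates = n_replicates, hold = hold,
                            max_trees = max_trees, seed = sd)
    cons <- strict_consensus(res$trees)
    list(length = tree_length(cons, mat),
         resolved = length(bipartitions(cons)),
         mpts = length(res$trees))
  }
  base <- summarise(x, sub_seeds[1])
  rows <- vector("list", n_chars(x))
  for (ch in seq_len(n_chars(x))) {
    r <- try(summarise(remove_character(x, ch), sub_seeds[ch + 1]), silent = TRUE)
    if (inherits(r, "try-error")) {
      rows[[ch]] <- data.frame(character = ch, consensus_length = NA,
                               delta_length = NA, delta_resolved = NA,
                               delta_mpts = NA, flagged = NA, failed = TRUE)
    } else {
      rows[[ch]] <- data.frame(
        character = ch, consensus_length = r$length,
        delta_length = base$length - r$length,
        delta_resolved = r$resolved - base$resolved,
        delta_mpts = r$mpts - base$mpts,
        flagged = (base$length - r$length) > threshold, failed = FALSE)
    }
    if (verbose) message(sprintf("character %d/%d: consensus length %s",
                                 ch, n_chars(x), rows[[ch]]$consensus_length))
  }
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- base
  attr(out, "threshold") <- threshold
  class(out) <- c("removal_profile", "data.frame")
  out
}

#' @export
print.removal_profile <- function(x, ...) {
  b <- attr(x, "baseline")
  cat(sprintf("Character-removal profile: baseline consensus length %g (%d splits, %d MPTs)\n",
              b$length, b$resolved, b$mpts))
  cat(sprintf("  threshold %g steps: %d character(s) flagged\n",
              attr(x, "threshold"), sum(x$flagged, na.rm = TRUE)))
  fl <- x$character[which(x$flagged)]
  if (length(fl)) cat("  flagged:", paste(fl, collapse = ", "), "\n")
  NextMethod()
}
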