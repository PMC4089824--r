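#' Construct a morphological character matrix
#'
#' A `char_matrix` is a taxa x characters grid of single-character state
#' codes.  Legal cell values are the digits `"0"`-`"9"`, `"?"` (missing,
#' not observed) and `"-"` (inapplicable).  Both `"?"` and `"-"` are
#' optimization-neutral in all downstream analyses (the NONA/WinClada
#' convention for inapplicable states).  Polymorphic codings such as
#' `[01]` are not supported and are rejected at parse time.
#'
#' @param cells character matrix of cell symbols; rownames are taxon labels
#'   unless `taxa` is given.
#' @param taxa character vector of unique, non-empty taxon labels.
#' @param character_notes optional character vector of per-character
#'   free-text descriptions (length `ncol(cells)`).
#' @return an object of class `char_matrix`.
#' @examples
#' m <- char_matrix(rbind(A = c("0", "0"), B = c("0", "1"),
#'                        C = c("1", "?"), D = c("1", "-")))
#' n_taxa(m)
#' @export
char_matrix <- function(cells, taxa = rownames(cells), character_notes = NULL) {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "character"
  if (is.null(taxa)) stop("taxon labels are required (rownames or `taxa`)")
  taxa <- as.character(taxa)
  if (length(taxa) != nrow(cells)) stop("length of `taxa` must match rows of `cells`")
  if (any(!nzchar(taxa))) stop("taxon labels must be non-empty")
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon label: ", taxa[duplicated(taxa)][1])
  }
  ok <- matrix(cells %in% c(as.character(0:9), "?", "-"), nrow(cells))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("illegal symbol '%s' at taxon '%s', character %d",
                 cells[bad[1], bad[2]], taxa[bad[1]], bad[2]))
  }
  if (!is.null(character_notes) && length(character_notes) != ncol(cells))
    stop("character_notes must have one entry per character")
  rownames(cells) <- taxa
  colnames(cells) <- NULL
  structure(list(taxa = taxa, cells = cells, character_notes = character_notes),
            class = "char_matrix")
}

#' @rdname char_matrix
#' @param x a `char_matrix`.
#' @export
n_taxa <- function(x) length(x$taxa)

#' @rdname char_matrix
#' @export
n_chars <- function(x) ncol(x$cells)

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("Character matrix: %d taxa x %d characters\n", n_taxa(x), n_chars(x)))
  cat(sprintf("  missing '?': %d cells, inapplicable '-': %d cells\n",
              sum(x$cells == "?"), sum(x$cells == "-")))
  show <- head(x$taxa, 5)
  for (t in show)
    cat(sprintf("  %-26s %s%s\n", t,
                paste(x$cells[t, seq_len(min(40, n_chars(x)))], collapse = ""),
                if (n_chars(x) > 40) "..." else ""))
  if (n_taxa(x) > 5) cat(sprintf("  ... and %d more taxa\n", n_taxa(x) - 5))
  invisible(x)
}

#' @export
as.matrix.char_matrix <- function(x, ...) x$cells

# Bitmask encoding used by the C engine: bit s set <=> state s allowed.
# Missing and inapplicable cells get the union of the column's observed
# states (optimization-neutral); an entirely unscored column scores 0 steps.
state_masks <- function(x, tip_order = x$taxa) {
  cells <- x$cells[tip_order, , drop = FALSE]
  digits <- suppressWarnings(matrix(as.integer(cells), nrow(cells)))
  masks <- matrix(0L, nrow(cells), ncol(cells))
  scored <- !is.na(digits)
  masks[scored] <- bitwShiftL(1L, digits[scored])
  obs <- vapply(seq_len(ncol(masks)), function(j) {
    m <- Reduce(bitwOr, masks[scored[, j], j], 0L)
    if (m == 0L) 1L else m
  }, integer(1))
  for (j in seq_len(ncol(masks)))
    masks[!scored[, j], j] <- obs[j]
  n_states <- max(1L, ceiling(log2(max(obs) + 1)))
  list(masks = masks, observed = obs, n_states = n_states)
}

#' Read a character matrix
#'
#' Supported formats:
#' \describe{
#'   \item{`tnt`}{Hennig86/TNT `xread` dialect: an `xread` line, an
#'     optional quoted title, a `<n_chars> <n_taxa>` header, one row per
#'     taxon (label then contiguous or spaced cells), `;` terminator.}
#'   \item{`nexus`}{A `DATA`/`CHARACTERS` block with
#'     `FORMAT SYMBOLS="0123456789" MISSING=? GAP=-`.}
#'   \item{`table`}{One taxon per line: the first whitespace-separated
#'     token is the label, remaining tokens are cells.}
#' }
#'
#' @param source path to a file, or a character string containing the
#'   document itself (recognised by embedded newlines).
#' @param format one of `"tnt"`, `"nexus"`, `"table"`.
#' @return a [char_matrix].
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(source, format = c("tnt", "nexus", "table")) {
  format <- match.arg(format)
  lines <- if (length(source) == 1 && !grepl("\n", source) && file.exists(source))
    readLines(source) else unlist(strsplit(source, "\n", fixed = TRUE))
  switch(format,
         tnt = parse_tnt(lines),
         nexus = parse_nexus(lines),
         table = parse_table(lines))
}

split_cells <- function(tokens, taxon) {
  cells <- unlist(strsplit(tokens, ""))
  bad <- !cells %in% c(as.character(0:9), "?", "-")
  if (any(bad))
    stop(sprintf("illegal symbol '%s' in row of taxon '%s' (character %d)",
                 cells[bad][1], taxon, which(bad)[1]))
  cells
}

assemble_rows <- function(labels, cellrows) {
  nc <- unique(lengths(cellrows))
  if (length(nc) != 1)
    stop("ragged rows: taxon '",
         labels[which(lengths(cellrows) != lengths(cellrows)[1])[1]],
         "' has a different number of cells")
  char_matrix(do.call(rbind, cellrows), taxa = labels)
}

parse_tnt <- function(lines) {
  lines <- trimws(lines)
  i <- grep("^xread", lines)
  if (length(i) == 0) stop("not a TNT xread document")
  i <- i[1] + 1
  # optional quoted title (possibly multi-line)
  if (i <= length(lines) && startsWith(lines[i], "'")) {
    while (i <= length(lines) && !grepl("'$", sub("^'", "", lines[i]))) i <- i + 1
    i <- i + 1
  }
  hdr <- as.integer(strsplit(lines[i], "\\s+")[[1]])
  if (length(hdr) != 2 || anyNA(hdr)) stop("malformed xread header: ", lines[i])
  nch <- hdr[1]; ntx <- hdr[2]
  labels <- character(0); cellrows <- list()
  i <- i + 1
  while (i <= length(lines)) {
    ln <- lines[i]; i <- i + 1
    if (ln == "" ) next
    if (ln == ";" || startsWith(ln, ";")) break
    toks <- strsplit(ln, "\\s+")[[1]]
    labels <- c(labels, toks[1])
    cellrows <- c(cellrows, list(split_cells(toks[-1], toks[1])))
  }
  if (length(labels) != ntx)
    stop(sprintf("xread header states %d taxa but %d rows found", ntx, length(labels)))
  m <- assemble_rows(labels, cellrows)
  if (n_chars(m) != nch)
    stop(sprintf("xread header states %d characters but rows have %d", nch, n_chars(m)))
  m
}

parse_nexus <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  if (!grepl("#NEXUS", txt, ignore.case = TRUE)) stop("not a NEXUS document")
  f <- tempfile(fileext = ".nex")
  on.exit(unlink(f))
  writeLines(lines, f)
  dat <- ape::read.nexus.data(f)
  labels <- names(dat)
  cellrows <- lapply(seq_along(dat), function(i)
    split_cells(toupper(dat[[i]]), labels[i]))
  assemble_rows(labels, cellrows)
}

parse_table <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty table")
  toks <- strsplit(lines, "\\s+")
  labels <- vapply(toks, `[`, "", 1)
  cellrows <- lapply(seq_along(toks), function(i)
    split_cells(toks[[i]][-1], labels[i]))
  assemble_rows(labels, cellrows)
}

#' Write a character matrix
#'
#' The emitted document parses back (with [read_matrix()]) to a matrix
#' with identical cells, taxon order and `?`/`-` symbols.  Taxon labels
#' have internal whitespace replaced by underscores in `tnt` output.
#'
#' @inheritParams read_matrix
#' @param x a [char_matrix].
#' @param file optional path; when `NULL` the document is returned as a
#'   single character string.
#' @export
write_matrix <- function(x, format = c("tnt", "nexus", "table"), file = NULL) {
  format <- match.arg(format)
  labels <- gsub("\\s+", "_", x$taxa)
  pad <- max(nchar(labels)) + 2
  rows <- sprintf("%-*s%s", pad, labels,
                  apply(x$cells, 1, paste, collapse = if (format == "table") " " else ""))
  doc <- switch(format,
    tnt = c("xread", sprintf("%d %d", n_chars(x), n_taxa(x)), rows, ";"),
    nexus = c("#NEXUS", "BEGIN DATA;",
              sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", n_taxa(x), n_chars(x)),
              "  FORMAT SYMBOLS=\"0123456789\" MISSING=? GAP=-;",
              "  MATRIX", paste0("    ", rows), "  ;", "END;"),
    table = rows)
  out <- paste(doc, collapse = "\n")
  if (is.null(file)) return(out)
  writeLines(doc, file)
  invisible(out)
}

#' Load the packaged Helopini matrix and taxon metadata
#'
#' Returns the published 33-taxon x 67-character morphological matrix of
#' the darkling-beetle tribe Helopini together with tribe/subtribe and
#' biogeographic metadata for every taxon.  The three outgroup taxa are
#' flagged, and *Uloma mexicana* is additionally flagged as the taxon on
#' which cladograms are rooted for display.  Cells are transcribed
#' verbatim from the published matrix, including its few codings that
#' exceed the states enumerated in the character descriptions.
#'
#' @return a list with components `matrix` (a [char_matrix]) and `taxa`
#'   (a data.frame with columns `taxon`, `tribe`, `subtribe`, `region`,
#'   `is_outgroup`, `is_root`).
#' @examples
#' fx <- load_helopini_fixture()
#' n_taxa(fx$matrix)
#' sum(!fx$taxa$is_outgroup)
#' @export
load_helopini_fixture <- function() {
  mat <- read_matrix(system.file("extdata", "helopini_matrix.tnt",
                                 package = "morphoclad", mustWork = TRUE), "tnt")
  taxa <- read.delim(system.file("extdata", "helopini_taxa.tsv",
                                 package = "morphoclad", mustWork = TRUE),
                     stringsAsFactors = FALSE)
  stopifnot(identical(mat$taxa, taxa$taxon),
            sum(taxa$is_root) == 1, all(taxa$is_outgroup[taxa$is_root]))
  list(matrix = mat, taxa = taxa)
}

#' Delete one character (column) from a matrix
#'
#' @param x a [char_matrix].
#' @param id 1-based character number.
#' @export
remove_character <- function(x, id) {
  id <- as.integer(id)
  if (length(id) != 1 || is.na(id) || id < 1 || id > n_chars(x))
    stop("character id out of range: ", id)
  char_matrix(x$cells[, -id, drop = FALSE], taxa = x$taxa,
              character_notes = x$character_notes[-id])
}
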