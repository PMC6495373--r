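#' Parse a Newick tree string
#'
#' Light validation layer over [ape::read.tree()]: square-bracket comments are
#' stripped, quoted labels are accepted, and the result is checked for unique
#' tip labels and usable branch lengths before any distance computation sees
#' it. Branch lengths are expected in substitutions per base (SPB).
#'
#' @param text a single Newick string (terminating ";" optional on input).
#' @param missing_lengths policy for edges without a branch length:
#'   `"error"` (default; patristic distances are meaningless without lengths)
#'   or `"zero"` to impute 0.
#' @return an object of class `"phylo"` (see [ape::read.tree()]).
#' @examples
#' tr <- parse_newick("((A:1,B:2):3,C:4);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text, missing_lengths = c("error", "zero")) {
  missing_lengths <- match.arg(missing_lengths)
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop_domain("newick parse error: input must be a single non-empty string")
  text <- strip_newick_comments(text)
  check_balanced(text)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop_domain("newick parse error: malformed tree")
  if (anyDuplicated(tr$tip.label))
    stop_domain("newick parse error: duplicate tip labels: ",
                paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
    if (missing_lengths == "error")
      stop_domain("newick parse error: missing branch lengths ",
                  "(set missing_lengths = \"zero\" to impute 0)")
    if (is.null(tr$edge.length)) tr$edge.length <- numeric(nrow(tr$edge))
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0))
    stop_domain("newick parse error: branch lengths must be finite and >= 0")
  tr
}

strip_newick_comments <- function(text) gsub("\\[[^]]*\\]", "", text)

# positional check so the error can name the offending character
check_balanced <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop_domain("newick parse error: unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L)
    stop_domain("newick parse error: ", depth, " unclosed '(' at end of input")
  invisible(TRUE)
}

#' Write a tree as a Newick string
#'
#' @param tree a `"phylo"` object.
#' @return a single Newick string ending in ";".
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Parse FASTA text into a named sequence set
#'
#' Records are returned in file order as a named character vector
#' (names = record ids, first whitespace-delimited token of each header).
#' Wrapped sequence lines are concatenated; blank lines are ignored.
#' The permitted alphabet is not restricted here beyond non-emptiness, so
#' both unaligned sequences and gapped ("-") alignment rows pass through.
#'
#' @param text FASTA content as a single string (or a character vector of lines).
#' @return named character vector of sequences.
#' @export
parse_fasta <- function(text) {
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop_domain("fasta format error: empty input")
  if (!startsWith(trimws(text), ">"))
    stop_domain("fasta format error: input does not start with '>'")
  tf <- tempfile(fileext = ".fasta")
  on.exit(unlink(tf), add = TRUE)
  writeLines(text, tf)
  set <- Biostrings::readBStringSet(tf)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(seqs))) {
    bad <- names(seqs)[!nzchar(seqs)]
    stop_domain("fasta format error: empty sequence for record(s): ",
                paste(bad, collapse = ", "))
  }
  if (anyDuplicated(names(seqs)))
    stop_domain("fasta format error: duplicate record ids")
  seqs
}

#' Write a named sequence set as FASTA text
#'
#' @param seqs named character vector of sequences.
#' @param width line-wrap width (default 60).
#' @return a single FASTA-formatted string.
#' @export
write_fasta <- function(seqs, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  recs <- vapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    wrapped <- substring(s, seq(1L, nchar(s), width),
                         pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s)))
    paste0(">", names(seqs)[i], "\n", paste(wrapped, collapse = "\n"))
  }, character(1))
  paste0(paste(recs, collapse = "\n"), "\n")
}

#' Read a labelled numeric matrix from delimited text
#'
#' First row holds column labels, first column row labels (RFC-4180 quoting).
#' Cells that cannot be parsed as numbers ("NA", empty) are kept as `NA` —
#' flagged, never silently zeroed. Ragged rows are an error naming the row.
#'
#' @param input path to a file, or the delimited text itself (anything
#'   containing a newline is treated as text).
#' @param sep field delimiter, default ",".
#' @return numeric matrix with `dimnames`; attribute `"n_missing"` holds the
#'   count of missing cells.
#' @export
read_table_matrix <- function(input, sep = ",") {
  is_text <- length(input) > 1L || grepl("\n", input, fixed = TRUE)
  lines <- if (is_text) {
    unlist(strsplit(paste(input, collapse = "\n"), "\n", fixed = TRUE))
  } else readLines(input)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop_domain("table format error: need a header row and at least one data row")
  nf <- utils::count.fields(textConnection(lines), sep = sep, quote = "\"")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    row_id <- strsplit(lines[bad], sep, fixed = TRUE)[[1]][1]
    stop_domain("table format error: ragged row '", row_id, "' (",
                nf[bad], " fields, expected ", nf[1], ")")
  }
  df <- utils::read.table(text = paste(lines, collapse = "\n"), sep = sep,
                          header = TRUE, check.names = FALSE, row.names = 1L,
                          quote = "\"", stringsAsFactors = FALSE)
  if (anyDuplicated(rownames(df)) || anyDuplicated(colnames(df)))
    stop_domain("table format error: duplicate row or column labels")
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  attr(m, "n_missing") <- sum(is.na(m))
  m
}

#' Write a labelled numeric matrix as delimited text
#'
#' @param m numeric matrix with `dimnames`.
#' @param sep field delimiter, default ",".
#' @return a single delimited string; `read_table_matrix()` round-trips it.
#' @export
write_table_matrix <- function(m, sep = ",") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  con <- textConnection("out", "w", local = TRUE)
  utils::write.table(m, con, sep = sep, col.names = NA, qmethod = "double")
  close(con)
  paste0(paste(out, collapse = "\n"), "\n")
}
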