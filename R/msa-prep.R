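# Alignment-curation steps applied to the LSU rRNA barcode data set before
# tree building, plus the ortholog filters used for the phylogenomic matrix.

normalize_seq <- function(s) chartr("u", "T", chartr("U", "T", toupper(s)))

#' Pairwise percent identity from a global alignment
#'
#' Needleman-Wunsch global alignment (match +1, mismatch 0, linear gap cost,
#' end gaps penalized) via [Biostrings::pairwiseAlignment()]; identity is
#' matches / aligned columns, gap-vs-gap columns excluded. Input gaps are
#' stripped first; sequences are uppercased and U is treated as T.
#'
#' @param a,b sequences (single strings).
#' @return identity in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  a <- gsub("-", "", normalize_seq(a), fixed = TRUE)
  b <- gsub("-", "", normalize_seq(b), fixed = TRUE)
  if (!nzchar(a) || !nzchar(b))
    stop_domain("pairwise_identity: empty sequence")
  letters_seen <- sort(unique(strsplit(paste0(a, b), "")[[1]]))
  sub <- diag(1, length(letters_seen))
  dimnames(sub) <- list(letters_seen, letters_seen)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b),
    type = "global", substitutionMatrix = sub,
    gapOpening = 0, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  keep <- !(pa == "-" & sa == "-")
  sum(pa[keep] == sa[keep] & pa[keep] != "-") / sum(keep)
}

#' Greedy centroid dereplication of a sequence set
#'
#' Removes redundancy by retaining only the centroid sequences of clusters of
#' near-identical sequences (default threshold 99% identity). Sequences are
#' processed in decreasing length order (ties broken by id); each joins the
#' first existing centroid with pairwise identity >= `identity_threshold`,
#' otherwise it founds a new cluster. All centroid pairs therefore have
#' identity < threshold at creation time.
#'
#' @param seqs named character vector of sequences.
#' @param identity_threshold identity in (0, 1\]; default 0.99.
#' @return list with `centroids` (named character vector, input order of the
#'   greedy pass) and `membership` (named character: every input id -> its
#'   centroid id).
#' @export
centroid_dereplicate <- function(seqs, identity_threshold = 0.99) {
  if (length(seqs) == 0L) stop_domain("centroid_dereplicate: empty input")
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (identity_threshold <= 0 || identity_threshold > 1)
    stop_domain("centroid_dereplicate: identity_threshold must be in (0, 1]")
  ord <- order(-nchar(seqs), names(seqs))
  centroids <- character(0)
  membership <- character(0)
  for (id in names(seqs)[ord]) {
    assigned <- NA_character_
    for (cid in names(centroids)) {
      if (pairwise_identity(seqs[[id]], centroids[[cid]]) >= identity_threshold) {
        assigned <- cid
        break
      }
    }
    if (is.na(assigned)) {
      centroids[id] <- seqs[[id]]
      assigned <- id
    }
    membership[id] <- assigned
  }
  list(centroids = centroids, membership = membership)
}

aln_matrix <- function(aln) {
  stopifnot(is.character(aln), !is.null(names(aln)))
  lens <- nchar(aln)
  if (length(unique(lens)) != 1L)
    stop_domain("alignment error: sequences have unequal lengths")
  do.call(rbind, strsplit(normalize_seq(aln), ""))
}

#' Remove alignment columns above a gap-proportion threshold
#'
#' A column is removed iff its gap proportion strictly exceeds
#' `max_gap_prop` (the rule is "over", so a column at exactly the threshold
#' is kept). Surviving column order is preserved.
#'
#' @param aln named character vector of equal-length aligned sequences
#'   (gap character "-").
#' @param max_gap_prop threshold in \[0, 1\]; default 0.8.
#' @return list: `alignment` (trimmed, same ids), `removed` (1-based indices
#'   of removed columns), `empty` (TRUE with a warning if nothing survived).
#' @export
trim_gappy_columns <- function(aln, max_gap_prop = 0.8) {
  m <- aln_matrix(aln)
  gap_prop <- colMeans(m == "-")
  removed <- which(gap_prop > max_gap_prop)
  keep <- setdiff(seq_len(ncol(m)), removed)
  out <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  if (ncol(m) > 0 && length(keep) == 0L) {
    warning("trim_gappy_columns: no columns survived trimming", call. = FALSE)
    out <- stats::setNames(rep("", nrow(m)), rownames(m))
  }
  list(alignment = stats::setNames(out, names(aln)),
       removed = removed, empty = length(keep) == 0L)
}

#' Count parsimony-informative alignment columns
#'
#' A column is parsimony-informative when it shows at least two character
#' states, each occurring in at least two sequences; gaps are not a state.
#'
#' @param aln named character vector of equal-length aligned sequences.
#' @return integer count (0 for an empty alignment).
#' @export
count_parsimony_informative <- function(aln) {
  if (length(aln) == 0L || !nzchar(aln[[1]])) return(0L)
  m <- aln_matrix(aln)
  sum(vapply(seq_len(ncol(m)), function(j) {
    tab <- table(m[, j][m[, j] != "-"])
    sum(tab >= 2L) >= 2L
  }, logical(1)))
}

#' Retain informative alignments
#'
#' Keeps alignments with at least `min_unique_seqs` distinct sequence strings
#' and at least `min_pi_columns` parsimony-informative columns (both bounds
#' inclusive).
#'
#' @param alignments list of alignments (each a named character vector).
#' @param min_unique_seqs minimum count of distinct sequences; default 10.
#' @param min_pi_columns minimum parsimony-informative columns; default 10.
#' @return list: `retained` (the surviving sublist) and `report` (data.frame
#'   with per-alignment unique-sequence and PI-column counts and pass flag).
#' @export
filter_informative_alignments <- function(alignments, min_unique_seqs = 10L,
                                          min_pi_columns = 10L) {
  if (length(alignments) == 0L)
    return(list(retained = list(),
                report = data.frame(id = character(0), n_unique = integer(0),
                                    n_pi = integer(0), pass = logical(0))))
  ids <- names(alignments) %||% as.character(seq_along(alignments))
  n_unique <- vapply(alignments, function(a) length(unique(unname(a))), integer(1))
  n_pi <- vapply(alignments, count_parsimony_informative, integer(1))
  pass <- n_unique >= min_unique_seqs & n_pi >= min_pi_columns
  list(retained = alignments[pass],
       report = data.frame(id = ids, n_unique = n_unique, n_pi = n_pi,
                           pass = pass, row.names = NULL,
                           stringsAsFactors = FALSE))
}

#' Filter ortholog clusters by genome occupancy
#'
#' Selects ortholog clusters with one representative in at least a fraction
#' `min_ref_fraction` of the reference genomes (rounded up) and in at least
#' `min_isolates` of the study isolates. With `one_to_one = TRUE` (default)
#' only single-copy presence qualifies, excluding paralog-expanded clusters;
#' otherwise any presence (count >= 1) counts.
#'
#' @param occupancy integer matrix, ortholog clusters (rows) x genomes
#'   (columns), representative counts.
#' @param ref_ids,isolate_ids column ids of the reference genomes and the
#'   study isolates (disjoint).
#' @param min_ref_fraction default 0.5.
#' @param min_isolates absolute count, default 3.
#' @param one_to_one require exactly one representative; default TRUE.
#' @return sorted character vector of retained cluster ids.
#' @export
filter_ortholog_occupancy <- function(occupancy, ref_ids, isolate_ids,
                                      min_ref_fraction = 0.5,
                                      min_isolates = 3L, one_to_one = TRUE) {
  stopifnot(is.matrix(occupancy))
  if (length(ref_ids) == 0L)
    stop_domain("filter_ortholog_occupancy: empty reference set")
  if (length(intersect(ref_ids, isolate_ids)))
    stop_domain("filter_ortholog_occupancy: reference and isolate sets overlap")
  missing <- setdiff(c(ref_ids, isolate_ids), colnames(occupancy))
  if (length(missing))
    stop_domain("filter_ortholog_occupancy: genomes not in table: ",
                paste(missing, collapse = ", "))
  qual <- if (one_to_one) {
    function(x) x == 1L
  } else {
    function(x) x >= 1L
  }
  need_refs <- ceiling(min_ref_fraction * length(ref_ids))
  ok <- rowSums(qual(occupancy[, ref_ids, drop = FALSE])) >= need_refs &
    rowSums(qual(occupancy[, isolate_ids, drop = FALSE])) >= min_isolates
  sort(rownames(occupancy)[ok])
}
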