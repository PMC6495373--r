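test_that("pairwise identity follows the aligned-columns definition", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 1)
  expect_equal(pairwise_identity("ACGTACGT", "ACGTTTTT"), 5 / 8)
  expect_equal(pairwise_identity("AAAA", "AATT"), 0.5)
  expect_equal(pairwise_identity("acgu", "ACGT"), 1)  # case and U/T folding
  expect_error(pairwise_identity("", "ACGT"), "empty")
})

test_that("centroid dereplication collapses redundancy greedily", {
  seqs <- c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT")
  dr <- centroid_dereplicate(seqs)
  expect_equal(length(dr$centroids), 1L)
  expect_equal(sort(names(dr$membership)), c("a", "b", "c"))
  expect_equal(length(unique(dr$membership)), 1L)

  # s3 has 4/8 matches to the first centroid: below 0.99, new centroid
  seqs2 <- c(s1 = "ACGTACGT", s2 = "ACGTACGT", s3 = "ACGTTTTT")
  dr2 <- centroid_dereplicate(seqs2)
  expect_equal(length(dr2$centroids), 2L)

  # strictest threshold: all distinct sequences become centroids
  seqs3 <- c(x = "ACGTACGA", y = "ACGTACGC", z = "ACGTACGG")
  dr3 <- centroid_dereplicate(seqs3, identity_threshold = 1.0)
  expect_equal(length(dr3$centroids), 3L)
  expect_error(centroid_dereplicate(character(0)), "empty")
})

test_that("every member has identity >= threshold to its centroid", {
  set.seed(31)
  base <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  mutate <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    at <- sample(length(v), k)
    v[at] <- sample(c("A", "C", "G", "T"), k, TRUE)
    paste(v, collapse = "")
  }
  seqs <- c(setNames(vapply(1:6, function(i) mutate(base, 1), ""),
                     paste0("near", 1:6)),
            setNames(vapply(1:3, function(i) mutate(base, 30), ""),
                     paste0("far", 1:3)))
  thr <- 0.9
  dr <- centroid_dereplicate(seqs, thr)
  for (id in names(dr$membership)) {
    cid <- dr$membership[[id]]
    if (id != cid)
      expect_gte(pairwise_identity(seqs[[id]], seqs[[cid]]), thr)
  }
  # injecting duplicate records leaves the centroid set unchanged
  dup <- c(seqs, setNames(seqs[1:2], paste0(names(seqs)[1:2], "_dup")))
  expect_equal(sort(names(centroid_dereplicate(dup, thr)$centroids)),
               sort(names(dr$centroids)))
})

test_that("gap-proportion trimming applies the strict 'over' rule", {
  aln <- c(r1 = "A-A", r2 = "A-A", r3 = "A-A", r4 = "A-A", r5 = "AAA")
  tr <- trim_gappy_columns(aln, 0.8)
  expect_equal(tr$removed, integer(0))  # 4/5 gaps = 0.8 exactly: kept
  aln2 <- c(r1 = "A-A", r2 = "A-A", r3 = "A-A", r4 = "A-A", r5 = "A-A")
  tr2 <- trim_gappy_columns(aln2, 0.8)
  expect_equal(tr2$removed, 2L)         # 5/5 gaps: removed
  expect_equal(unname(tr2$alignment), rep("AA", 5))

  clean <- c(a = "ACGT", b = "TGCA")
  expect_equal(trim_gappy_columns(clean)$alignment, clean)
})

test_that("trimming is idempotent", {
  set.seed(33)
  rows <- replicate(6, paste(sample(c("A", "C", "-", "-"), 40, TRUE),
                             collapse = ""))
  names(rows) <- paste0("s", 1:6)
  once <- trim_gappy_columns(rows, 0.5)$alignment
  twice <- trim_gappy_columns(once, 0.5)$alignment
  expect_equal(twice, once)
})

test_that("parsimony-informative counting matches the two-by-two rule", {
  expect_equal(count_parsimony_informative(
    c(a = "A", b = "A", c = "C", d = "C")), 1L)   # AACC informative
  expect_equal(count_parsimony_informative(
    c(a = "A", b = "A", c = "A", d = "C")), 0L)   # singleton state
  expect_equal(count_parsimony_informative(
    c(a = "A", b = "C", c = "G", d = "T")), 0L)   # all singletons
  expect_equal(count_parsimony_informative(
    c(a = "A-", b = "A-", c = "C-", d = "C-")), 1L)  # gaps are not a state
  expect_equal(count_parsimony_informative(character(0)), 0L)
})

test_that("PI counting equals a brute-force per-column tally", {
  set.seed(35)
  for (rep in 1:5) {
    nseq <- sample(4:10, 1); ncol_ <- sample(10:50, 1)
    m <- matrix(sample(c("A", "C", "G", "T", "-"), nseq * ncol_, TRUE),
                nseq, ncol_)
    aln <- setNames(apply(m, 1, paste, collapse = ""), paste0("s", 1:nseq))
    brute <- sum(apply(m, 2, function(col) {
      tb <- table(col[col != "-"])
      sum(tb >= 2) >= 2
    }))
    expect_equal(count_parsimony_informative(aln), brute)
  }
})

test_that("informative-alignment filter applies inclusive bounds", {
  identical12 <- setNames(rep("ACGTACGT", 12), paste0("s", 1:12))
  expect_equal(length(filter_informative_alignments(
    list(x = identical12))$retained), 0L)

  # 10 unique sequences and exactly 10 PI columns: retained at the boundary.
  # First 10 columns split A/C five-five (each PI); a trailing block gives
  # each sequence a single private T (singleton states, never PI).
  block <- function(ch) strrep(ch, 10)
  uniq_tail <- vapply(1:10, function(i) {
    v <- rep("G", 10); v[i] <- "T"; paste(v, collapse = "")
  }, "")
  aln <- setNames(paste0(rep(c(block("A"), block("C")), each = 5), uniq_tail),
                  paste0("s", 1:10))
  res <- filter_informative_alignments(list(y = aln), min_unique_seqs = 10,
                                       min_pi_columns = 10)
  expect_equal(res$report$n_unique, 10L)
  expect_equal(res$report$n_pi, 10L)
  expect_true(res$report$pass)
  # one PI column fewer fails the boundary
  res9 <- filter_informative_alignments(list(y = aln), min_unique_seqs = 10,
                                        min_pi_columns = 11)
  expect_false(res9$report$pass)

  empty <- filter_informative_alignments(list())
  expect_equal(length(empty$retained), 0L)
})

test_that("ortholog occupancy filter matches its set-comprehension oracle", {
  refs <- paste0("ref", 1:10); isos <- paste0("iso", 1:5)
  occ <- matrix(0L, 3, 15, dimnames = list(c("c1", "c2", "c3"), c(refs, isos)))
  occ["c1", c(refs[1:5], isos[1:3])] <- 1L   # 5/10 refs, 3/5 isolates: kept
  occ["c2", ] <- 2L                          # paralogous everywhere
  occ["c3", c(refs[1:4], isos[1:5])] <- 1L   # 4/10 refs: below fraction
  expect_equal(filter_ortholog_occupancy(occ, refs, isos), "c1")
  expect_equal(filter_ortholog_occupancy(occ, refs, isos, one_to_one = FALSE),
               c("c1", "c2"))
  expect_error(filter_ortholog_occupancy(occ, character(0), isos), "empty")

  set.seed(39)
  for (rep in 1:5) {
    occ2 <- matrix(sample(0:3, 20 * 15, TRUE), 20, 15,
                   dimnames = list(sprintf("og%02d", 1:20), c(refs, isos)))
    got <- filter_ortholog_occupancy(occ2, refs, isos)
    keep <- vapply(rownames(occ2), function(cl) {
      sum(occ2[cl, refs] == 1) >= ceiling(0.5 * 10) &&
        sum(occ2[cl, isos] == 1) >= 3
    }, logical(1))
    expect_equal(got, sort(rownames(occ2)[keep]))
  }
})
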