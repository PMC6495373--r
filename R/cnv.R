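# Copy-number-variation signature scoring between a pair of isolates.
# Directionality is evaluated relative to the other isolate of the pair:
# for an expected duplication, the isolate with the HIGHER copy number at
# that cluster is concordant with the beverage-yeast signature; for an
# expected deletion, the LOWER one.

check_pair <- function(table, isolate_a, isolate_b) {
  stopifnot(is.matrix(table))
  for (iso in c(isolate_a, isolate_b))
    if (!iso %in% rownames(table))
      stop_domain("isolate '", iso, "' not in copy-number table")
  if (any(table < 0) || any(table != round(table)))
    stop_domain("copy numbers must be nonnegative integers")
  invisible(TRUE)
}

#' Ortholog clusters with copy-number variation between two isolates
#'
#' @param table copy-number matrix, isolates (rows) x ortholog clusters
#'   (columns), nonnegative integer counts.
#' @param isolate_a,isolate_b row ids to compare.
#' @return sorted character vector of cluster ids whose copy numbers differ.
#' @export
detect_cnv_clusters <- function(table, isolate_a, isolate_b) {
  check_pair(table, isolate_a, isolate_b)
  sort(colnames(table)[table[isolate_a, ] != table[isolate_b, ]])
}

#' Concordance of an isolate pair with a CNV signature
#'
#' Restricts to the signature clusters that show CNV between the pair and, at
#' each, credits the isolate whose copy number lies in the signature's
#' expected direction (higher for an expected duplication, lower for an
#' expected deletion). An equal-split chi-square test
#' ([neutral_split_chisq()]) against the neutral expectation accompanies the
#' counts whenever any signature cluster varies.
#'
#' @inheritParams detect_cnv_clusters
#' @param signature named character vector: cluster id ->
#'   `"duplication"` or `"deletion"`.
#' @return list of class `"cnv_concordance"`: `count_a`, `count_b`, `total`
#'   (signature clusters with CNV), `chi2`, `p_value` (NA and `flagged =
#'   TRUE` when total is 0), `per_cluster` data.frame.
#' @export
signature_concordance <- function(table, isolate_a, isolate_b, signature) {
  check_pair(table, isolate_a, isolate_b)
  stopifnot(is.character(signature), !is.null(names(signature)))
  if (!all(signature %in% c("duplication", "deletion")))
    stop_domain("signature directions must be 'duplication' or 'deletion'")
  missing <- setdiff(names(signature), colnames(table))
  if (length(missing))
    stop_domain("signature cluster(s) absent from table: ",
                paste(missing, collapse = ", "))
  cl <- sort(names(signature))
  a <- table[isolate_a, cl]
  b <- table[isolate_b, cl]
  varied <- a != b
  dir <- signature[cl]
  winner <- ifelse(!varied, NA_character_,
                   ifelse((dir == "duplication") == (a > b), isolate_a, isolate_b))
  count_a <- sum(winner == isolate_a, na.rm = TRUE)
  count_b <- sum(winner == isolate_b, na.rm = TRUE)
  total <- sum(varied)
  if (total > 0) {
    test <- neutral_split_chisq(count_a, count_b)
  } else {
    test <- list(chi2 = NA_real_, p_value = NA_real_)
  }
  structure(list(isolate_a = isolate_a, isolate_b = isolate_b,
                 count_a = count_a, count_b = count_b, total = total,
                 chi2 = test$chi2, p_value = test$p_value,
                 flagged = total == 0,
                 per_cluster = data.frame(cluster = cl, direction = unname(dir),
                                          copy_a = unname(a), copy_b = unname(b),
                                          concordant = unname(winner),
                                          stringsAsFactors = FALSE)),
            class = "cnv_concordance")
}

#' @export
print.cnv_concordance <- function(x, ...) {
  cat("CNV signature concordance:", x$isolate_a, "vs", x$isolate_b, "\n")
  cat(sprintf("  %d signature clusters with CNV; %s: %d, %s: %d\n",
              x$total, x$isolate_a, x$count_a, x$isolate_b, x$count_b))
  if (x$flagged) {
    cat("  no signature cluster varies between the pair (test undefined)\n")
  } else {
    cat(sprintf("  equal-split chi2 = %.3f, p = %.3g\n", x$chi2, x$p_value))
  }
  invisible(x)
}

#' Chi-square test of a count pair against the equal split
#'
#' One-degree-of-freedom goodness-of-fit of (count_a, count_b) against the
#' neutral expectation (n/2, n/2), where n = count_a + count_b. No continuity
#' correction by default.
#'
#' @param count_a,count_b nonnegative integer counts, not both zero.
#' @param correct apply Yates continuity correction; default FALSE.
#' @return list with `chi2` and `p_value`.
#' @export
neutral_split_chisq <- function(count_a, count_b, correct = FALSE) {
  assert_scalar_number(count_a, "count_a")
  assert_scalar_number(count_b, "count_b")
  if (count_a < 0 || count_b < 0)
    stop_domain("neutral_split_chisq: counts must be nonnegative")
  n <- count_a + count_b
  if (n <= 0) stop_domain("neutral_split_chisq: total count must be positive")
  e <- n / 2
  dev <- abs(count_a - e)
  if (correct) dev <- max(dev - 0.5, 0)
  chi2 <- 2 * dev^2 / e
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Paired t test of two isolates' copy-number profiles over a signature
#'
#' Tests whether the expected CNVs fall in systematically different clusters
#' for the two isolates: by default a paired two-sided t test across the
#' signature clusters on the per-cluster copy-number differences (a - b); a
#' Welch two-sample variant on the two profiles is available.
#'
#' @inheritParams signature_concordance
#' @param method `"paired"` (default) or `"welch"`.
#' @return list: `statistic`, `p_value`, `method`. All-zero differences give
#'   p = 1 (profiles identical); a nonzero constant difference has zero
#'   variance and errors, pointing at the Welch variant.
#' @export
signature_profile_ttest <- function(table, isolate_a, isolate_b, signature,
                                    method = c("paired", "welch")) {
  method <- match.arg(method)
  check_pair(table, isolate_a, isolate_b)
  cl <- sort(names(signature))
  missing <- setdiff(cl, colnames(table))
  if (length(missing))
    stop_domain("signature cluster(s) absent from table: ",
                paste(missing, collapse = ", "))
  if (length(cl) < 2L)
    stop_domain("signature_profile_ttest: need >= 2 signature clusters")
  a <- table[isolate_a, cl]
  b <- table[isolate_b, cl]
  if (method == "paired") {
    d <- a - b
    if (all(d == 0))
      return(list(statistic = 0, p_value = 1, method = "paired (all differences 0)"))
    if (stats::var(d) == 0)
      stop_domain("signature_profile_ttest: zero variance of nonzero ",
                  "differences; use method = \"welch\"")
    tt <- stats::t.test(d)
    list(statistic = unname(tt$statistic), p_value = tt$p.value, method = "paired")
  } else {
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      # both profiles constant: difference is exact, no sampling variation
      same <- isTRUE(all.equal(mean(a), mean(b)))
      return(list(statistic = if (same) 0 else sign(mean(a) - mean(b)) * Inf,
                  p_value = if (same) 1 else .Machine$double.xmin,
                  method = "welch (constant profiles)"))
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    list(statistic = unname(tt$statistic), p_value = tt$p.value, method = "welch")
  }
}
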