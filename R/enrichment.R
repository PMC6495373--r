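# Exact isolation-frequency enrichment: is yeast recovery biased toward
# putative beverage vessels relative to control samples?

#' Fisher's exact test for a 2x2 contingency table
#'
#' Exact hypergeometric computation with log-factorial accumulation (no
#' normal approximation, stable for totals into the thousands). With margins
#' fixed, the probability of a table with top-left cell k is
#' dhyper-distributed; the one-sided (`"greater"`) p sums the tail k >= a,
#' and the two-sided p follows the sum-of-small-point-probabilities rule of
#' mainstream statistical software: all tables whose point probability does
#' not exceed that of the observed table (within 1e-7 relative slack)
#' contribute. A doubled-one-tail two-sided rule is available by flag.
#'
#' @param a,b positives and negatives in group 1.
#' @param c,d positives and negatives in group 2.
#' @param sided `"two"` (default) or `"greater"` (enrichment of group 1).
#' @param two_sided_rule `"minlike"` (default) or `"doubling"`.
#' @return p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c, d, sided = c("two", "greater"),
                             two_sided_rule = c("minlike", "doubling")) {
  sided <- match.arg(sided)
  two_sided_rule <- match.arg(two_sided_rule)
  cells <- c(a = a, b = b, c = c, d = d)
  for (nm in names(cells)) assert_scalar_number(cells[[nm]], nm)
  if (any(cells < 0) || any(cells != round(cells)))
    stop_domain("fisher_exact_2x2: cells must be nonnegative integers")
  n <- a + b + c + d
  if (n < 1) stop_domain("fisher_exact_2x2: grand total must be >= 1")
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  ks <- max(0, c1 - r2):min(r1, c1)
  # log point probability of each admissible table, margins fixed
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  obs <- logp[ks == a]
  if (sided == "greater") {
    p <- sum(exp(logp[ks >= a]))
  } else if (two_sided_rule == "minlike") {
    p <- sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
  } else {
    lo <- sum(exp(logp[ks <= a]))
    hi <- sum(exp(logp[ks >= a]))
    p <- min(2 * min(lo, hi), 1)
  }
  min(max(p, .Machine$double.xmin), 1)
}

#' Build and test a 2x2 isolation-enrichment table from sample records
#'
#' Splits sample records into two disjoint groups by category, tabulates
#' yeast recovery into a 2x2 table and delegates to [fisher_exact_2x2()].
#'
#' @param records data.frame with columns `sample`, `category`,
#'   `yeast_recovered` (logical or 0/1); one row per sample.
#' @param group_a,group_b character vectors of categories defining the two
#'   groups (e.g. `"putative-beverage"` vs the control categories); they must
#'   not overlap and both must select at least one sample.
#' @return list of class `"enrichment_test"`: `table` (2x2 matrix
#'   positives/negatives by group), `odds_ratio` (sample cross-product),
#'   `p_two_sided`, `p_greater`.
#' @export
isolation_enrichment <- function(records, group_a, group_b) {
  need <- c("sample", "category", "yeast_recovered")
  if (!all(need %in% names(records)))
    stop_domain("isolation_enrichment: records must have columns ",
                paste(need, collapse = ", "))
  if (anyDuplicated(records$sample))
    stop_domain("isolation_enrichment: duplicate sample ids")
  if (length(intersect(group_a, group_b)))
    stop_domain("isolation_enrichment: groups share categories: ",
                paste(intersect(group_a, group_b), collapse = ", "))
  in_a <- records$category %in% group_a
  in_b <- records$category %in% group_b
  if (!any(in_a) || !any(in_b))
    stop_domain("isolation_enrichment: both groups must select >= 1 sample")
  pos <- as.logical(records$yeast_recovered)
  a <- sum(in_a & pos); b <- sum(in_a & !pos)
  c <- sum(in_b & pos); d <- sum(in_b & !pos)
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("group_a", "group_b"),
                                c("yeast", "no_yeast")))
  or <- if (b * c == 0) Inf else (a * d) / (b * c)
  structure(list(table = tab, odds_ratio = or,
                 p_two_sided = fisher_exact_2x2(a, b, c, d, sided = "two"),
                 p_greater = fisher_exact_2x2(a, b, c, d, sided = "greater")),
            class = "enrichment_test")
}

#' @export
print.enrichment_test <- function(x, ...) {
  cat("Isolation-frequency enrichment (Fisher's exact test)\n")
  print(x$table)
  cat(sprintf("  odds ratio = %.3g; two-sided p = %.3g; one-sided p = %.3g\n",
              x$odds_ratio, x$p_two_sided, x$p_greater))
  invisible(x)
}
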