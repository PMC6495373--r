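#' Patristic distance matrix of a tree
#'
#' The patristic distance between two tips is the cumulative branch length
#' along the unique path connecting them; it is invariant to root placement.
#' Branch lengths (and hence distances) are in substitutions per base (SPB).
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @return symmetric numeric matrix (zero diagonal) over the tip labels,
#'   in the tree's tip order.
#' @export
patristic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 2L)
    stop_domain("patristic_matrix: tree must have at least 2 tips")
  if (is.null(tree$edge.length))
    stop_domain("patristic_matrix: tree has no branch lengths")
  d <- stats::cophenetic(tree)
  # cophenetic.phylo returns tips in an internal order; restore tree order
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Intraspecific patristic distances
#'
#' Collects the distance for every unordered tip pair whose two tips carry the
#' same species label. Tips absent from the species map are ignored (queries
#' of unknown affiliation stay out of the reference distribution).
#'
#' @param pd patristic distance matrix from [patristic_matrix()].
#' @param species_map named character vector: tip label -> species label.
#' @return sorted numeric vector, one value per intraspecific pair.
#' @export
intraspecific_distances <- function(pd, species_map) {
  stopifnot(is.matrix(pd), is.character(species_map), !is.null(names(species_map)))
  species_map <- species_map[names(species_map) %in% rownames(pd)]
  out <- numeric(0)
  for (sp in unique(species_map)) {
    tips <- sort(names(species_map)[species_map == sp])
    if (length(tips) < 2L) next
    pairs <- utils::combn(tips, 2L)
    out <- c(out, pd[cbind(pairs[1L, ], pairs[2L, ])])
  }
  if (length(out) == 0L)
    stop_domain("intraspecific_distances: no intraspecific pairs ",
                "(no species has >= 2 mapped tips on the tree)")
  sort(out)
}

#' Test whether a tip's distance to its closest relative is conspecific
#'
#' Species-membership test for barcode delimitation: given the observed
#' patristic distance from a query to its closest relative and the reference
#' distribution of intraspecific distances, computes a right-tail p-value for
#' the hypothesis that the query distance belongs to that distribution. A
#' small p means the query is more divergent than conspecific pairs get, i.e.
#' a candidate novel species.
#'
#' Two rules are provided and the one used is recorded in the result:
#' * `"empirical"` — the plus-one counting rule
#'   p = (#\{x >= d_obs\} + 1) / (n + 1), which can never drop below
#'   1/(n+1) and therefore cannot flag a query beyond the observed maximum
#'   more strongly than the sample size allows;
#' * `"parametric"` (default) — right-tail probability of a maximum-likelihood
#'   lognormal (or gamma) fitted to the positive reference distances, which
#'   extrapolates beyond the observed maximum.
#'
#' With fewer than 5 positive reference values the parametric fit is
#' unreliable and the function falls back to the empirical rule with a
#' warning.
#'
#' @param d_obs observed distance (SPB, >= 0).
#' @param intraspecific numeric vector of reference intraspecific distances.
#' @param method `"parametric"` or `"empirical"`.
#' @param alpha significance level for the verdict (default 0.05).
#' @param family parametric family, `"lognormal"` (default) or `"gamma"`.
#' @return list of class `"membership_test"`: `d_obs`, `n`, `p_value`,
#'   `verdict` (`"conspecific"` or `"novel-species-candidate"`), `method`,
#'   `alpha`.
#' @export
species_membership_test <- function(d_obs, intraspecific,
                                    method = c("parametric", "empirical"),
                                    alpha = 0.05,
                                    family = c("lognormal", "gamma")) {
  method <- match.arg(method)
  family <- match.arg(family)
  assert_scalar_number(d_obs, "d_obs")
  if (d_obs < 0) stop_domain("species_membership_test: d_obs must be >= 0")
  if (length(intraspecific) == 0L)
    stop_domain("species_membership_test: empty reference distribution")
  n <- length(intraspecific)

  pos <- intraspecific[intraspecific > 0]
  if (method == "parametric" && length(pos) < 5L) {
    warning("fewer than 5 positive reference distances; ",
            "falling back to the empirical rule", call. = FALSE)
    method <- "empirical"
  }

  if (method == "empirical") {
    p <- (sum(intraspecific >= d_obs) + 1) / (n + 1)
    label <- "empirical"
  } else if (family == "lognormal") {
    lx <- log(pos)
    meanlog <- mean(lx)
    sdlog <- sqrt(mean((lx - meanlog)^2))  # ML, not n-1
    p <- if (d_obs <= 0) 1 else
      stats::plnorm(d_obs, meanlog, max(sdlog, 1e-12), lower.tail = FALSE)
    label <- "parametric-lognormal"
  } else {
    fit <- MASS::fitdistr(pos, "gamma")
    p <- if (d_obs <= 0) 1 else
      stats::pgamma(d_obs, shape = fit$estimate[["shape"]],
                    rate = fit$estimate[["rate"]], lower.tail = FALSE)
    label <- "parametric-gamma"
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(d_obs = d_obs, n = n, p_value = p,
                 verdict = if (p < alpha) "novel-species-candidate" else "conspecific",
                 method = label, alpha = alpha),
            class = "membership_test")
}

#' @export
print.membership_test <- function(x, ...) {
  cat("Species-membership test (", x$method, ")\n", sep = "")
  cat(sprintf("  d_obs = %g SPB against %d intraspecific distances\n", x$d_obs, x$n))
  cat(sprintf("  p = %.4g  ->  %s (alpha = %g)\n", x$p_value, x$verdict, x$alpha))
  invisible(x)
}

#' Closest relative of a tip
#'
#' @param pd patristic distance matrix.
#' @param query tip label present in the matrix.
#' @return list with `tip` (closest non-query tip; lexicographic tie-break)
#'   and `distance` (SPB).
#' @export
closest_relative <- function(pd, query) {
  stopifnot(is.matrix(pd))
  if (!query %in% rownames(pd))
    stop_domain("closest_relative: query tip '", query, "' not in matrix")
  d <- pd[query, ]
  d <- d[names(d) != query]
  d <- d[order(d, names(d))]  # lexicographic tie-break on equal distances
  list(tip = names(d)[1L], distance = unname(d[1L]))
}

# bipartitions of the unrooted tree as canonical keys: for each edge, the tip
# set on the side NOT containing the reference tip (first sorted label),
# frozen as a sorted comma-joined string. Trivial (single-tip) splits are
# excluded unless requested — the weighted variant sums over all branches
# (branch-score convention), the unweighted one over internal splits only.
# Returns named numeric vector key -> branch length.
tree_bipartitions <- function(tree, include_trivial = FALSE) {
  tree <- ape::unroot(tree)
  tips <- tree$tip.label
  ntip <- length(tips)
  ref <- sort(tips)[1L]
  prop <- ape::prop.part(tree)  # clades as tip indices, rooted view
  keys <- character(0); wts <- numeric(0)
  child <- tree$edge[, 2L]
  for (i in seq_along(child)) {
    desc <- if (child[i] <= ntip) tips[child[i]] else tips[prop[[child[i] - ntip]]]
    trivial <- length(desc) <= 1L || length(desc) >= ntip - 1L
    if (trivial && !include_trivial) next
    if (trivial && length(desc) >= ntip - 1L) next  # complement of a tip: dup key
    side <- if (ref %in% desc) setdiff(tips, desc) else desc
    keys <- c(keys, paste(sort(side), collapse = ","))
    wts <- c(wts, if (is.null(tree$edge.length)) 0 else tree$edge.length[i])
  }
  # unrooting can leave two edges describing the same split; sum their lengths
  tapply(wts, keys, sum)[unique(keys)]
}

#' Robinson-Foulds distance between two trees
#'
#' Unweighted: the size of the symmetric difference of the two trees'
#' non-trivial bipartition sets (computed on the unrooted forms). Weighted
#' (WRF): the sum over the union of bipartitions of the absolute difference
#' in branch length, an absent bipartition contributing weight 0; terminal
#' branches are included (branch-score convention), so two trees with the
#' same topology but different tip branch lengths are separated.
#'
#' @param tree1,tree2 `"phylo"` objects over the same tip label set.
#' @param weighted logical; compute the weighted variant.
#' @param normalized logical; divide by the maximum attainable value
#'   (unweighted: total bipartition count of both trees; weighted: sum of all
#'   compared branch lengths). Raw by default.
#' @return a single nonnegative number.
#' @export
robinson_foulds <- function(tree1, tree2, weighted = FALSE, normalized = FALSE) {
  stopifnot(inherits(tree1, "phylo"), inherits(tree2, "phylo"))
  t1 <- sort(tree1$tip.label); t2 <- sort(tree2$tip.label)
  if (!identical(t1, t2))
    stop_domain("robinson_foulds: tip sets differ: ",
                paste(c(setdiff(t1, t2), setdiff(t2, t1)), collapse = ", "))
  b1 <- tree_bipartitions(tree1, include_trivial = weighted)
  b2 <- tree_bipartitions(tree2, include_trivial = weighted)
  if (weighted) {
    keys <- union(names(b1), names(b2))
    w1 <- ifelse(keys %in% names(b1), b1[keys], 0)
    w2 <- ifelse(keys %in% names(b2), b2[keys], 0)
    val <- sum(abs(w1 - w2))
    if (normalized) val <- val / max(sum(w1) + sum(w2), .Machine$double.eps)
  } else {
    val <- length(setdiff(names(b1), names(b2))) +
      length(setdiff(names(b2), names(b1)))
    if (normalized) val <- val / max(length(b1) + length(b2), 1L)
  }
  val
}

#' All pairwise Robinson-Foulds distances of a tree list
#'
#' @param trees list of `"phylo"` objects sharing a tip set (names used as ids).
#' @inheritParams robinson_foulds
#' @return symmetric distance matrix with zero diagonal.
#' @export
robinson_foulds_matrix <- function(trees, weighted = FALSE, normalized = FALSE) {
  n <- length(trees)
  ids <- names(trees) %||% as.character(seq_len(n))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- robinson_foulds(trees[[i]], trees[[j]],
                                          weighted = weighted,
                                          normalized = normalized)
  }
  m
}

#' Density-based clustering of a precomputed distance matrix
#'
#' DBSCAN over precomputed distances, as used to group gene trees by their
#' pairwise (weighted) Robinson-Foulds distances and detect conflicting
#' phylogenetic signal. A point is a core point when at least `min_neighbors`
#' points (itself included) lie within `eps`; clusters are maximal
#' density-connected sets; non-core points unreachable from any core point
#' are noise. Border points are assigned to the first core cluster reaching
#' them when items are processed in sorted-id order, making the labelling
#' deterministic.
#'
#' @param d symmetric distance matrix with zero diagonal (dimnames = item ids).
#' @param eps neighborhood radius (> 0); 0.03 is the radius used for
#'   weighted-RF gene-tree clustering.
#' @param min_neighbors minimum neighborhood size for a core point (>= 1).
#' @return named integer vector: cluster id (1, 2, ...) per item, 0 = noise.
#' @export
dbscan_cluster <- function(d, eps, min_neighbors) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (!is.numeric(eps) || eps <= 0) stop_domain("dbscan_cluster: eps must be > 0")
  if (!is.numeric(min_neighbors) || min_neighbors < 1)
    stop_domain("dbscan_cluster: min_neighbors must be >= 1")
  if (max(abs(d - t(d))) > 1e-9 || any(abs(diag(d)) > 1e-9))
    stop_domain("dbscan_cluster: matrix must be symmetric with zero diagonal")
  ids <- rownames(d) %||% as.character(seq_len(nrow(d)))
  ord <- order(ids)
  n <- nrow(d)
  nbr <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))  # self included
  core <- vapply(nbr, length, integer(1)) >= min_neighbors
  label <- integer(n)            # 0 = unvisited/noise
  visited <- logical(n)
  cl <- 0L
  for (i in ord) {
    if (visited[i] || !core[i]) next
    cl <- cl + 1L
    queue <- i
    visited[i] <- TRUE
    label[i] <- cl
    while (length(queue)) {
      p <- queue[1L]; queue <- queue[-1L]
      for (q in sort(nbr[[p]])) {
        if (label[q] == 0L) label[q] <- cl        # border or new core
        if (core[q] && !visited[q]) {
          visited[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
  }
  stats::setNames(label, ids)
}

#' Delimit query tips on a barcode tree
#'
#' End-to-end species-delimitation wrapper: computes the patristic matrix,
#' builds the intraspecific reference distribution from the species map,
#' then for every query tip finds its closest relative and runs
#' [species_membership_test()].
#'
#' @param tree a `"phylo"` barcode tree.
#' @param species_map named character vector tip -> species (query tips and
#'   any unidentified references may be absent).
#' @param queries character vector of query tip labels.
#' @inheritParams species_membership_test
#' @return data.frame: query, closest relative, `d_obs`, `n`, `p_value`,
#'   verdict, method.
#' @export
delimit_species <- function(tree, species_map, queries,
                            method = c("parametric", "empirical"),
                            alpha = 0.05, family = c("lognormal", "gamma")) {
  method <- match.arg(method); family <- match.arg(family)
  pd <- patristic_matrix(tree)
  missing <- setdiff(queries, rownames(pd))
  if (length(missing))
    stop_domain("delimit_species: query tip(s) not in tree: ",
                paste(missing, collapse = ", "))
  ref <- intraspecific_distances(pd, species_map)
  rows <- lapply(queries, function(q) {
    # the query itself must not contribute reference distances; map hygiene
    cr <- closest_relative(pd, q)
    mt <- species_membership_test(cr$distance, ref, method = method,
                                  alpha = alpha, family = family)
    data.frame(query = q, closest = cr$tip, d_obs = cr$distance,
               n = mt$n, p_value = mt$p_value, verdict = mt$verdict,
               method = mt$method, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
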