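# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and, where possible, the
# libraries) used by the package itself.

# per-pair path-sum patristic distances: walk each tip's path to the root,
# take the symmetric difference of the two edge sets, sum lengths
oracle_patristic <- function(tree) {
  ntip <- length(tree$tip.label)
  parent_of <- integer(max(tree$edge))
  len_of <- numeric(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  len_of[tree$edge[, 2]] <- tree$edge.length
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  path_edges <- function(i) {
    out <- integer(0)
    while (i != root) {
      out <- c(out, i)  # edge identified by its child node
      i <- parent_of[i]
    }
    out
  }
  m <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip - 1)) for (j in (i + 1):ntip) {
    pi <- path_edges(i); pj <- path_edges(j)
    sym <- c(setdiff(pi, pj), setdiff(pj, pi))
    m[i, j] <- m[j, i] <- sum(len_of[sym])
  }
  m
}

# complete margin-preserving enumeration via dhyper (implementation uses
# lchoose accumulation instead)
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(ks, r1, r2, c1)
  obs <- probs[ks == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# naive Lance-Williams ward.D2 agglomeration on squared Euclidean distances;
# returns the sorted merge heights and the set of leaf-sets formed
oracle_ward <- function(x) {
  d2 <- as.matrix(dist(x))^2
  active <- as.list(seq_len(nrow(x)))
  sizes <- rep(1, nrow(x))
  heights <- numeric(0)
  clades <- list()
  D <- d2
  idx <- seq_len(nrow(x))
  while (length(idx) > 1) {
    best <- c(NA, NA); bestv <- Inf
    for (ii in seq_along(idx)) for (jj in seq_along(idx)) {
      if (ii >= jj) next
      v <- D[idx[ii], idx[jj]]
      if (v < bestv - 1e-12) { bestv <- v; best <- c(ii, jj) }
    }
    i <- idx[best[1]]; j <- idx[best[2]]
    heights <- c(heights, sqrt(bestv))
    merged <- sort(c(active[[i]], active[[j]]))
    clades[[length(clades) + 1]] <- merged
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(idx, c(i, j))) {
      nk <- sizes[k]
      # Lance-Williams update for Ward on squared distances
      D[i, k] <- D[k, i] <-
        ((ni + nk) * D[i, k] + (nj + nk) * D[j, k] - nk * D[i, j]) /
        (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    active[[i]] <- merged
    idx <- setdiff(idx, j)
  }
  list(heights = heights, clades = clades)
}

# brute-force DBSCAN semantics: core points, density-connected components
oracle_dbscan_partition <- function(d, eps, min_pts) {
  n <- nrow(d)
  nbr <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nbr, length, integer(1)) >= min_pts
  # connected components of the "within eps" graph restricted to cores
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (s in which(core)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, intersect(nbr[[v]], which(core & is.na(comp))))
    }
  }
  # border points: reachable from >= 1 core cluster
  border_opts <- lapply(seq_len(n), function(i) {
    if (core[i]) return(comp[i])
    sort(unique(stats::na.omit(comp[intersect(nbr[[i]], which(core))])))
  })
  list(core = core, core_comp = comp, border_opts = border_opts)
}

# hclust leaf sets per internal node (merge order not compared)
clade_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    pick <- function(j) if (j < 0) -j else sets[[j]]
    sets[[i]] <- sort(c(pick(hc$merge[i, 1]), pick(hc$merge[i, 2])))
  }
  sets
}

rand_bltree <- function(ntip) {
  tr <- ape::rtree(ntip)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 2)
  tr
}
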