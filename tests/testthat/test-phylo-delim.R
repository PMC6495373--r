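hand_tree <- parse_newick("((A:1,B:2):3,C:4);")

test_that("patristic distances match hand path sums", {
  pd0 <- patristic_matrix(parse_newick("(A:0,B:0);"))
  expect_equal(pd0["A", "B"], 0)

  pd <- patristic_matrix(hand_tree)
  expect_equal(pd["A", "B"], 3)
  expect_equal(pd["A", "C"], 8)
  expect_equal(pd["B", "C"], 9)
  expect_equal(diag(pd), c(A = 0, B = 0, C = 0))
  expect_error(patristic_matrix(ape::rtree(1)), "2 tips")
})

test_that("patristic matrix equals the brute-force path oracle", {
  set.seed(7)
  for (i in 1:10) {
    tr <- rand_bltree(sample(4:30, 1))
    expect_equal(patristic_matrix(tr),
                 oracle_patristic(tr)[tr$tip.label, tr$tip.label],
                 tolerance = 1e-9)
  }
})

test_that("patristic distances are invariant to rerooting", {
  set.seed(11)
  tr <- rand_bltree(12)
  pd <- patristic_matrix(tr)
  for (node in sample(tr$tip.label, 3)) {
    rr <- ape::root(tr, outgroup = node, resolve.root = TRUE)
    expect_equal(patristic_matrix(rr)[rownames(pd), colnames(pd)], pd,
                 tolerance = 1e-9)
  }
})

test_that("intraspecific distances cover exactly the same-species pairs", {
  pd <- patristic_matrix(hand_tree)
  expect_equal(intraspecific_distances(pd, c(A = "sp1", B = "sp1", C = "sp2")),
               3)
  expect_error(intraspecific_distances(pd, c(A = "sp1", B = "sp2", C = "sp3")),
               "no intraspecific pairs")
  tr4 <- parse_newick("((A:1,B:1):1,(C:2,D:2):1);")
  d4 <- intraspecific_distances(patristic_matrix(tr4),
                                c(A = "x", B = "x", C = "y", D = "y"))
  expect_equal(d4, c(2, 4))  # sorted, one value per pair
})

test_that("empirical membership test follows the counting rule exactly", {
  ref <- c(0.001, 0.002, 0.003, 0.004, 0.005)
  res <- species_membership_test(0.003, ref, method = "empirical")
  expect_equal(res$p_value, 4 / 6)
  expect_equal(res$verdict, "conspecific")

  res0 <- species_membership_test(0, ref, method = "empirical")
  expect_equal(res0$p_value, 1)
  expect_equal(res0$verdict, "conspecific")

  # monotone non-increasing in d_obs
  ps <- vapply(seq(0, 0.01, 0.001), function(d)
    species_membership_test(d, ref, method = "empirical")$p_value, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("parametric tail matches Monte-Carlo resampling from the fit", {
  set.seed(21)
  ref <- rlnorm(200, meanlog = log(0.004), sdlog = 0.5)
  d_obs <- 0.012
  res <- species_membership_test(d_obs, ref, method = "parametric")
  # refit independently and resample
  ml <- mean(log(ref)); sl <- sqrt(mean((log(ref) - ml)^2))
  sim <- rlnorm(2e5, ml, sl)
  p_mc <- mean(sim >= d_obs)
  se <- sqrt(p_mc * (1 - p_mc) / 2e5)
  expect_lt(abs(res$p_value - p_mc), 4 * se + 1e-4)
  expect_match(res$method, "lognormal")
})

test_that("parametric method falls back to empirical below 5 references", {
  expect_warning(
    res <- species_membership_test(0.01, c(0.001, 0.002, 0.003),
                                   method = "parametric"),
    "empirical")
  expect_equal(res$method, "empirical")
})

test_that("a query far beyond the reference maximum is a novel candidate", {
  # the regime of the divergent isolate: observed 0.023 vs reference max 0.012
  set.seed(3)
  ref <- pmin(rlnorm(100, log(0.003), 0.8), 0.012)
  res <- species_membership_test(0.023, ref)
  expect_equal(res$verdict, "novel-species-candidate")
  emp <- species_membership_test(0.023, ref, method = "empirical")
  expect_equal(emp$p_value, 1 / 101)  # empirical floor: cannot go lower
})

test_that("closest_relative picks the minimum with lexicographic ties", {
  pd <- patristic_matrix(hand_tree)
  expect_equal(closest_relative(pd, "A"), list(tip = "B", distance = 3))
  tie <- parse_newick("((B:1,C:1):1,A:1);")
  pdt <- patristic_matrix(tie)
  expect_equal(closest_relative(pdt, "A")$tip, "B")  # B and C equidistant
  two <- patristic_matrix(parse_newick("(A:1,B:2);"))
  expect_equal(closest_relative(two, "A")$tip, "B")
  expect_error(closest_relative(pd, "Z"), "not in matrix")
})

test_that("robinson_foulds matches definitions on hand examples", {
  t1 <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- parse_newick("((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(robinson_foulds(t1, t1), 0)
  expect_equal(robinson_foulds(t1, t2), 2)
  expect_equal(robinson_foulds(t1, t2), robinson_foulds(t2, t1))

  t3 <- parse_newick("((A:1,B:1):1.5,(C:1,D:1):1);")
  expect_equal(robinson_foulds(t1, t3, weighted = TRUE), 0.5)
  expect_equal(robinson_foulds(t1, t1, weighted = TRUE), 0)
  expect_error(robinson_foulds(t1, parse_newick("(A:1,B:1);")), "tip sets")
})

test_that("RF behaves as a metric on all binary 5-tip topologies", {
  trees <- phangorn::allTrees(5, rooted = FALSE, tip.label = LETTERS[1:5])
  trees <- lapply(trees, function(t) { t$edge.length <- rep(1, nrow(t$edge)); t })
  n <- length(trees)
  expect_equal(n, 15)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    d[i, j] <- robinson_foulds(trees[[i]], trees[[j]])
  expect_true(all(diag(d) == 0))
  expect_true(all(d == t(d)))
  expect_true(all(d[upper.tri(d)] > 0))      # distinct topologies separated
  expect_true(max(d) <= 2 * (5 - 3))         # bound for binary unrooted trees
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(d[i, j], d[i, k] + d[k, j])
})

test_that("RF agrees with an independent implementation on random trees", {
  set.seed(13)
  for (i in 1:10) {
    nt <- sample(5:20, 1)
    t1 <- rand_bltree(nt)
    t2 <- rand_bltree(nt)
    t2$tip.label <- sample(t1$tip.label)
    expect_equal(robinson_foulds(t1, t2),
                 as.numeric(phangorn::RF.dist(t1, t2)))
    expect_equal(robinson_foulds(t1, t2, weighted = TRUE),
                 as.numeric(phangorn::wRF.dist(t1, t2)),
                 tolerance = 1e-9)
  }
})

test_that("dbscan_cluster implements density-based semantics", {
  # all pairwise distances above eps: everything is noise
  d <- matrix(1, 4, 4); diag(d) <- 0
  dimnames(d) <- list(letters[1:4], letters[1:4])
  expect_true(all(dbscan_cluster(d, eps = 0.03, min_neighbors = 2) == 0))

  # two tight blobs of 5: two clusters, no noise
  set.seed(5)
  pts <- rbind(matrix(rnorm(10, 0, 0.003), 5), matrix(rnorm(10, 1, 0.003), 5))
  d2 <- as.matrix(dist(pts))
  dimnames(d2) <- list(paste0("t", 1:10), paste0("t", 1:10))
  cl <- dbscan_cluster(d2, eps = 0.03, min_neighbors = 3)
  expect_equal(length(unique(cl)), 2)
  expect_true(all(cl > 0))
  expect_equal(length(unique(cl[1:5])), 1)
  expect_equal(length(unique(cl[6:10])), 1)

  # single item cannot be core with min_neighbors = 2
  d1 <- matrix(0, 1, 1, dimnames = list("x", "x"))
  expect_equal(unname(dbscan_cluster(d1, 0.03, 2)), 0L)

  expect_error(dbscan_cluster(d, eps = 0, min_neighbors = 2), "eps")
  expect_error(dbscan_cluster(d, eps = 1, min_neighbors = 0), "min_neighbors")
})

test_that("dbscan_cluster agrees with brute-force density reachability", {
  set.seed(17)
  for (rep in 1:10) {
    pts <- matrix(rnorm(40), 20, 2)
    d <- as.matrix(dist(pts))
    dimnames(d) <- list(paste0("p", 1:20), paste0("p", 1:20))
    eps <- runif(1, 0.3, 1.2)
    mp <- sample(2:4, 1)
    got <- dbscan_cluster(d, eps, mp)
    orc <- oracle_dbscan_partition(d, eps, mp)
    # cores: same partition up to relabeling
    core_ids <- which(orc$core)
    expect_equal(length(unique(got[core_ids])),
                 length(unique(orc$core_comp[core_ids])))
    relabel <- tapply(orc$core_comp[core_ids], got[core_ids],
                      function(x) length(unique(x)))
    expect_true(all(relabel == 1))
    # non-core points: noise iff unreachable, else in one reachable cluster
    for (i in setdiff(seq_len(20), core_ids)) {
      opts <- orc$border_opts[[i]]
      if (length(opts) == 0) {
        expect_equal(unname(got[i]), 0L)
      } else {
        expect_true(got[i] %in% got[core_ids][orc$core_comp[core_ids] %in% opts])
      }
    }
  }
})

test_that("dbscan labelling is stable under row permutation", {
  set.seed(19)
  pts <- rbind(matrix(rnorm(10, 0, 0.01), 5), matrix(rnorm(10, 3, 0.01), 5))
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("x", 1:10), paste0("x", 1:10))
  base <- dbscan_cluster(d, 0.1, 3)
  perm <- sample(10)
  shuffled <- dbscan_cluster(d[perm, perm], 0.1, 3)[names(base)]
  # same partition up to relabeling
  expect_equal(length(unique(base)), length(unique(shuffled)))
  expect_true(all(tapply(shuffled, base, function(x) length(unique(x))) == 1))
})

test_that("delimit_species recovers planted query truth end to end", {
  sim <- gen_species_tree(101, intra_scale = 0.005, inter_scale = 0.2)
  res <- delimit_species(sim$tree, sim$species_map, sim$queries$tip)
  got <- ifelse(res$verdict == "conspecific", "conspecific", "novel")
  expect_equal(got, sim$queries$truth)
})
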