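# Seeded generators emulating every input the pipeline consumes, each with
# planted ground truth. One global seed fans out to independent per-generator
# streams (derive_seed), so adding a generator never perturbs the draws of
# an existing one.

# random binary clade over pre-rendered Newick units (each already carrying
# its own ":length"); internal edges drawn exponential at the given scale
rand_clade <- function(units, scale) {
  if (length(units) == 1L) return(units)
  k <- sample.int(length(units) - 1L, 1L)
  pick <- sample.int(length(units), k)
  sprintf("(%s,%s):%.10f",
          rand_clade(units[pick], scale), rand_clade(units[-pick], scale),
          stats::rexp(1, 1 / scale))
}

render_tips <- function(labels, scale)
  sprintf("%s:%.10f", labels, stats::rexp(length(labels), 1 / scale))

#' Simulate a barcode tree with species structure and planted queries
#'
#' Builds species subtrees with exponential branch lengths at the
#' intraspecific scale, joined by a backbone at the (much larger)
#' interspecific scale, so intra- and inter-specific patristic distances live
#' on separated scales — the regime in which barcode-gap species delimitation
#' is expected to work. Two kinds of query tips with known truth are planted:
#' a conspecific query inside the first species (excluded from the species
#' map) and novel-species queries on their own backbone branches.
#'
#' @param seed integer seed; identical seeds give identical Newick strings.
#' @param n_species number of reference species (>= 2).
#' @param tips_per_species mapped tips per species (>= 2 so intraspecific
#'   distances exist).
#' @param intra_scale mean branch length inside species (SPB); default 0.005.
#' @param inter_scale mean backbone branch length (SPB); default 0.2.
#' @param n_conspecific,n_novel planted query counts; defaults 1 and 1.
#' @return list: `tree` (`"phylo"`), `species_map` (named character,
#'   reference tips only), `queries` (data.frame tip/truth with truth in
#'   `"conspecific"`, `"novel"`).
#' @export
gen_species_tree <- function(seed, n_species = 5L, tips_per_species = 4L,
                             intra_scale = 0.005, inter_scale = 0.2,
                             n_conspecific = 1L, n_novel = 1L) {
  if (n_species < 2L) stop_domain("gen_species_tree: need >= 2 species")
  if (tips_per_species < 2L)
    stop_domain("gen_species_tree: need >= 2 tips per species")
  if (intra_scale <= 0 || inter_scale <= 0)
    stop_domain("gen_species_tree: scales must be > 0")
  set.seed(derive_seed(seed, "species_tree"))

  species <- paste0("species", seq_len(n_species))
  tips <- lapply(seq_len(n_species), function(i)
    paste0("sp", i, "_t", seq_len(tips_per_species)))
  consp <- if (n_conspecific > 0) paste0("query_consp", seq_len(n_conspecific)) else character(0)
  tips[[1L]] <- c(tips[[1L]], consp)   # conspecific queries ride inside species 1
  novel <- if (n_novel > 0) paste0("query_novel", seq_len(n_novel)) else character(0)

  subclades <- vapply(tips, function(lb)
    rand_clade(render_tips(lb, intra_scale), intra_scale), character(1))
  # re-hang each species subtree from a backbone-scale stem edge
  stems <- inter_scale * stats::runif(n_species, 0.75, 1.25)
  units <- sub(":[0-9.]+$", "", subclades)
  units <- sprintf("%s:%.10f", units, stems)
  if (length(novel))
    units <- c(units, sprintf("%s:%.10f", novel,
                              inter_scale * stats::runif(length(novel), 0.75, 1.25)))
  backbone <- rand_clade(units, inter_scale)
  tree <- parse_newick(paste0(sub(":[0-9.]+$", "", backbone), ";"))

  species_map <- stats::setNames(
    rep(species, each = tips_per_species),
    unlist(lapply(seq_len(n_species), function(i)
      paste0("sp", i, "_t", seq_len(tips_per_species)))))
  queries <- data.frame(
    tip = c(consp, novel),
    truth = c(rep("conspecific", length(consp)), rep("novel", length(novel))),
    stringsAsFactors = FALSE)
  list(tree = tree, species_map = species_map, queries = queries)
}

#' Simulate replicate OD600 growth curves with planted origin labels
#'
#' Logistic trajectories plus additive Gaussian noise truncated at 0.
#' Beverage-like strains (and the control) share the control growth-rate
#' regime; the remaining strains get a shifted rate, emulating isolates that
#' were not selected for growth in wort. Replicates model independent
#' colonies: each draws its own rate around the strain regime.
#'
#' @param seed integer seed.
#' @param n_beverage,n_other strain counts in the two regimes; defaults 6 and 6.
#' @param replicates colonies per strain (>= 3); default 3.
#' @param times sampling times in hours; default `seq(0, 48, 2)`.
#' @param K,N0 logistic carrying capacity and inoculum (OD600); defaults 1.2,
#'   0.05.
#' @param r_control,r_other regime growth rates (per hour); defaults 0.5, 0.25.
#' @param noise_sd additive OD noise sd; default 0.02.
#' @param rep_sd between-colony sd of the rate; default 0.01.
#' @return list: `curves` (long data.frame strain/replicate/time_h/od600),
#'   `truth` (data.frame strain/beverage/r_regime; the control strain is
#'   `"control"`).
#' @export
gen_growth_curves <- function(seed, n_beverage = 6L, n_other = 6L,
                              replicates = 3L, times = seq(0, 48, 2),
                              K = 1.2, N0 = 0.05,
                              r_control = 0.5, r_other = 0.25,
                              noise_sd = 0.02, rep_sd = 0.01) {
  if (n_beverage < 1L || n_other < 1L)
    stop_domain("gen_growth_curves: need >= 1 strain per regime")
  if (replicates < 3L) stop_domain("gen_growth_curves: need >= 3 replicates")
  if (noise_sd < 0 || rep_sd < 0)
    stop_domain("gen_growth_curves: noise sds must be >= 0")
  set.seed(derive_seed(seed, "growth_curves"))

  truth <- data.frame(
    strain = c("control", paste0("bev", seq_len(n_beverage)),
               paste0("oth", seq_len(n_other))),
    beverage = c(TRUE, rep(TRUE, n_beverage), rep(FALSE, n_other)),
    r_regime = c(r_control, rep(r_control, n_beverage), rep(r_other, n_other)),
    stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    for (rep_i in seq_len(replicates)) {
      r <- truth$r_regime[i] + stats::rnorm(1, 0, rep_sd)
      od <- logistic_model(times, K, N0, r) + stats::rnorm(length(times), 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        strain = truth$strain[i], replicate = rep_i,
        time_h = times, od600 = pmax(od, 0), stringsAsFactors = FALSE)
    }
  }
  list(curves = do.call(rbind, rows), truth = truth)
}

#' Simulate a copy-number table with a planted directional signature
#'
#' All clusters start at the baseline copy number; each signature cluster is
#' perturbed one copy in its expected direction for isolate A with
#' probability `concordance_f`, and for isolate B otherwise, so the planted
#' concordance fraction of isolate A is `concordance_f`.
#'
#' @param seed integer seed.
#' @param n_clusters total ortholog clusters; default 596.
#' @param signature_size clusters carrying the beverage-yeast signature;
#'   default 79.
#' @param concordance_f probability a signature CNV favors isolate A;
#'   default 0.85.
#' @param baseline baseline copy number; default 2.
#' @param isolates the two isolate ids; default `c("A", "B")`.
#' @return list: `table` (2 x n_clusters integer matrix), `signature` (named
#'   direction vector), `truth` (data.frame cluster/direction/concordant).
#' @export
gen_cnv_table <- function(seed, n_clusters = 596L, signature_size = 79L,
                          concordance_f = 0.85, baseline = 2L,
                          isolates = c("A", "B")) {
  if (signature_size > n_clusters)
    stop_domain("gen_cnv_table: signature larger than cluster set")
  if (concordance_f < 0 || concordance_f > 1)
    stop_domain("gen_cnv_table: concordance_f must be in [0, 1]")
  set.seed(derive_seed(seed, "cnv_table"))

  clusters <- sprintf("og%04d", seq_len(n_clusters))
  tab <- matrix(as.integer(baseline), nrow = 2L, ncol = n_clusters,
                dimnames = list(isolates, clusters))
  sig_cl <- sort(sample(clusters, signature_size))
  dir <- sample(c("duplication", "deletion"), signature_size, replace = TRUE)
  to_a <- stats::runif(signature_size) < concordance_f
  for (i in seq_along(sig_cl)) {
    iso <- if (to_a[i]) 1L else 2L
    shift <- if (dir[i] == "duplication") 1L else -1L
    tab[iso, sig_cl[i]] <- tab[iso, sig_cl[i]] + shift
  }
  list(table = tab,
       signature = stats::setNames(dir, sig_cl),
       truth = data.frame(cluster = sig_cl, direction = dir,
                          concordant = ifelse(to_a, isolates[1L], isolates[2L]),
                          stringsAsFactors = FALSE))
}

#' Simulate binary isolation outcomes for two sample groups
#'
#' Bernoulli yeast recovery per sample at group-specific rates, emulating
#' screening putative beverage vessels against non-beverage controls
#' (control samples are spread over the control-vessel, sediment/stone and
#' off-site categories).
#'
#' @param seed integer seed.
#' @param n_beverage,n_control group sizes; defaults 21 and 110.
#' @param rate_beverage,rate_control per-sample recovery probabilities;
#'   defaults 6/21 and 2/110.
#' @return data.frame: `sample`, `site`, `category`, `yeast_recovered`.
#' @export
gen_isolation_samples <- function(seed, n_beverage = 21L, n_control = 110L,
                                  rate_beverage = 6 / 21,
                                  rate_control = 2 / 110) {
  if (n_beverage < 1L || n_control < 1L)
    stop_domain("gen_isolation_samples: group sizes must be >= 1")
  for (r in c(rate_beverage, rate_control))
    if (r < 0 || r > 1)
      stop_domain("gen_isolation_samples: rates must be in [0, 1]")
  set.seed(derive_seed(seed, "isolation_samples"))
  ctrl_cats <- c("control-vessel", "sediment/stone", "off-site")
  data.frame(
    sample = sprintf("s%03d", seq_len(n_beverage + n_control)),
    site = "synthetic-site",
    category = c(rep("putative-beverage", n_beverage),
                 rep_len(ctrl_cats, n_control)),
    yeast_recovered = c(stats::runif(n_beverage) < rate_beverage,
                        stats::runif(n_control) < rate_control),
    stringsAsFactors = FALSE)
}

#' Simulate a compound matrix with planted sample clusters
#'
#' Cluster-specific log-scale compound means plus lognormal measurement
#' noise. The `separation` parameter is the ratio of the between-cluster
#' spread of log-means to the log-noise sd; at 10x the planted clusters are
#' unambiguous, at 0 all samples share one profile.
#'
#' @param seed integer seed.
#' @param n_clusters planted sample clusters (>= 2); default 2.
#' @param samples_per_cluster samples per cluster (>= 2); default 4.
#' @param n_compounds compounds (>= 3); default 30.
#' @param separation between-cluster spread in units of the noise sd;
#'   default 10.
#' @param noise_sdlog lognormal noise sd (log scale); default 0.1.
#' @return list: `matrix` (samples x compounds), `clusters` (named integer,
#'   planted cluster per sample).
#' @export
gen_compound_matrix <- function(seed, n_clusters = 2L, samples_per_cluster = 4L,
                                n_compounds = 30L, separation = 10,
                                noise_sdlog = 0.1) {
  if (n_clusters < 2L || samples_per_cluster < 2L || n_compounds < 3L)
    stop_domain("gen_compound_matrix: need >= 2 clusters, >= 2 samples each, >= 3 compounds")
  if (separation < 0 || noise_sdlog < 0)
    stop_domain("gen_compound_matrix: separation and noise must be >= 0")
  set.seed(derive_seed(seed, "compound_matrix"))

  mu <- matrix(stats::rnorm(n_clusters * n_compounds, 0, separation * noise_sdlog),
               n_clusters, n_compounds)
  n <- n_clusters * samples_per_cluster
  cl <- rep(seq_len(n_clusters), each = samples_per_cluster)
  vals <- exp(mu[cl, , drop = FALSE] +
                matrix(stats::rnorm(n * n_compounds, 0, noise_sdlog), n, n_compounds))
  dimnames(vals) <- list(sprintf("sample%02d", seq_len(n)),
                         sprintf("compound%02d", seq_len(n_compounds)))
  list(matrix = vals, clusters = stats::setNames(cl, rownames(vals)))
}
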