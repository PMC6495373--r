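---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the models and procedures, the parameters that matter, what the synthetic
data does and does not emulate, and the choices made where the design was
genuinely open.

## Species delimitation by patristic distances

A barcode tree (here, LSU rRNA) with branch lengths in substitutions per
base (SPB) carries two distance scales: distances between conspecific tips
and distances between species. Given a species map for the reference tips,
`intraspecific_distances()` collects one patristic distance per same-species
tip pair; `species_membership_test()` then asks whether a query's distance
to its closest relative could have come from that distribution.

The membership test is deliberately available in two forms, and every
result records which was used:

* **empirical** — p = (#{x ≥ d_obs} + 1)/(n + 1). Exact and
  assumption-free, but bounded below by 1/(n+1): a query beyond the
  observed maximum cannot get a p smaller than the sample size allows.
* **parametric** (default) — the right tail of a maximum-likelihood
  lognormal (optionally gamma) fitted to the positive intraspecific
  distances. This extrapolates beyond the observed maximum, which is
  precisely the regime that matters for a divergent isolate: an observed
  distance of 0.023 SPB against a reference distribution whose maximum is
  0.012 SPB is only quantifiable by a fitted tail. With fewer than five
  positive reference values the fit is unreliable and the function falls
  back to the empirical rule with a warning.

The lognormal default reflects the shape of intraspecific distance
distributions (positive, right-skewed, multiplicative accumulation of
branch lengths); the gamma option is provided because neither family is
canonical. The verdict threshold `alpha` defaults to 0.05.

Patristic distances themselves are delegated to the cophenetic computation
of `ape` (a single traversal family); the test suite checks them against a
brute-force per-pair path-sum oracle and for rerooting invariance, at an
absolute tolerance of 1e-9.

## Intertree distances and conflict detection

`robinson_foulds()` computes the unweighted RF distance as the symmetric
difference of non-trivial bipartition sets on the unrooted trees.
Bipartitions are frozen as canonical tip sets: the side not containing a
fixed reference tip (the lexicographically first label). The weighted
variant sums |w1 − w2| over the union of bipartitions with absent
bipartitions contributing 0 and *includes terminal branches* — the
branch-score convention of standard implementations — so that trees of
identical topology but different tip lengths are separated. Whether raw or
normalized weights are wanted is exposed by a flag; raw is the default
because the downstream DBSCAN radius is calibrated on raw distances.

`dbscan_cluster()` implements density-based clustering over a precomputed
distance matrix (radius `eps`, core threshold `min_neighbors`, self
included). Cluster content is order-invariant; the one underdetermined
detail of DBSCAN — which cluster claims a border point reachable from two
cores — is made deterministic by processing items in sorted-id order.
A radius of 0.03 is the working value for weighted-RF gene-tree clustering
at the scale of single-gene yeast phylogenies.

## Alignment curation

* `centroid_dereplicate()` removes redundancy at an identity threshold
  (default 0.99). The greedy scheme processes sequences in decreasing
  length order (ties by id): each sequence joins the first centroid at or
  above the threshold, else founds a cluster. Pairwise identity is
  matches / aligned columns of a global Needleman–Wunsch alignment
  (match +1, mismatch 0, linear gap cost, end gaps penalized), gap–gap
  columns excluded, after uppercasing and folding U to T. The identity
  denominator is not universal across tools; this definition is documented
  here and fixed.
* `trim_gappy_columns()` removes a column iff its gap proportion strictly
  exceeds the threshold (default 0.8) — a column at exactly 0.8 is kept.
  Trimming is idempotent.
* `count_parsimony_informative()` requires at least two states each in at
  least two sequences; gaps are not a state.
* `filter_ortholog_occupancy()` rounds the reference fraction up
  (ceiling), treats the isolate minimum as an absolute count, and by
  default requires single-copy presence (`one_to_one = TRUE`), which
  excludes paralog-expanded clusters from phylogenomic matrices.

## Copy-number signatures

Between a pair of isolates, `signature_concordance()` restricts to
signature clusters whose copy numbers differ and credits, per cluster, the
isolate whose count lies in the expected direction — higher for an expected
duplication, lower for an expected deletion. Directionality is thus
evaluated *relative to the other isolate of the pair*, not against an
external baseline; an absolute-baseline reading is also defensible, but the
pairwise reading is the one that matches comparing a beer-producing isolate
against its non-producing sister.

The concordant/discordant split is tested by `neutral_split_chisq()`: a
1-df goodness-of-fit against the equal split (n/2, n/2), no continuity
correction by default. On a 67:12 split this closed form gives
χ² ≈ 38.29. Published analyses of this design have printed other values
under unstated expectation models; the equal split is the only expectation
the phrase "neutral" pins down, so numeric equality with any particular
printed χ² is not asserted anywhere in the package.

`signature_profile_ttest()` defaults to a paired t test across signature
clusters on per-cluster differences; all-zero differences report p = 1, a
nonzero constant difference has zero variance and errors with a pointer to
the Welch variant, and a Welch call on two exactly constant profiles
reports the degenerate exact answer rather than failing.

## Growth-curve fingerprinting

`fit_logistic()` fits N(t) = K / (1 + ((K − N0)/N0)·e^(−rt)) by
Levenberg–Marquardt least squares. Units: K and N0 in OD600, r per hour,
time in hours. Initialization is deterministic: K from the maximum
reading, N0 from the first reading clipped to ≥ 1e-6, r from the slope of
the logit-linearised fit log(N/(K − N)) over readings strictly inside
(0, K). Convergence: relative RSS change below 1e-10 or 500 iterations;
non-convergence returns the best point flagged. Constant series are flagged
degenerate (r unidentifiable) rather than erroring, so plate-scale batch
fits never abort. Optional blank correction (subtract first reading, clip
at 1e-6) is off by default since blanking regimes vary between labs.

Replicates (at least three colonies per strain) are fitted individually
and the replicate r values compared by a two-sided Welch t test
(`growth_rate_test()`), preserving between-colony variance rather than
fitting a mean curve. The similarity call uses a single alpha of 0.01: the
published two-threshold convention (similar above 0.01, different below
0.02) leaves (0.01, 0.02] ambiguous, so the raw p is always reported
alongside the call.

`pca_parameters()` performs covariance PCA of the centered (K, N0, r)
vectors — the stock `prcomp()` behaviour this analysis idiom is built on —
so the parameter with the largest spread dominates; under fermentation
screening that is the growth rate, which is the biologically discriminating
parameter. Standardized (correlation) PCA is available with `scale = TRUE`
for settings where the parameters should contribute equally; note that
standardization inflates pure-noise parameters to unit variance and can
drown a clear rate separation. Components are sign-fixed (largest-magnitude
loading positive) for reproducibility. Distances to the control strain in
score space, combined with the rate test, classify strains
(`distance_classify()`), and `origin_correlation()` reports the
point-biserial correlation of the negated distance with the binary
beverage-origin label, so beverage-like growth scores high. How such a
correlation is paired and signed is not canonical; the point-biserial
choice is documented rather than claimed unique.

## Isolation enrichment

`fisher_exact_2x2()` computes the exact hypergeometric tail with
log-factorial accumulation, stable for totals into the thousands. The
two-sided rule is the sum of all point probabilities not exceeding the
observed one (within 1e-7 relative slack) — the convention of mainstream
statistical software — with doubling-the-smaller-tail available by flag.
The test suite proves equality with complete margin-preserving enumeration
for every 2×2 table with grand total up to 60, and agreement with the stock
implementation on random larger tables. On recovery counts of 6/21 versus
2/110 the two-sided p is about 2 × 10⁻⁴ — comfortably significant; printed
values for this design differ slightly depending on how the underlying
sample table is grouped, so only the significance claim, not a specific
decimal, is asserted. Sample categories (putative-beverage, control-vessel,
sediment/stone, off-site) make the grouping an explicit, logged choice —
lamps and other edge categories can be included or excluded deliberately.

## Beverage analytics

Relative GC-MS peak areas normalize by the ethanol peak scaled by its
distillation-determined concentration, ×1000. Percent-of-max scaling puts
compounds on a common 0–100 scale; all-zero compounds are flagged, not
divided. Beer colour is linear in 430-nm absorbance (SRM = 12.7·A,
EBC = 25.0·A). Carbohydrate quantitation inverts an OLS calibration line of
485-nm absorbance on glucose standards (µg/ml), multiplies by the dilution
factor (1000 for 1 ml made up to 1 l) and reports g/l glucose equivalents;
readings outside the calibration range are flagged as extrapolated.

Clustering uses Ward's criterion on Euclidean distances in the `ward.D2`
convention (distances squared inside the criterion, merge heights on the
Euclidean scale, no inversions); the test suite checks the merge sequence
against a hand-rolled Lance–Williams oracle. Bootstrap support resamples
features (the non-clustered axis) with replacement: `bp` is the fraction of
bootstrap dendrograms containing the identical leaf set; `au` runs the
multiscale bootstrap at scale factors 0.5–1.4 of the feature count,
regresses the probit-transformed bootstrap probabilities on the scale
signature (v·σ + c/σ) and reports 1 − Φ(v − c). BP is the default, AU the
option, and both are reported per node with a flag at the conventional
\>95% strength; clades present in every replicate at every scale short-cut
to 100 rather than passing through a degenerate probit fit.

## Synthetic data: what it emulates, and what it does not

Each generator is a pure function of its seed (one global seed fans out to
independent per-generator streams, so adding a generator never perturbs
another's draws):

* `gen_species_tree()` — species subtrees with exponential branch lengths
  at the intra scale (default 0.005 SPB) under a backbone at the inter
  scale (default 0.2 SPB), plus planted conspecific and novel query tips.
  The defaults keep the two distance scales separated by ~40×, the regime
  the delimitation logic assumes; exponential lengths are a simplicity
  choice, not an evolutionary model.
* `gen_growth_curves()` — logistic trajectories, additive Gaussian OD noise
  (default sd 0.02) truncated at zero, three colonies per strain, two rate
  regimes (0.5 vs 0.25 per hour, between-colony sd 0.01).
* `gen_cnv_table()` — baseline copy number 2 everywhere; signature clusters
  (default 79 of 596) perturbed one copy in the expected direction toward
  isolate A with probability f (default 0.85), else toward B.
* `gen_isolation_samples()` — Bernoulli recovery at two group rates
  (defaults 6/21 and 2/110 over 21 and 110 samples).
* `gen_compound_matrix()` — cluster-specific log-normal compound profiles;
  `separation` is the ratio of between-cluster spread to log-noise sd.

What passing on these data shows is parameter recovery under the stated
generating model: clean logistic kinetics, independent Gaussian noise,
planted distance-scale separation, independent Bernoulli recovery. Real
data violate all of these in ways the generators deliberately do not
emulate — diauxic or lagged growth, heteroscedastic plate effects, rate
variation across a real phylogeny, site-level correlation in recovery,
compositional structure in GC-MS areas. Green tests certify the
implementation, not the biology.

## Numerical choices and problem sizes

Distance equality checks use 1e-9 absolute tolerance. Ties are broken
lexicographically (closest relative, DBSCAN processing order, Ward merge
candidates via the stock implementation's ordering). The test suite runs
the exhaustive exact-test sweep at grand totals ≤ 60, the patristic oracle
on 200 random trees of 4–50 tips, delimitation recovery over 20 seeds,
the logistic grid at r ∈ {0.2, 0.5, 1.0} × noise sd ∈ {0, 0.01, 0.05} with
50 replicates, CNV recovery over 20 seeds of 79-cluster signatures, and
bootstrap support at B = 1000 — sizes chosen to exercise the asymptotics
the methods rely on while staying comfortably reproducible on a laptop.

## Known limitations

Tree inference, alignment construction, orthology assignment and reference
retrieval are consumed as inputs, never performed. The AU implementation
follows the multiscale-bootstrap extrapolation recipe at desk scale and is
not a drop-in replacement for dedicated packages at publication scale. The
empirical membership rule saturates at 1/(n+1); the parametric rule's
accuracy depends on the fitted family far in the tail. Copy-number
concordance treats clusters, not genes; a per-cluster gene-multiplicity
weighting is a possible extension, off by default.
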