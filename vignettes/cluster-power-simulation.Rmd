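---
title: "Estimating statistical power for cluster analysis by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating statistical power for cluster analysis by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(powerclust)
```

## The question

A researcher planning a cluster analysis faces three questions that a
conventional power analysis does not answer: how likely is the pipeline to
detect that subgroups exist at all; how likely is it to select the correct
number of subgroups; and how accurately will observations be assigned to
their subgroup? `powerclust` treats all three as Monte-Carlo estimands. A
population with known subgroup structure is simulated many times at a given
sample size, the full analysis pipeline (optional dimensionality reduction,
clustering over a candidate-k grid, silhouette-based evaluation) is run on
every sample, and the three probabilities are estimated as observed
fractions.

## Generative model

Each subgroup is a multivariate normal distribution in *standardised space*:
every feature has standard deviation 1, so subgroup mean vectors are in
Cohen's-*d* units and covariance matrices are correlation matrices. The
separation between two subgroups is the Euclidean distance between their
centroids,

$$\Delta = \sqrt{\textstyle\sum_i \delta_i^2},$$

the quadrature sum of the per-feature standardised differences
$\delta_i$ — a multivariate analogue of Cohen's *d*
(`delta_from_effects()`). Two construction routes are provided:

* **Per-feature effects** (`feature_design()`, `make_mean_arrays()`): a
  common *d* on a chosen number of differing features. With two subgroups
  each differing feature contributes means $\pm d/2$, assigned in an
  independently shuffled order per feature; with three subgroups the middle
  subgroup sits at zero and the outer two receive $\pm d$. This emulates a
  planning scenario ("small effects on 20 of 100 features").
* **Direct centroid layouts** (`power_design()`,
  `make_equidistant_centroids()`): k = 1–4 equidistant centroids in two
  features at nearest-neighbour separation Δ — a single point, a pair, an
  equilateral triangle, or a square. Four mutually equidistant points do not
  exist in the plane; the square convention fixes the *nearest-neighbour*
  distance (the quantity detection depends on) at Δ, leaving diagonal pairs
  at Δ√2. All layouts are centred on the origin so the population grand
  mean is zero.

Correlation structure (`make_covariance()`) is `"none"` (identity),
`"random"` (off-diagonals uniform on [−0.3, 0.3]), or `"factor"`
(contiguous, near-equal blocks of features with within-block magnitudes
uniform on [0.4, 0.9], one random sign per block, and between-block entries
uniform on [−0.3, 0.3]); mixed designs give each subgroup its own structure.
Randomly filled correlation matrices can be indefinite, so matrices are
repaired by clipping negative eigenvalues at zero, reconstructing, and
rescaling to unit diagonal — a deterministic repair that approximately
preserves the intended block pattern. Factor-block assignment is contiguous
because nothing downstream depends on which features share a factor.

Subgroup sizes are deterministic (largest-remainder apportionment of
`weights * n`, ties to the lower index), not multinomially drawn: a "10/90%"
population at N = 100 is exactly 10 and 90. This matches the fixed-percentage
framing of the study designs and removes one source of Monte-Carlo noise;
`simulate_dataset()` errors if any subgroup would receive zero observations
rather than silently dropping a subgroup.

## Pipeline stages

**Reduction** (`reduce_dims()`): `"none"`, metric MDS, or UMAP
(`uwot::umap()` with default neighbourhood parameters, 2 components,
seeded). MDS deserves a note: classical principal-coordinate scaling is an
orthogonal projection and can only shrink pairwise distances, which would
make 2-D separations systematically *under*-read the design Δ. The package
instead minimises raw stress by SMACOF majorisation (uniform weights, 4
random starts, convergence when the relative stress drop falls below 1e-3,
at most 300 iterations, best stress kept), which preserves the distance
scale; on feature-rich designs the test suite asserts the resulting
embedded separation is at least the original-space separation in a majority
of designs. Perfectly 2-D input is reproduced up to rigid motion to
numerical precision.

**Clustering adapters** return either hard partitions (integer labels, `NA`
for observations an algorithm leaves unassigned) or row-stochastic
membership matrices:

* `run_kmeans()` — `stats::kmeans()` with 10 random restarts (best
  within-cluster sum of squares kept; restarts make the Hartigan–Wong and
  Lloyd solutions coincide in practice at these sample sizes). `k = N`
  returns the trivial all-singletons partition directly.
* `run_agglomerative()` — Ward on Euclidean distances (`ward.D2`, the
  squared-increment form matching the usual Ward criterion) or average
  linkage on cosine dissimilarity; deterministic.
* `run_hdbscan()` — implemented natively (no R implementation of HDBSCAN
  was available to build on): core distances at `min_samples` neighbours,
  mutual-reachability distances, a Prim minimum spanning tree, the
  single-linkage hierarchy, a condensed tree pruned at `min_cluster_size`,
  and excess-of-mass selection by stability. The whole-sample root is never
  selected, so unstructured data yields zero clusters; samples with
  $N \le 2\,\texttt{min\_cluster\_size}$ are below the resolvable size and
  return an all-unassigned partition. The test suite pins the
  implementation to reference labelings (noise set and assigned partition)
  on frozen fixtures.
* `run_cmeans()` — fuzzy c-means via `e1071::cmeans()` with fuzzifier
  m = 2, the conventional default (exposed as an argument).
* `run_gmm()` — a full-covariance Gaussian mixture fitted by EM with one
  run initialised from k-means centroids (hard assignments as starting
  responsibilities), a 1e-6 ridge on covariance diagonals, and convergence
  when the mean log-likelihood changes by less than 1e-3 (at most 100
  iterations). The initialisation and stopping rule were chosen to match
  common practice for mixture-based cluster scans; a model-based
  hierarchical initialisation run to tight convergence produces noticeably
  fuzzier posteriors on overlapping components, which materially lowers
  fuzzy-silhouette detection near the threshold. BIC is returned as
  $-2\ell + p\log N$ (lower is better); collapsed fits (empty or singular
  components) are reported as failed and excluded from model selection with
  a warning.

**Evaluation** (`silhouette_score()`, `fuzzy_silhouette()`,
`adjusted_rand()`, `classification_accuracy()`): the silhouette uses mean
pairwise Euclidean distances (the classical Rousseeuw definition) rather
than distances to centroids; the simplified centroid form runs
systematically higher and would shift every detection threshold. Singleton
clusters contribute a width of 0, and unassigned observations are excluded
(`n_used` reports how many entered the mean). The fuzzy silhouette weights
each observation's crisp width by $(\mu_p - \mu_q)^\alpha$, the gap between
its two largest memberships; α = 0 (or a crisp membership matrix) recovers
the plain silhouette exactly, and exactly tied memberships get weight 0, so
maximally ambiguous observations contribute nothing. ARI excludes
unassigned predictions from the contingency table (mirroring the
silhouette's exclusion rule), whereas classification accuracy counts them
as errors — detection metrics should not reward an algorithm for refusing
to assign, but accuracy must. Accuracy is maximised over one-to-one
cluster-to-subgroup assignments (Hungarian matching on the padded confusion
matrix) and reported next to its chance level, the largest subgroup's share
of the sample.

## The decision rule and the power engine

`decision_rule()` holds the detection parameters: silhouette threshold 0.5
(0.7 for strong evidence), candidate grid k = 2..5 by default (2..7 in the
matched method comparison), fuzzy exponent α = 1. For k-requiring
algorithms, `detect_clustering()` fits every k in the grid, scores hard
partitions with the plain silhouette and soft ones with the fuzzy
silhouette, and selects the maximum score; ties resolve to the smallest k,
and degenerate fits (fewer than two populated clusters, collapsed mixtures)
score `NA` and drop out. HDBSCAN is fit once and reports its own k; fewer
than two found clusters means "not clustered". The detection decision uses
the maximum score over the grid — not the score at the true k, which a
blinded analyst cannot know — so k-selection and detection are mutually
consistent.

`estimate_power()` aggregates `n_iterations` independent
simulate-then-detect runs into power, k-accuracy (share of iterations whose
selected k equals the true k), mean classification accuracy at the selected
k (computed even when the selected k is wrong — surplus clusters absorb
errors), and mean best silhouette. `power_grid()` maps this over a (Δ × N)
grid; `compare_methods()` runs k-means, c-means, and the Gaussian mixture on
the *same* simulated datasets per iteration, which removes between-method
sampling noise from their comparison, and additionally records whether the
BIC-minimising component count equals the true k. With a single-subgroup
design the reported "power" is the false-positive rate, and
`union_detection_rate()` gives the fraction of iterations on which *any*
method crossed the threshold.

Every source of randomness flows from one master seed. Child seeds are
derived by a counter scheme (LCG steps interleaved with xorshift
scrambling, all below 2³¹) so that any cell or iteration can be recomputed
in isolation; an early affine-only derivation produced arithmetic
progressions of seeds whose generator streams were visibly correlated
across master seeds, which the scrambling rounds eliminate. Identical
configuration and seed reproduce every table bit for bit.

## Problem sizes

The packaged replications use the study conditions themselves: 100
iterations per power cell; two-feature populations at N = 10–160 for the
power tables; N = 120 with candidate grid 2..7 for the matched comparison;
N = 80 for the HDBSCAN cells. Distributional invariants (separation and
covariance recovery) are checked at N = 20 000, where sampling error on a
centroid distance is below 0.05. Trend-level checks (MDS exaggeration, UMAP
shrinkage at small Δ) use 200–400 observations and majority votes over
design grids, reflecting that stress- and manifold-based embeddings are
stochastic. These sizes are the package's own test design, chosen to match
the simulation conditions being replicated.

## What the generator does and does not emulate

The generator produces exactly the conditions the power estimates are
defined for: Gaussian subgroups with unit feature SDs, equidistant
centroids, at most moderate correlation, fixed subgroup proportions. Real
biomedical data violate most of these in some degree — skewed and
heavy-tailed features, measurement error that inflates within-subgroup
spread, unequal and unknown subgroup proportions, non-Gaussian cluster
shapes that favour density-based methods, and missing data (out of scope
here). A passing power replication therefore says the *pipeline* behaves as
specified under the stated model, not that a given real dataset carries that
model. Users should treat the power tables as planning estimates under a
best-case generative model, and re-run `power_grid()` with the covariance
model and weights closest to their own setting.

## Known limitations

* **Silhouette definition.** The literature is ambiguous between
  mean-pairwise and centroid-based per-observation silhouettes. This
  package uses the mean-pairwise (Rousseeuw) form everywhere, including
  inside the fuzzy silhouette. Centroid-based scores run higher,
  particularly with three or more clusters, so fuzzy-silhouette detection
  rates at intermediate separations (Δ ≈ 3) are conservative relative to
  analyses that used the centroid form; the matched-comparison mixture
  results are the most affected.
* **HDBSCAN parameterisation.** Density-based detection rates are highly
  sensitive to `min_cluster_size` (default 5, exposed in the API and
  config). Published HDBSCAN power values rarely state it, so HDBSCAN
  cells should be read with a wider tolerance than the k-means/c-means
  ones.
* **UMAP variability.** UMAP embeddings are non-linear and seed-dependent;
  only trend-level statements (separation shrinks below Δ ≈ 3, inflates
  above Δ ≈ 5) are supported, not numeric reproduction of embedded
  separations.
* **Scale.** All distance computations are O(N²) in memory or time;
  the engine targets the N ≤ a-few-thousand regime of power simulation,
  not embedding or clustering of very large datasets.

## A minimal session

```{r example, eval = FALSE}
library(powerclust)

# expected separation for a planned 100-feature study
delta_from_effects(c(rep(0.3, 20), rep(0.5, 12), rep(0.8, 4), rep(0, 64)))

# power of k-means detection around that regime
pt <- power_grid(k = 2, delta = 2:5, n = c(10, 20, 40),
                 algorithm = "kmeans", n_iterations = 100, seed = 42)
format_power_table(pt)
autoplot(pt)

# fuzzy clustering at the same design, same seeds, for comparison
cm <- power_grid(k = 2, delta = 2:5, n = c(10, 20, 40),
                 algorithm = "cmeans", n_iterations = 100, seed = 42)

# matched three-method comparison on shared data
cmp <- compare_methods(k_true = 2, delta = c(2, 3, 4), n = 120,
                       n_iterations = 100, seed = 42)
autoplot(cmp)
```
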