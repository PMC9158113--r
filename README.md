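# powerclust

Simulation-based statistical power analysis for cluster analysis.

Cluster algorithms (k-means, hierarchical clustering, HDBSCAN, fuzzy c-means,
Gaussian mixture models) are increasingly used in biomedical research to find
discrete subgroups — patient subtypes, behavioural phenotypes, responder
classes — in multivariate data. Unlike for t-tests or regressions, there is no
established way to compute a priori statistical power for such analyses: how
likely is a given pipeline to *detect* that subgroups exist at all, to select
the right number of subgroups, and to classify observations correctly, given a
sample size and an expected subgroup separation? `powerclust` answers these
questions by Monte-Carlo simulation, for researchers planning a study (e.g. a
preregistration) that will include a cluster analysis.

## The model

Subgroups are modelled as multivariate normal distributions in standardised
space (all feature SDs equal 1). Their separation is the multivariate effect
size Δ, the Euclidean distance between subgroup centroids, which accumulates
per-feature standardised differences (Cohen's *d*) in quadrature:

Δ = √(Σᵢ δᵢ²)

so many small per-feature effects can add up to a large multivariate
separation. A pipeline *detects* clustering when the silhouette coefficient of
its best solution — maximised over a candidate-k grid — reaches 0.5 (0.7 for
strong evidence). Soft partitions (c-means memberships, mixture posteriors)
are scored with the fuzzy silhouette, which weights each observation's crisp
silhouette width *s* by (μₚ − μ_q)^α, the gap between its two largest
membership weights. Statistical power is the fraction of simulated datasets on
which the pipeline detects clustering; cluster-number accuracy is the fraction
on which the silhouette-maximising k (or BIC-minimising k, for mixtures)
equals the true subgroup count; classification accuracy is the proportion of
observations assigned to their true subgroup under optimal label matching,
with chance set at the largest subgroup's share of the sample.

The toolkit covers population design (per-feature effect sizes or direct
equidistant centroid layouts for k = 1–4; none/random/factor correlation
structures), dimensionality reduction (none, metric MDS by SMACOF stress
majorisation, UMAP), clustering adapters (k-means, Ward and average-cosine
agglomerative, HDBSCAN — implemented natively, with noise points excluded
from evaluation — c-means, full-covariance Gaussian mixtures), validity
metrics (silhouette, fuzzy silhouette, adjusted Rand index, matched
classification accuracy), and a seeded Monte-Carlo engine for power tables
over (Δ × N) grids and matched discrete-vs-fuzzy method comparisons.

## Worked example

Suppose you plan to measure 100 features in a population you believe splits
into two equally sized subgroups, with small differences (*d* = 0.3) on 20
features, medium (*d* = 0.5) on 12, and large (*d* = 0.8) on 4:

```r
library(powerclust)
delta_from_effects(c(rep(0.3, 20), rep(0.5, 12), rep(0.8, 4), rep(0, 64)))
#> [1] 2.712932
```

The expected separation is Δ ≈ 2.7 — a regime where detection is far from
guaranteed. Power for k-means detection near that separation, as a function
of sample size (100 iterations per cell, integer percentages):

```r
pt <- power_grid(k = 2, delta = c(2, 3, 4, 5), n = c(10, 20, 40),
                 algorithm = "kmeans", n_iterations = 100, seed = 42)
format_power_table(pt)
#> # A tibble: 3 × 8
#>   algorithm k_true weights     n `delta=2` `delta=3` `delta=4` `delta=5`
#>   <chr>      <int> <chr>   <int>     <dbl>     <dbl>     <dbl>     <dbl>
#> 1 kmeans         2 50/50      10        39        68        85        99
#> 2 kmeans         2 50/50      20        14        52        94       100
#> 3 kmeans         2 50/50      40         1        37        98       100
```

Power is driven by separation far more than by sample size: at Δ = 2 more
data actually *lowers* detection (larger samples make the single merged
ellipsoid more obvious), while from Δ = 4 about 20 observations per subgroup
already give >90% power. `autoplot(pt)` draws the corresponding power curves,
and swapping `algorithm = "cmeans"` shows the fuzzy-clustering advantage at
intermediate separations.

One-shot analysis of a dataset (here the packaged demo, two subgroups at
Δ = 10) reports the verdict a blinded analyst would reach:

```r
demo <- read_dataset(system.file("extdata", "demo-two-clusters.csv",
                                 package = "powerclust"))
detect_clustering(demo, "kmeans", seed = 1)
#> <clustering_outcome> kmeans: clustered (strong evidence)
#>   best k = 2, silhouette = 0.8404 (thresholds 0.5 / 0.7)
#>   vs ground truth: ARI = 1.000, accuracy = 1.000 (chance 0.500)
```

`tidy()` and `glance()` return the per-k score table and a one-row summary.
A thin command-line front end over the same functions lives at
`inst/scripts/powerclust` (subcommands `simulate`, `power`, `detect`, driven
by a YAML run configuration; see `inst/extdata/example-config.yaml`).

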