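# Example run configuration: power of k-means for two equally sized
# subgroups over a small effect-size / sample-size grid.
design:
  k: 2
  weights: [0.5, 0.5]
  delta: 4          # used by `simulate` and `detect`; `power` uses monte_carlo.delta
  covariance: none
pipeline:
  reduction: none
  algorithm: kmeans
  min_cluster_size: 5
  rule:
    silhouette_threshold: 0.5
    strong_threshold: 0.7
    k_min: 2
    k_max: 5
    alpha: 1
monte_carlo:
  sample_sizes: [10, 20, 40]
  delta: [2, 4, 6]
  iterations: 25
  seed: 42
output:
  dir: powerclust-results
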