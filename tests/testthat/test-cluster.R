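test_that("k-means recovers well-separated blobs and degenerate cases", {
  d <- two_blob_data(n_per = 25, delta = 10, seed = 1)
  p <- run_kmeans(d, 2, seed = 1)
  expect_equal(adjusted_rand(d$.cluster, p), 1)
  expect_equal(p$n_clusters, 2L)
  expect_false(anyNA(p$labels))

  # k = N: every observation its own cluster
  small <- d[seq(1, 50, by = 10), ]
  pN <- run_kmeans(small, nrow(small), seed = 1)
  expect_equal(pN$n_clusters, nrow(small))
  expect_error(run_kmeans(small, 10), "between 1 and")
})

test_that("k-means classifies a separated 3-subgroup design accurately", {
  d <- simulate_dataset(power_design(3, 4), 600, seed = 2)
  p <- run_kmeans(d, 3, seed = 2)
  expect_gte(adjusted_rand(d$.cluster, p), 0.8)
})

test_that("agglomerative flavours behave deterministically and sensibly", {
  d <- two_blob_data(n_per = 20, delta = 8, seed = 3)
  expect_equal(adjusted_rand(d$.cluster, run_agglomerative(d, 2)), 1)
  expect_identical(run_agglomerative(d, 3), run_agglomerative(d, 3))

  # duplicated points merge first: they always share a cluster
  X <- rbind(c(0, 0), c(0, 0), c(5, 5), c(9, 0))
  p <- run_agglomerative(X, 3)
  expect_equal(p$labels[1], p$labels[2])

  cosd <- run_agglomerative(d, 2, "average_cosine")
  expect_equal(cosd$n_clusters, 2L)
  expect_error(run_agglomerative(rbind(c(0, 0), c(1, 1), c(2, 2)), 2,
                                 "average_cosine"), "zero-vector")
})

test_that("ward agglomerative tracks k-means on simulated designs", {
  ari_gap <- vapply(1:8, function(i) {
    d <- simulate_dataset(power_design(2, 3 + i %% 3), 120, seed = 500 + i)
    a_km <- adjusted_rand(d$.cluster, run_kmeans(d, 2, seed = i))
    a_wd <- adjusted_rand(d$.cluster, run_agglomerative(d, 2))
    abs(a_km - a_wd)
  }, 1)
  expect_lt(mean(ari_gap), 0.1)
})

test_that("c-means memberships are row-stochastic with sensible limits", {
  d <- two_blob_data(n_per = 25, delta = 10, seed = 4)
  p <- run_cmeans(d, 2, seed = 4)
  expect_lt(max(abs(rowSums(p$U) - 1)), 1e-9)
  expect_equal(adjusted_rand(d$.cluster, p$hard_labels), 1)
  expect_identical(run_cmeans(d, 2, seed = 9)$U, run_cmeans(d, 2, seed = 9)$U)
  expect_error(run_cmeans(d, 2, m = 1), "must be > 1")

  # membership symmetry: a point equidistant from two point-mass clusters
  X <- rbind(matrix(rep(c(-2, 0), 10), ncol = 2, byrow = TRUE),
             matrix(rep(c(2, 0), 10), ncol = 2, byrow = TRUE), c(0, 0))
  pm <- run_cmeans(X, 2, seed = 5)
  expect_equal(unname(pm$U[21, ]), c(0.5, 0.5), tolerance = 0.02)
  # points sitting on a converged centroid belong to it almost fully
  expect_gt(max(pm$U[1, ]), 0.97)
})

test_that("the mixture EM fits match an independent implementation", {
  skip_if_not_installed("mclust")
  mclustBIC <- mclust::mclustBIC  # Mclust() resolves this in the caller's frame
  d <- two_blob_data(n_per = 60, delta = 8, seed = 6)
  X <- as.matrix(d[paste0("f", 1:2)])
  fit <- run_gmm(X, 2, seed = 6)
  ref <- mclust::Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE)
  # both should find the same (global) optimum on a well-separated instance
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-3)
  expect_equal(fit$bic, -as.numeric(ref$bic), tolerance = 0.05)
  expect_equal(adjusted_rand(ref$classification, fit$hard_labels), 1)
})

test_that("mixture posteriors behave across component counts", {
  d <- two_blob_data(n_per = 60, delta = 10, seed = 7)
  one <- run_gmm(d, 1)
  expect_equal(unname(one$U[, 1]), rep(1, 120))

  two <- run_gmm(d, 2, seed = 7)
  expect_lt(max(abs(rowSums(two$U) - 1)), 1e-9)
  expect_gt(mean(apply(two$U, 1, max)), 0.99)  # near 0/1 posteriors

  # BIC prefers the true component count over a heavily over-fitted one
  d6 <- simulate_dataset(power_design(2, 6), 600, seed = 8)
  expect_lt(run_gmm(d6, 2, seed = 8)$bic, run_gmm(d6, 5, seed = 8)$bic)
})

test_that("partitions constructed from invalid memberships are rejected", {
  expect_error(fuzzy_partition(matrix(c(0.7, 0.7, 0.2, 0.2), 2)), "sum to 1")
  expect_error(fuzzy_partition(matrix(c(1.2, -0.2, 0.5, 0.5), 2, byrow = TRUE)),
               "\\[0, 1\\]")
})
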