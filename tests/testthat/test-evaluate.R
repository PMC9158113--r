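test_that("silhouette matches hand-worked and brute-force values", {
  # two duplicated-point clusters far apart: perfect cohesion, score 1
  X <- rbind(c(0, 0), c(0, 0), c(9, 9), c(9, 9))
  expect_equal(silhouette_score(X, c(1, 1, 2, 2))$score, 1)

  # two tight pairs: a = 1, b = (10 + sqrt(101))/2 for every point
  X4 <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  b <- (10 + sqrt(101)) / 2
  expect_equal(silhouette_score(X4, c(1, 1, 2, 2))$score, (b - 1) / b)
  expect_equal(round(silhouette_score(X4, c(1, 1, 2, 2))$score, 3), 0.9)

  # brute-force oracle agreement on random instances
  withr::with_seed(21, {
    for (i in 1:5) {
      X <- matrix(rnorm(40 * 3), 40)
      labels <- sample(1:3, 40, replace = TRUE)
      expect_equal(silhouette_score(X, labels)$score,
                   mean(oracle_silhouette(X, labels)))
    }
  })
})

test_that("silhouette agrees with the classical reference implementation", {
  skip_if_not_installed("cluster")
  withr::with_seed(22, {
    X <- matrix(rnorm(60 * 2), 60)
    labels <- sample(1:4, 60, replace = TRUE)
    ref <- mean(cluster::silhouette(labels, dist(X))[, "sil_width"])
    expect_equal(silhouette_score(X, labels)$score, ref)
  })
})

test_that("unassigned observations are excluded from the silhouette", {
  d <- two_blob_data(n_per = 20, delta = 8, seed = 23)
  labels <- d$.cluster
  labels[c(1, 25)] <- NA
  res <- silhouette_score(d, labels)
  expect_equal(res$n_used, 38)
  expect_equal(res$score,
               silhouette_score(as.matrix(d[paste0("f", 1:2)])[-c(1, 25), ],
                                d$.cluster[-c(1, 25)])$score)
})

test_that("silhouettes are invariant to rigid motion and relabelling", {
  d <- simulate_dataset(power_design(3, 3), 90, seed = 24)
  X <- as.matrix(d[paste0("f", 1:2)])
  labels <- run_kmeans(X, 3, seed = 1)$labels
  s0 <- silhouette_score(X, labels)$score
  expect_equal(silhouette_score(rigid_motion(X), labels)$score, s0, tolerance = 1e-9)
  relab <- c(3L, 1L, 2L)[labels]
  expect_equal(silhouette_score(X, relab)$score, s0)

  U <- run_cmeans(X, 3, seed = 2)$U
  f0 <- fuzzy_silhouette(X, fuzzy_partition(U))$score
  expect_equal(fuzzy_silhouette(rigid_motion(X), fuzzy_partition(U))$score, f0,
               tolerance = 1e-9)
  expect_equal(fuzzy_silhouette(X, fuzzy_partition(U[, c(2, 3, 1)]))$score, f0)
})

test_that("fuzzy silhouette reduces to the plain silhouette when crisp or alpha 0", {
  withr::with_seed(25, {
    for (i in 1:5) {
      d <- simulate_dataset(power_design(2, 3), 50, seed = 300 + i)
      X <- as.matrix(d[paste0("f", 1:2)])
      labels <- run_kmeans(X, 2, seed = i)$labels
      crisp <- matrix(0, 50, 2)
      crisp[cbind(1:50, labels)] <- 1
      plain <- silhouette_score(X, labels)$score
      expect_equal(fuzzy_silhouette(X, fuzzy_partition(crisp), alpha = 1)$score,
                   plain)
      U <- run_cmeans(X, 2, seed = i)$U
      expect_equal(fuzzy_silhouette(X, fuzzy_partition(U), alpha = 0)$score,
                   silhouette_score(X, max.col(U, ties.method = "first"))$score)
    }
  })
})

test_that("fuzzy silhouette weights observations by their membership gap", {
  # third point has tied memberships and must contribute nothing
  X <- rbind(c(0, 0), c(4, 0), c(2, 3))
  U <- rbind(c(0.9, 0.1), c(0.4, 0.6), c(0.5, 0.5))
  s <- oracle_silhouette(X, c(1, 2, 1))
  expected <- (0.8 * s[1] + 0.2 * s[2]) / (0.8 + 0.2)
  expect_equal(fuzzy_silhouette(X, fuzzy_partition(U))$score, expected)
})

test_that("adjusted Rand index matches its definition", {
  truth <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_rand(truth, truth), 1)
  expect_equal(adjusted_rand(truth, c(3, 3, 1, 1, 2, 2)), 1)  # pure relabelling
  pred <- c(1, 1, 2, 3, 3, 3)
  expect_equal(adjusted_rand(truth, pred), oracle_ari(truth, pred))

  skip_if_not_installed("mclust")
  withr::with_seed(26, {
    for (i in 1:5) {
      a <- sample(1:3, 30, replace = TRUE)
      b <- sample(1:4, 30, replace = TRUE)
      expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b))
    }
  })
})

test_that("random labelings score an ARI near zero on average", {
  withr::with_seed(27, {
    vals <- replicate(1000, {
      adjusted_rand(sample(1:3, 200, replace = TRUE),
                    sample(1:3, 200, replace = TRUE))
    })
  })
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("classification accuracy uses optimal matching and counts NA as errors", {
  truth <- rep(1:2, each = 50)
  expect_equal(classification_accuracy(truth, truth)$accuracy, 1)
  swapped <- c(2L, 1L)[truth]
  expect_equal(classification_accuracy(truth, swapped)$accuracy, 1)

  pred <- swapped
  pred[c(1:4, 51:53)] <- NA  # 7 unassigned count against accuracy
  res <- classification_accuracy(truth, pred)
  expect_equal(res$accuracy, 0.93)
  expect_equal(res$chance, 0.5)
  expect_equal(res$n_unassigned, 7L)

  # the majority-vote predictor scores exactly the chance level
  truth2 <- rep(1:3, times = c(60, 25, 15))
  res2 <- classification_accuracy(truth2, rep(1L, 100))
  expect_equal(res2$accuracy, res2$chance)

  # brute-force permutation oracle, including surplus predicted clusters
  withr::with_seed(28, {
    for (i in 1:5) {
      t <- sample(1:3, 40, replace = TRUE)
      p <- sample(1:5, 40, replace = TRUE)
      expect_equal(classification_accuracy(t, p)$accuracy, oracle_accuracy(t, p))
    }
  })
})
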