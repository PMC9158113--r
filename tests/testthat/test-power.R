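test_that("detection selects the true k on separable data", {
  d <- two_blob_data(n_per = 80, delta = 10, seed = 31)
  out <- detect_clustering(d, "kmeans", seed = 31)
  expect_true(out$is_clustered)
  expect_true(out$is_strong)
  expect_equal(out$best_k, 2L)
  expect_equal(out$accuracy, 1)

  # two point-mass clusters: silhouette exactly 1
  X <- rbind(matrix(rep(c(0, 0), 10), ncol = 2, byrow = TRUE),
             matrix(rep(c(4, 0), 10), ncol = 2, byrow = TRUE))
  out_pm <- detect_clustering(X, "kmeans", seed = 1)
  expect_equal(out_pm$best_silhouette, 1)
  expect_true(out_pm$is_clustered)

  g <- glance(out)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$best_k, 2L)
  td <- tidy(out)
  expect_equal(td$k, 2:5)
  expect_equal(sum(td$selected), 1L)
})

test_that("fuzzy algorithms are scored with the fuzzy silhouette", {
  d <- simulate_dataset(power_design(2, 3), 120, seed = 32)
  cm <- detect_clustering(d, "cmeans", seed = 32)
  U <- run_cmeans(d, cm$best_k, seed = powerclust:::derive_seed(32, cm$best_k))
  expect_equal(cm$best_silhouette, fuzzy_silhouette(d, U)$score)
})

test_that("estimate_power is reproducible and seed-sensitive", {
  design <- power_design(2, 4)
  a <- estimate_power(design, 20, "kmeans", n_iterations = 10, seed = 5)
  b <- estimate_power(design, 20, "kmeans", n_iterations = 10, seed = 5)
  expect_identical(a, b)
  c <- estimate_power(design, 20, "kmeans", n_iterations = 10, seed = 6)
  expect_false(identical(a$mean_silhouette, c$mean_silhouette))
})

test_that("raising the silhouette threshold never increases power", {
  design <- power_design(2, 4)
  loose <- estimate_power(design, 20, "kmeans",
                          rule = decision_rule(silhouette_threshold = 0.5),
                          n_iterations = 40, seed = 7)
  strict <- estimate_power(design, 20, "kmeans",
                           rule = decision_rule(silhouette_threshold = 0.7),
                           n_iterations = 40, seed = 7)
  expect_lte(strict$power, loose$power)
})

test_that("power rises monotonically with separation", {
  pt <- power_grid(k = 2, delta = 1:6, n = 40, algorithm = "kmeans",
                   n_iterations = 30, seed = 8)
  expect_gte(cor(pt$power, pt$delta, method = "spearman"), 0.8)
})

test_that("power tables format into the wide percentage layout", {
  pt <- power_grid(k = 2, delta = c(2, 6), n = c(10, 20), algorithm = "kmeans",
                   n_iterations = 5, seed = 9)
  expect_equal(nrow(pt), 4)
  expect_true(all(pt$power >= 0 & pt$power <= 1))
  wide <- format_power_table(pt)
  expect_equal(names(wide), c("algorithm", "k_true", "weights", "n",
                              "delta=2", "delta=6"))
  expect_true(all(wide$`delta=6` %in% 0:100))

  # single-iteration cells are exact 0/1 fractions
  p1 <- power_grid(k = 2, delta = 4, n = 20, algorithm = "kmeans",
                   n_iterations = 1, seed = 10)
  expect_true(all(p1$power %in% c(0, 1)))

  p <- autoplot(pt)
  expect_s3_class(p, "ggplot")
})

test_that("matched comparisons share data across methods and stay reproducible", {
  cmp <- suppressWarnings(
    compare_methods(k_true = 2, delta = 6, n = 60, n_iterations = 5, seed = 11)
  )
  expect_setequal(cmp$method, c("kmeans", "cmeans", "gmm"))
  log <- attr(cmp, "per_iteration")
  expect_equal(nrow(log), 15)
  # strong separation: every method detects in every iteration
  expect_true(all(cmp$power == 1))
  expect_equal(union_detection_rate(cmp)$any_power, 1)

  cmp2 <- suppressWarnings(
    compare_methods(k_true = 2, delta = 6, n = 60, n_iterations = 5, seed = 11)
  )
  expect_identical(as.data.frame(cmp), as.data.frame(cmp2))
  expect_s3_class(autoplot(cmp), "ggplot")
})

test_that("fuzzy detection is at least as powerful as discrete at moderate separation", {
  km <- estimate_power(power_design(2, 3), 40, "kmeans", n_iterations = 40, seed = 12)
  cm <- estimate_power(power_design(2, 3), 40, "cmeans", n_iterations = 40, seed = 12)
  expect_gte(cm$power, km$power)
})
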