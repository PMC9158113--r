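test_that("covariance models produce the intended correlation structure", {
  expect_equal(make_covariance("none", 15), diag(15))

  raw <- make_covariance("factor", 15, n_factors = 3, seed = 3, repair = FALSE)
  expect_equal(raw, t(raw))
  expect_equal(diag(raw), rep(1, 15))
  block <- sort(rep_len(1:3, 15))
  within <- outer(block, block, "==") & lower.tri(raw)
  expect_true(all(abs(raw[within]) >= 0.4 & abs(raw[within]) <= 0.9))
  expect_true(all(abs(raw[!within & lower.tri(raw)]) <= 0.3))

  repaired <- make_covariance("factor", 15, n_factors = 3, seed = 3)
  ev <- eigen(repaired, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_equal(diag(repaired), rep(1, 15))

  rnd <- make_covariance("random", 5, seed = 9, repair = FALSE)
  expect_true(all(abs(rnd[lower.tri(rnd)]) <= 0.3))
  expect_identical(make_covariance("random", 5, seed = 9),
                   make_covariance("random", 5, seed = 9))
  expect_error(make_covariance("factor", 2, n_factors = 3), "Invalid design")
})

test_that("subgroup sizes follow the largest-remainder rule", {
  expect_equal(subgroup_sizes(c(0.1, 0.9), 100), c(10L, 90L))
  expect_equal(subgroup_sizes(c(0.1, 0.9), 10), c(1L, 9L))
  expect_equal(subgroup_sizes(rep(1 / 3, 3), 150), rep(50L, 3))
  expect_equal(sum(subgroup_sizes(c(0.33, 0.34, 0.33), 100)), 100L)
  expect_error(subgroup_sizes(c(0.01, 0.99), 10), "Sizing error")
})

test_that("simulated samples match their generating population", {
  spec <- power_design(3, 4)
  d <- simulate_dataset(spec, 150, seed = 21)
  expect_equal(as.integer(table(d$.cluster)), rep(50L, 3))

  # per-subgroup feature means within a 4-SE band of the design means
  X <- as.matrix(d[paste0("f", 1:2)])
  for (g in 1:3) {
    emp <- colMeans(X[d$.cluster == g, ])
    expect_true(all(abs(emp - spec$means[[g]]) < 4 / sqrt(50)))
  }

  # same seed, bit-identical data; different seed, different data
  expect_identical(simulate_dataset(spec, 40, seed = 5),
                   simulate_dataset(spec, 40, seed = 5))
  expect_false(identical(as.matrix(simulate_dataset(spec, 40, seed = 5)),
                         as.matrix(simulate_dataset(spec, 40, seed = 6))))
})

test_that("large samples recover the factor covariance entrywise", {
  S <- make_covariance("factor", 6, n_factors = 3, seed = 13)
  spec <- population_spec(list(rep(0, 6)), covariances = S)
  d <- simulate_dataset(spec, 20000, seed = 14)
  emp <- cor(as.matrix(d[paste0("f", 1:6)]))
  expect_lt(max(abs(emp - S)), 0.05)
})

test_that("large samples recover the design separation", {
  for (k in 2:3) {
    spec <- power_design(k, delta = 3.5)
    d <- simulate_dataset(spec, 20000, seed = 40 + k)
    expect_equal(centroid_separation(d), 3.5, tolerance = 0.05 / 3.5)
  }
})

test_that("datasets round-trip through delimited text", {
  d <- simulate_dataset(power_design(2, 4), 25, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, path)
  back <- read_dataset(path)
  expect_equal(as.matrix(back[paste0("f", 1:2)]), as.matrix(d[paste0("f", 1:2)]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$.cluster, d$.cluster)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,x"), bad)
  expect_error(read_dataset(bad), "Parse error")
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b", empty)
  expect_error(read_dataset(empty), "no observations")
})
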