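#' Multivariate effect size from per-feature effect sizes
#'
#' Combines per-feature standardised mean differences (Cohen's d) into the
#' centroid separation Delta between two subgroups in standardised feature
#' space: `Delta = sqrt(sum(d_i^2))`, the Euclidean quadrature of the
#' per-feature effects. Features with no expected difference contribute 0 and
#' may simply be omitted.
#'
#' @param effects Numeric vector of non-negative per-feature Cohen's d values,
#'   one entry per feature (zeros allowed), or an [effect_design()].
#' @return A single non-negative number, the expected centroid separation
#'   Delta in standardised (unit-SD) space.
#' @examples
#' # 100 measured features: 20 small, 12 medium, 4 large expected differences
#' d <- c(rep(0.3, 20), rep(0.5, 12), rep(0.8, 4), rep(0, 64))
#' delta_from_effects(d) # ~2.7
#' @seealso [effect_design()], [make_mean_arrays()]
#' @export
delta_from_effects <- function(effects) {
  effects <- unclass(effects)
  if (!is.numeric(effects) || length(effects) == 0L) {
    abort("`effects` must be a non-empty numeric vector of per-feature Cohen's d.")
  }
  if (anyNA(effects) || any(effects < 0)) {
    abort("Invalid effect design: all per-feature effect sizes must be >= 0 and non-missing.")
  }
  sqrt(sum(effects^2))
}

#' Per-feature effect-size design
#'
#' A validated vector of per-feature Cohen's d values describing the expected
#' differences between two subgroups, one entry per measured feature.
#'
#' @param per_feature_d Numeric vector of non-negative effect sizes.
#' @return An `effect_design` object (a classed numeric vector).
#' @export
effect_design <- function(per_feature_d) {
  if (!is.numeric(per_feature_d) || length(per_feature_d) == 0L) {
    abort("`per_feature_d` must be a non-empty numeric vector.")
  }
  if (anyNA(per_feature_d) || any(per_feature_d < 0)) {
    abort("Invalid effect design: all entries of `per_feature_d` must be >= 0.")
  }
  structure(as.numeric(per_feature_d), class = "effect_design")
}

#' @export
print.effect_design <- function(x, ...) {
  cat(sprintf("<effect_design> %d features, %d differing, Delta = %.3f\n",
              length(x), sum(x > 0), delta_from_effects(x)))
  invisible(x)
}

#' Construct subgroup mean arrays from a per-feature effect size
#'
#' Builds the mean vectors of k = 2 or 3 subgroups from a common per-feature
#' Cohen's d. For two subgroups, each differing feature assigns means -d/2 and
#' +d/2 to the two subgroups, with the order shuffled independently per
#' feature. For three subgroups, the "middle" subgroup has an all-zero mean
#' array and the two outer subgroups receive +d and -d on each differing
#' feature, again in shuffled order. Non-differing features have mean 0
#' everywhere.
#'
#' @param k Number of subgroups, 2 or 3. For other layouts use
#'   [make_equidistant_centroids()].
#' @param n_features Total number of features p.
#' @param d Cohen's d applied to each differing feature (non-negative).
#' @param n_diff_features Number of features that differ between subgroups
#'   (the first `n_diff_features` features; between 1 and `n_features`).
#' @param seed Optional integer seed controlling the per-feature shuffles.
#' @return A list of k numeric mean vectors of length `n_features`.
#' @export
make_mean_arrays <- function(k, n_features, d, n_diff_features, seed = NULL) {
  if (!k %in% c(2L, 3L)) {
    abort(paste("`k` must be 2 or 3 for effect-size mean arrays;",
                "use make_equidistant_centroids() for other subgroup counts."))
  }
  check_scalar_number(d, "d", min = 0)
  if (n_diff_features < 1 || n_diff_features > n_features) {
    abort("`n_diff_features` must be between 1 and `n_features`.")
  }
  means <- replicate(k, numeric(n_features), simplify = FALSE)
  with_seed_(seed, {
    for (j in seq_len(n_diff_features)) {
      if (k == 2L) {
        vals <- sample(c(-d / 2, d / 2))
        means[[1]][j] <- vals[1]
        means[[2]][j] <- vals[2]
      } else {
        vals <- sample(c(-d, d))   # middle subgroup (index 2) stays at 0
        means[[1]][j] <- vals[1]
        means[[3]][j] <- vals[2]
      }
    }
  })
  means
}

#' Equidistant centroid layouts in two dimensions
#'
#' Places k subgroup centroids in 2-D so that the nearest-neighbour centroid
#' separation equals `delta`, centred on the origin: a single point (k = 1), a
#' pair on a line (k = 2), an equilateral triangle (k = 3), or a square of
#' side `delta` (k = 4). Four mutually equidistant points do not exist in the
#' plane, so for k = 4 the square convention fixes the nearest-neighbour
#' separation (the quantity power depends on) at `delta`, while diagonal
#' pairs sit at `delta * sqrt(2)`.
#'
#' @param k Number of subgroups, 1 to 4.
#' @param delta Non-negative nearest-neighbour centroid separation in
#'   standardised units.
#' @return A `centroid_layout`: list with `k`, `delta`, and a k x 2 matrix
#'   `centroids` whose rows are centroid coordinates.
#' @export
make_equidistant_centroids <- function(k, delta) {
  check_scalar_number(delta, "delta", min = 0)
  if (!k %in% 1:4) {
    abort("Unsupported design: equidistant layouts are defined for k = 1..4.")
  }
  centroids <- switch(as.character(k),
    "1" = matrix(c(0, 0), nrow = 1),
    "2" = matrix(c(-delta / 2, 0, delta / 2, 0), nrow = 2, byrow = TRUE),
    "3" = {
      r <- delta / sqrt(3)  # circumradius of an equilateral triangle of side delta
      ang <- pi / 2 + 2 * pi * (0:2) / 3
      cbind(r * cos(ang), r * sin(ang))
    },
    "4" = delta / 2 * matrix(c(-1, -1, -1, 1, 1, 1, 1, -1), nrow = 4, byrow = TRUE)
  )
  centroids <- sweep(centroids, 2, colMeans(centroids))  # centre on origin
  dimnames(centroids) <- NULL
  structure(list(k = as.integer(k), delta = delta, centroids = centroids),
            class = "centroid_layout")
}

#' @export
print.centroid_layout <- function(x, ...) {
  cat(sprintf("<centroid_layout> k = %d, delta = %g\n", x$k, x$delta))
  print(round(x$centroids, 4))
  invisible(x)
}

#' Full generative description of a clustered population
#'
#' Bundles subgroup weights, mean arrays, and per-subgroup correlation
#' matrices into a population specification for [simulate_dataset()]. All
#' features have unit standard deviation, so means are in standardised units
#' and covariance matrices are correlation matrices.
#'
#' @param means List of k numeric mean vectors (equal length p), or a k x p
#'   matrix of means.
#' @param covariances A single p x p correlation matrix (shared by all
#'   subgroups) or a list of k such matrices. Defaults to the identity
#'   (uncorrelated features).
#' @param weights Numeric vector of k positive subgroup proportions summing
#'   to 1. Defaults to equal weights.
#' @return A `population_spec` object.
#' @examples
#' layout <- make_equidistant_centroids(3, delta = 4)
#' spec <- population_spec(means = layout$centroids)
#' @export
population_spec <- function(means, covariances = NULL, weights = NULL) {
  if (is.matrix(means)) means <- lapply(seq_len(nrow(means)), function(i) means[i, ])
  if (!is.list(means) || length(means) == 0L) {
    abort("`means` must be a list of mean vectors or a matrix with one row per subgroup.")
  }
  k <- length(means)
  p <- length(means[[1]])
  if (any(vapply(means, length, 1L) != p)) {
    abort("All mean arrays must have the same length.")
  }
  means <- lapply(means, as.numeric)

  weights <- weights %||% rep(1 / k, k)
  if (length(weights) != k || any(weights <= 0) || abs(sum(weights) - 1) > 1e-8) {
    abort("`weights` must be k positive values summing to 1.")
  }

  covariances <- covariances %||% diag(p)
  if (is.matrix(covariances)) covariances <- replicate(k, covariances, simplify = FALSE)
  if (length(covariances) != k) {
    abort("`covariances` must be one matrix or a list with one matrix per subgroup.")
  }
  for (S in covariances) {
    if (!is.matrix(S) || nrow(S) != p || ncol(S) != p) {
      abort("Each covariance matrix must be p x p.")
    }
    if (max(abs(S - t(S))) > 1e-8 || max(abs(diag(S) - 1)) > 1e-8) {
      abort("Covariance matrices must be symmetric with unit diagonal (correlation matrices).")
    }
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      abort("Covariance matrices must be positive semi-definite; see make_covariance(repair = TRUE).")
    }
  }

  structure(
    list(n_features = as.integer(p), k = as.integer(k),
         weights = as.numeric(weights), means = means, covariances = covariances),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec> k = %d subgroups, p = %d features\n", x$k, x$n_features))
  cat("  weights:", paste(format(x$weights, digits = 3), collapse = ", "), "\n")
  sep <- tryCatch(design_separation(x), error = function(e) NA_real_)
  if (is.finite(sep)) cat(sprintf("  minimum centroid separation Delta = %.3f\n", sep))
  invisible(x)
}

#' Design-level centroid separation of a population
#'
#' Minimum pairwise Euclidean distance between subgroup mean vectors; the
#' design-level effect size Delta of a `population_spec`.
#'
#' @param spec A [population_spec()].
#' @return Non-negative number (NA for single-subgroup designs).
#' @export
design_separation <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  if (spec$k < 2) return(NA_real_)
  M <- do.call(rbind, spec$means)
  min(dist(M))
}

#' Two-feature population with equidistant subgroups
#'
#' Convenience constructor for the power-simulation designs: k equally
#' spaced subgroup centroids ([make_equidistant_centroids()]) in two
#' standardised features, with configurable subgroup weights and covariance
#' structure.
#'
#' @param k Number of subgroups (1 to 4).
#' @param delta Nearest-neighbour centroid separation Delta.
#' @param weights Subgroup proportions (default equal).
#' @param covariance `"none"` (identity, the default), `"random"`, or
#'   `"factor"`; passed to [make_covariance()]. May also be a precomputed
#'   matrix or list of matrices.
#' @param n_factors Number of factors when `covariance = "factor"`.
#' @param seed Seed for random covariance generation.
#' @return A [population_spec()] with 2 features.
#' @examples
#' power_design(k = 2, delta = 4)
#' @export
power_design <- function(k, delta, weights = NULL, covariance = "none",
                         n_factors = 3, seed = NULL) {
  layout <- make_equidistant_centroids(k, delta)
  covs <- if (is.character(covariance)) {
    make_covariance(covariance, n_features = 2, n_factors = min(n_factors, 2), seed = seed)
  } else {
    covariance
  }
  population_spec(means = layout$centroids, covariances = covs, weights = weights)
}

#' High-dimensional population from a per-feature effect design
#'
#' Builds a `population_spec` with k = 2 or 3 subgroups whose mean arrays are
#' constructed from a common per-feature Cohen's d ([make_mean_arrays()]),
#' with a shared or per-subgroup covariance structure.
#'
#' @inheritParams make_mean_arrays
#' @param covariance Covariance kind (`"none"`, `"random"`, `"factor"`), a
#'   vector of kinds (one per subgroup, for mixed structures), or
#'   precomputed matrices.
#' @param n_factors Factors for `"factor"` covariance (3 or 4 typical).
#' @param weights Subgroup proportions (default equal).
#' @param seed Seed for mean shuffles and covariance generation.
#' @return A [population_spec()].
#' @examples
#' feature_design(k = 2, n_features = 15, d = 1.3, n_diff_features = 10,
#'                covariance = "factor", seed = 1)
#' @export
feature_design <- function(k, n_features, d, n_diff_features,
                           covariance = "none", n_factors = 3,
                           weights = NULL, seed = NULL) {
  means <- make_mean_arrays(k, n_features, d, n_diff_features,
                            seed = if (is.null(seed)) NULL else derive_seed(seed, 1))
  covs <- if (is.character(covariance)) {
    if (length(covariance) > 1) {
      lapply(seq_along(covariance), function(i) {
        make_covariance(covariance[i], n_features, n_factors = n_factors,
                        seed = if (is.null(seed)) NULL else derive_seed(seed, 2, i))
      })
    } else {
      make_covariance(covariance, n_features, n_factors = n_factors,
                      seed = if (is.null(seed)) NULL else derive_seed(seed, 2))
    }
  } else {
    covariance
  }
  population_spec(means = means, covariances = covs, weights = weights)
}
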