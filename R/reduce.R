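#' Dimensionality reduction to two components
#'
#' Projects an observations-by-features dataset into two dimensions before
#' clustering. `"mds"` is metric multi-dimensional scaling on Euclidean
#' distances between standardised features, minimising raw stress by SMACOF
#' majorisation (4 random starts, best stress kept) so that the embedded
#' distances approximate the original ones on their original scale — in
#' practice this subtly exaggerates cluster-centroid separation, unlike a
#' classical principal-coordinate projection, which can only shrink
#' distances. `"umap"` is uniform manifold approximation and projection
#' ([uwot::umap()]) with the library's default neighbourhood parameters and
#' 2 output components; `"none"` passes the data through unchanged (any
#' feature count). Both mds and umap are stochastic and take a seed for
#' reproducibility.
#'
#' @param data A dataset tibble/data frame or numeric matrix; a `.cluster`
#'   column, if present, is carried through unchanged.
#' @param method `"none"`, `"mds"`, or `"umap"`.
#' @param seed Optional integer seed (used by mds and umap).
#' @param ... Further arguments passed to [uwot::umap()].
#' @return A tibble of reduced coordinates (`dim1`, `dim2` for mds/umap; the
#'   original features for `"none"`), plus `.cluster` when available, with
#'   the method recorded in attribute `"method"`.
#' @examples
#' d <- simulate_dataset(power_design(2, 4), n = 50, seed = 1)
#' reduce_dims(d, "mds")
#' @export
reduce_dims <- function(data, method = c("none", "mds", "umap"), seed = NULL, ...) {
  method <- match.arg(method)
  X <- feature_matrix(data)
  labels <- truth_labels(data)
  if (method != "none" && nrow(X) < 3) {
    abort("mds/umap need at least 3 observations for a 2-D embedding.")
  }
  Y <- switch(method,
    none = X,
    mds = {
      Y <- with_seed_(seed, smacof_mds(dist(X)))
      colnames(Y) <- c("dim1", "dim2")
      Y
    },
    umap = {
      Y <- with_seed_(seed, uwot::umap(X, n_components = 2, n_threads = 1,
                                       n_sgd_threads = 0, ...))
      colnames(Y) <- c("dim1", "dim2")
      Y
    }
  )
  out <- as_tibble(as.data.frame(Y))
  if (!is.null(labels)) out$.cluster <- labels
  attr(out, "method") <- method
  out
}

# Metric MDS by SMACOF majorisation (raw stress, uniform weights): repeat the
# Guttman transform from random starts and keep the lowest-stress
# configuration. Keeps the distance scale, so embedded separations are
# comparable to standardised-space Delta.
smacof_mds <- function(D, n_components = 2, n_init = 4, max_iter = 300,
                       eps = 1e-3) {
  D <- as.matrix(D)
  n <- nrow(D)
  best <- NULL
  best_stress <- Inf
  for (init in seq_len(n_init)) {
    X <- matrix(rnorm(n * n_components), n, n_components)
    old_stress <- Inf
    for (it in seq_len(max_iter)) {
      d <- as.matrix(dist(X))
      d[d == 0] <- 1e-12
      stress <- sum((D[upper.tri(D)] - d[upper.tri(d)])^2)
      if (it > 1 && old_stress - stress < eps * old_stress) break
      old_stress <- stress
      B <- -D / d
      diag(B) <- 0
      diag(B) <- -rowSums(B)
      X <- B %*% X / n
    }
    if (stress < best_stress) {
      best_stress <- stress
      best <- X
    }
  }
  best
}

#' Observed centroid separation of labelled data
#'
#' Euclidean distance between the average positions of observations within
#' each cluster; for more than two clusters, the minimum over all centroid
#' pairs (for three clusters this is the middle-to-outer distance, the
#' smallest between-cluster distance). This is the sample counterpart of the
#' design effect size Delta, measurable before or after dimensionality
#' reduction.
#'
#' @param data Dataset tibble (with `.cluster`) or numeric matrix.
#' @param labels Integer cluster labels; defaults to the `.cluster` column.
#' @return Non-negative number: minimum pairwise centroid distance.
#' @examples
#' d <- simulate_dataset(power_design(2, 4), n = 2000, seed = 1)
#' centroid_separation(d)  # ~4
#' @export
centroid_separation <- function(data, labels = NULL) {
  X <- feature_matrix(data)
  labels <- labels %||% truth_labels(data)
  if (is.null(labels)) abort("`labels` required (no `.cluster` column found).")
  labels <- as.integer(labels)
  keep <- !is.na(labels)
  X <- X[keep, , drop = FALSE]
  labels <- labels[keep]
  cl <- sort(unique(labels))
  if (length(cl) < 2) {
    abort("Undefined separation: need at least 2 clusters with members.")
  }
  centroids <- t(vapply(cl, function(c) colMeans(X[labels == c, , drop = FALSE]),
                        numeric(ncol(X))))
  min(dist(centroids))
}
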