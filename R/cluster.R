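# Uniform adapters around the clustering algorithms. Hard partitions carry
# integer labels (NA = unassigned); fuzzy partitions carry a row-stochastic
# membership matrix.

#' Hard and fuzzy partition containers
#'
#' `hard_partition()` wraps integer cluster labels (1..m, `NA` for
#' observations an algorithm left unassigned); `n_clusters` is the number of
#' distinct non-missing labels. `fuzzy_partition()` wraps an N x k
#' membership-weight matrix whose rows sum to 1; `hard_labels` is the
#' row-wise argmax.
#'
#' @param labels Integer vector of cluster labels (NA allowed).
#' @return A `hard_partition` or `fuzzy_partition` object.
#' @export
hard_partition <- function(labels) {
  labels <- as.integer(labels)
  structure(list(labels = labels,
                 n_clusters = length(unique(labels[!is.na(labels)]))),
            class = "hard_partition")
}

#' @rdname hard_partition
#' @param U Numeric N x k matrix of membership weights in \[0, 1\], rows
#'   summing to 1.
#' @export
fuzzy_partition <- function(U) {
  U <- as.matrix(U)
  if (any(U < -1e-9) || any(U > 1 + 1e-9)) {
    abort("Membership weights must lie in [0, 1].")
  }
  if (max(abs(rowSums(U) - 1)) > 1e-9) {
    abort("Each row of the membership matrix must sum to 1.")
  }
  structure(list(U = U, hard_labels = max.col(U, ties.method = "first")),
            class = "fuzzy_partition")
}

#' @export
print.hard_partition <- function(x, ...) {
  cat(sprintf("<hard_partition> %d observations, %d clusters, %d unassigned\n",
              length(x$labels), x$n_clusters, sum(is.na(x$labels))))
  invisible(x)
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat(sprintf("<fuzzy_partition> %d observations, %d clusters\n",
              nrow(x$U), ncol(x$U)))
  invisible(x)
}

#' @export
tidy.hard_partition <- function(x, ...) {
  tibble(observation = seq_along(x$labels), cluster = x$labels)
}

#' @export
tidy.fuzzy_partition <- function(x, ...) {
  out <- tibble(observation = seq_len(nrow(x$U)), cluster = x$hard_labels)
  U <- as.data.frame(x$U)
  names(U) <- paste0("membership_", seq_len(ncol(U)))
  dplyr::bind_cols(out, U)
}

#' K-means clustering adapter
#'
#' Lloyd-style k-means ([stats::kmeans()]) with multiple random restarts
#' (best within-cluster sum of squares kept); all observations are assigned.
#'
#' @param data Dataset tibble or numeric matrix (a `.cluster` column is
#'   ignored).
#' @param k Number of clusters (>= 2 and <= N).
#' @param seed Optional integer seed (initial centroids are random).
#' @param nstart Number of random restarts (default 10).
#' @return A [hard_partition()].
#' @export
run_kmeans <- function(data, k, seed = NULL, nstart = 10) {
  X <- feature_matrix(data)
  if (k < 1 || k > nrow(X)) abort("`k` must be between 1 and the number of observations.")
  if (k == nrow(X)) return(hard_partition(seq_len(k)))  # every point its own cluster
  fit <- with_seed_(seed, kmeans(X, centers = k, nstart = nstart, iter.max = 50))
  hard_partition(fit$cluster)
}

#' Agglomerative hierarchical clustering adapter
#'
#' Deterministic bottom-up merging cut at k clusters: `"ward_euclidean"`
#' uses Ward's minimum-variance criterion on Euclidean distances
#' (`hclust(method = "ward.D2")`); `"average_cosine"` uses average linkage
#' on cosine dissimilarity (1 - cosine similarity), which requires no
#' zero-length observation vectors.
#'
#' @inheritParams run_kmeans
#' @param flavour `"ward_euclidean"` or `"average_cosine"`.
#' @return A [hard_partition()].
#' @export
run_agglomerative <- function(data, k, flavour = c("ward_euclidean", "average_cosine")) {
  flavour <- match.arg(flavour)
  X <- feature_matrix(data)
  if (k < 1 || k > nrow(X)) abort("`k` must be between 1 and the number of observations.")
  if (flavour == "ward_euclidean") {
    hc <- hclust(dist(X), method = "ward.D2")
  } else {
    nrm <- sqrt(rowSums(X^2))
    if (any(nrm == 0)) abort("Cosine distance is undefined for zero-vector observations.")
    S <- tcrossprod(X / nrm)
    D <- stats::as.dist(pmax(1 - S, 0))
    hc <- hclust(D, method = "average")
  }
  hard_partition(cutree(hc, k = k))
}

#' Fuzzy c-means clustering adapter
#'
#' Fuzzy c-means ([e1071::cmeans()]): converges on centroids like k-means
#' but assigns each observation a membership weight for every cluster.
#'
#' @inheritParams run_kmeans
#' @param m Fuzzifier exponent (> 1; default 2, the conventional choice).
#' @return A [fuzzy_partition()].
#' @export
run_cmeans <- function(data, k, m = 2, seed = NULL) {
  X <- feature_matrix(data)
  if (m <= 1) abort("The fuzzifier `m` must be > 1.")
  if (k < 2 || k > nrow(X)) abort("`k` must be between 2 and the number of observations.")
  fit <- with_seed_(seed, e1071::cmeans(X, centers = k, m = m, iter.max = 200))
  U <- fit$membership
  U <- U / rowSums(U)  # guard against accumulated round-off
  fuzzy_partition(U)
}

#' Gaussian mixture model adapter
#'
#' Fits a k-component Gaussian mixture with full (unconstrained)
#' per-component covariance matrices by expectation-maximisation: one EM run
#' initialised from k-means centroids (hard assignments as starting
#' responsibilities), with a small regularisation jitter (`1e-6`) on the
#' covariance diagonals to avoid singularities, run until the mean
#' log-likelihood changes by less than `1e-3` (at most 100 iterations).
#' Posterior component probabilities play the role of fuzzy membership
#' weights, and the Bayesian Information Criterion is returned on the
#' minimise-me scale (`-2 logLik + npar log N`; lower is better).
#'
#' @inheritParams run_kmeans
#' @param k Number of mixture components (>= 1).
#' @param reg_covar Ridge added to covariance diagonals (default `1e-6`).
#' @param tol Convergence tolerance on the mean log-likelihood change.
#' @param max_iter Maximum EM iterations.
#' @return A `mixture_fit`: list with `U` (posterior matrix), `hard_labels`,
#'   `bic`, and `loglik`; or `NULL` when the fit collapses (singular
#'   component), which callers exclude from model selection with a warning.
#' @export
run_gmm <- function(data, k, seed = NULL, reg_covar = 1e-6, tol = 1e-3,
                    max_iter = 100) {
  X <- feature_matrix(data)
  n <- nrow(X)
  d <- ncol(X)
  if (k < 1) abort("`k` must be >= 1.")
  if (n <= k * d) abort("Too few observations to fit full per-component covariances.")

  fit <- with_seed_(seed, tryCatch({
    R <- if (k == 1) {
      matrix(1, n, 1)
    } else {
      km <- kmeans(X, centers = k, nstart = 10, iter.max = 50)
      R0 <- matrix(0, n, k)
      R0[cbind(seq_len(n), km$cluster)] <- 1
      R0
    }
    ll_old <- -Inf
    lse <- NULL
    for (iter in seq_len(max_iter)) {
      nk <- colSums(R)
      if (any(nk < 1e-8)) stop("empty mixture component")
      w <- nk / n
      mu <- crossprod(R, X) / nk
      logdens <- matrix(0, n, k)
      for (j in seq_len(k)) {
        Xc <- sweep(X, 2, mu[j, ])
        S <- crossprod(Xc * R[, j], Xc) / nk[j] + diag(reg_covar, d)
        ch <- chol(S)  # fails on singular components -> failed fit
        z <- backsolve(ch, t(Xc), transpose = TRUE)
        logdens[, j] <- -0.5 * colSums(z^2) - sum(log(diag(ch))) -
          0.5 * d * log(2 * pi) + log(w[j])
      }
      mx <- apply(logdens, 1, max)
      lse <- mx + log(rowSums(exp(logdens - mx)))
      R <- exp(logdens - lse)
      ll <- mean(lse)
      if (is.finite(ll) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    list(U = R, loglik = sum(lse))
  }, error = function(e) NULL))
  if (is.null(fit)) return(NULL)

  npar <- (k - 1) + k * d + k * d * (d + 1) / 2
  U <- fit$U / rowSums(fit$U)
  structure(
    list(U = U, hard_labels = max.col(U, ties.method = "first"),
         bic = -2 * fit$loglik + npar * log(n), loglik = fit$loglik, k = k),
    class = c("mixture_fit")
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> %d components, BIC = %.2f (lower is better)\n",
              x$k, x$bic))
  invisible(x)
}

#' @export
tidy.mixture_fit <- function(x, ...) {
  tidy(fuzzy_partition(x$U))
}

#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(k = x$k, bic = x$bic, loglik = x$loglik)
}
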