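# Cluster-validity and accuracy metrics.

# Per-observation silhouette widths (Rousseeuw): a_i = mean distance to the
# other members of the own cluster, b_i = smallest mean distance to another
# cluster, s_i = (b - a) / max(a, b); singletons get s = 0. `labels` must be
# free of NA here.
silhouette_widths <- function(X, labels) {
  cl <- sort(unique(labels))
  D <- as.matrix(dist(X))
  n <- nrow(X)
  counts <- tabulate(match(labels, cl), nbins = length(cl))
  # n x n_clusters matrix of summed distances to each cluster
  S <- vapply(seq_along(cl),
              function(j) rowSums(D[, labels == cl[j], drop = FALSE]),
              numeric(n))
  own <- match(labels, cl)
  s <- numeric(n)
  for (i in seq_len(n)) {
    m <- counts[own[i]] - 1L
    if (m == 0L) next  # singleton cluster: s = 0 by convention
    a <- S[i, own[i]] / m
    b <- min(S[i, -own[i]] / counts[-own[i]])
    s[i] <- (b - a) / max(a, b)
  }
  s
}

#' Silhouette score of a hard partition
#'
#' Mean silhouette width over assigned observations, using Euclidean
#' distances and mean pairwise distances (the standard Rousseeuw
#' definition): per observation, `a` is the mean distance to the other
#' members of its cluster, `b` the smallest mean distance to another
#' cluster, and `s = (b - a) / max(a, b)`. Observations an algorithm left
#' unassigned (`NA` labels, e.g. HDBSCAN noise) are excluded. Scores of 0.5
#' and 0.7 are the conventional thresholds for evidence and strong evidence
#' of clustering.
#'
#' @param data Dataset tibble or numeric matrix (a `.cluster` column is
#'   ignored — the score is computed from the candidate partition, not the
#'   ground truth).
#' @param partition A [hard_partition()] or an integer label vector (NA =
#'   unassigned).
#' @return One-row tibble with `score` (in \[-1, 1\]) and `n_used`, the
#'   number of assigned observations included.
#' @examples
#' d <- simulate_dataset(power_design(2, 8), n = 60, seed = 1)
#' silhouette_score(d, run_kmeans(d, 2, seed = 1))
#' @export
silhouette_score <- function(data, partition) {
  X <- feature_matrix(data)
  labels <- if (inherits(partition, "hard_partition")) partition$labels else as.integer(partition)
  if (length(labels) != nrow(X)) abort("`partition` length must match the number of observations.")
  keep <- !is.na(labels)
  X <- X[keep, , drop = FALSE]
  labels <- labels[keep]
  if (length(unique(labels)) < 2) {
    abort("Silhouette is undefined with fewer than 2 populated clusters.")
  }
  s <- silhouette_widths(X, labels)
  tibble(score = mean(s), n_used = length(s))
}

#' Fuzzy silhouette score of a soft partition
#'
#' Membership-weighted silhouette for fuzzy clustering and mixture-model
#' posteriors: crisp silhouette widths `s_j` are computed from the
#' highest-membership (argmax) labels, and each observation is weighted by
#' `(mu_p - mu_q)^alpha`, the gap between its largest and second-largest
#' membership weights. Observations the partition is confident about
#' dominate; exactly tied memberships get weight 0 (and with `alpha = 0` all
#' weights are 1, recovering the plain silhouette).
#'
#' @inheritParams silhouette_score
#' @param partition A [fuzzy_partition()], a `mixture_fit` from
#'   [run_gmm()], or a membership matrix with rows summing to 1.
#' @param alpha Non-negative weighting exponent (default 1).
#' @return One-row tibble with `score` and `n_used` (all observations).
#' @export
fuzzy_silhouette <- function(data, partition, alpha = 1) {
  X <- feature_matrix(data)
  U <- if (is.matrix(partition)) fuzzy_partition(partition)$U else partition$U
  if (alpha < 0) abort("`alpha` must be >= 0.")
  if (nrow(U) != nrow(X)) abort("Membership matrix rows must match the observations.")
  hl <- max.col(U, ties.method = "first")
  if (length(unique(hl)) < 2) {
    abort("Fuzzy silhouette is undefined with fewer than 2 populated clusters.")
  }
  s <- silhouette_widths(X, hl)
  top2 <- t(apply(U, 1, function(r) -sort(-r, partial = 2)[1:2]))
  w <- (top2[, 1] - top2[, 2])^alpha
  if (sum(w) == 0) abort("Undefined score: all membership gaps are zero.")
  tibble(score = sum(w * s) / sum(w), n_used = nrow(X))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between a candidate partition and the ground
#' truth, from the contingency table: 1 = identical partitions (up to
#' relabelling), 0 = chance-level overlap, negative = worse than chance.
#' Unassigned predictions (`NA`) are excluded from the contingency table,
#' mirroring the silhouette's exclusion rule.
#'
#' @param truth Integer ground-truth labels.
#' @param pred A [hard_partition()] or integer label vector of the same
#'   length (NA = unassigned).
#' @return A single number <= 1.
#' @export
adjusted_rand <- function(truth, pred) {
  if (inherits(pred, "hard_partition")) pred <- pred$labels
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  if (length(truth) != length(pred)) abort("`truth` and `pred` must have equal length.")
  keep <- !is.na(pred) & !is.na(truth)
  truth <- truth[keep]
  pred <- pred[keep]
  n <- length(truth)
  if (n < 2) return(NA_real_)
  tab <- table(truth, pred)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  maximum <- (a + b) / 2
  if (maximum == expected) return(as.numeric(sum_ij == expected))
  (sum_ij - expected) / (maximum - expected)
}

#' Classification accuracy under optimal cluster-label matching
#'
#' Proportion of observations assigned to their true subgroup, maximised
#' over one-to-one assignments of predicted cluster ids to true subgroup
#' ids (optimal bipartite matching; surplus clusters on either side simply
#' absorb errors). Unassigned observations (`NA`) count as incorrect. The
#' chance level is the proportion of the sample in the largest true
#' subgroup — the accuracy of always guessing the majority subgroup.
#'
#' @inheritParams adjusted_rand
#' @return One-row tibble with `accuracy`, `chance`, `n`, and
#'   `n_unassigned`.
#' @examples
#' classification_accuracy(c(1, 1, 2, 2), c(2, 2, 1, 1))  # accuracy 1
#' @export
classification_accuracy <- function(truth, pred) {
  if (inherits(pred, "hard_partition")) pred <- pred$labels
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  if (length(truth) != length(pred)) abort("`truth` and `pred` must have equal length.")
  n <- length(truth)
  chance <- max(table(truth)) / n
  keep <- !is.na(pred)
  correct <- 0
  if (any(keep)) {
    tab <- table(factor(truth[keep]), factor(pred[keep]))
    m <- max(dim(tab))
    C <- matrix(0, m, m)
    C[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
    assignment <- clue::solve_LSAP(C, maximum = TRUE)
    correct <- sum(C[cbind(seq_len(m), assignment)])
  }
  tibble(accuracy = correct / n, chance = as.numeric(chance),
         n = n, n_unassigned = sum(!keep))
}
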