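#' HDBSCAN density-based clustering
#'
#' Hierarchical density-based clustering: identifies clusters of denser
#' observations among lower-density observations, which remain unassigned
#' (`NA` labels). The algorithm reports its own number of clusters, so no
#' candidate-k grid is needed.
#'
#' The implementation follows the standard construction: core distances at
#' `min_samples` neighbours, the mutual-reachability distance
#' `max(core_i, core_j, d_ij)`, a minimum spanning tree of the
#' mutual-reachability graph, the single-linkage hierarchy over its edges, a
#' condensed tree pruned at `min_cluster_size`, and excess-of-mass cluster
#' selection by stability (the whole-sample root is never selected, so a
#' dataset with no sub-structure yields zero clusters). Samples of
#' `2 * min_cluster_size` observations or fewer are below the resolvable
#' size and return an all-unassigned partition. Complexity is O(N^2),
#' suitable for the sample sizes used in power simulation.
#'
#' @param data Dataset tibble or numeric matrix (a `.cluster` column is
#'   ignored).
#' @param min_cluster_size Smallest group of observations accepted as a
#'   cluster (default 5).
#' @param min_samples Neighbour count for core distances; defaults to
#'   `min_cluster_size`.
#' @return A [hard_partition()] whose labels may contain `NA` (unassigned);
#'   `n_clusters` may be 0, which downstream detection treats as "not
#'   clustered".
#' @examples
#' d <- simulate_dataset(power_design(2, 8), n = 100, seed = 1)
#' run_hdbscan(d)
#' @export
run_hdbscan <- function(data, min_cluster_size = 5, min_samples = min_cluster_size) {
  X <- feature_matrix(data)
  n <- nrow(X)
  if (min_cluster_size < 2) abort("`min_cluster_size` must be >= 2.")
  if (n < min_samples || n <= 2 * min_cluster_size) {
    # below the resolvable sample size no density structure is reported
    return(hard_partition(rep(NA_integer_, n)))
  }

  D <- as.matrix(dist(X))
  # core distance: k-th smallest including self (= (k-1)-th nearest neighbour)
  core <- apply(D, 1, function(r) sort(r, partial = min_samples)[min_samples])
  MR <- pmax(D, outer(core, core, pmax))

  edges <- mst_edges(MR)
  hier <- single_linkage(edges, n)
  cond <- condense_tree(hier, n, min_cluster_size)
  if (nrow(cond$edges) == 0L) return(hard_partition(rep(NA_integer_, n)))
  sel <- select_eom(cond, n)
  hard_partition(label_points(cond, sel, n))
}

# Prim's algorithm on a dense distance matrix; returns edges (from, to, w).
mst_edges <- function(W) {
  n <- nrow(W)
  in_tree <- logical(n)
  in_tree[1] <- TRUE
  best <- W[1, ]
  from <- rep(1L, n)
  out <- matrix(0, n - 1L, 3L)
  for (step in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    out[step, ] <- c(from[v], v, best[v])
    in_tree[v] <- TRUE
    upd <- !in_tree & W[v, ] < best
    best[upd] <- W[v, upd]
    from[upd] <- v
  }
  out[order(out[, 3]), , drop = FALSE]
}

# Single-linkage dendrogram over sorted MST edges. Leaves are 1..n, internal
# nodes n+1..2n-1 with children and merge heights.
single_linkage <- function(edges, n) {
  parent <- seq_len(2L * n - 1L)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  node_of <- seq_len(n)          # component root -> current dendrogram node
  left <- right <- integer(n - 1L)
  height <- numeric(n - 1L)
  counts <- c(rep(1L, n), integer(n - 1L))
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges[i, 1]); rb <- find(edges[i, 2])
    m <- n + i
    left[i] <- node_of[ra]; right[i] <- node_of[rb]
    height[i] <- edges[i, 3]
    counts[m] <- counts[left[i]] + counts[right[i]]
    parent[ra] <- rb
    node_of[rb] <- m
  }
  list(left = left, right = right, height = height, counts = counts)
}

# All leaf points under a dendrogram node.
subtree_leaves <- function(hier, node, n) {
  stack <- node
  leaves <- integer(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v <= n) {
      leaves <- c(leaves, v)
    } else {
      i <- v - n
      stack <- c(stack, hier$left[i], hier$right[i])
    }
  }
  leaves
}

# Condense the dendrogram: subtrees smaller than min_cluster_size fall out of
# their cluster at the lambda (1/distance) of the disconnecting split; splits
# into two sufficiently large subtrees create child clusters. Returns the
# condensed-tree edge table; clusters are numbered n+1 (root), n+2, ...
condense_tree <- function(hier, n, min_cluster_size) {
  root <- 2L * n - 1L
  relabel <- integer(root)
  next_cluster <- n + 1L
  relabel[root] <- next_cluster
  next_cluster <- next_cluster + 1L

  parent <- child <- integer(0)
  lambda <- size <- numeric(0)
  add <- function(p, c, l, s) {
    parent[length(parent) + 1L] <<- p
    child[length(child) + 1L] <<- c
    lambda[length(lambda) + 1L] <<- l
    size[length(size) + 1L] <<- s
  }

  stack <- root
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    i <- node - n
    kids <- c(hier$left[i], hier$right[i])
    lam <- if (hier$height[i] > 0) 1 / hier$height[i] else Inf
    cnt <- hier$counts[kids]
    big <- cnt >= min_cluster_size
    if (all(big)) {
      for (kid in kids) {
        add(relabel[node], next_cluster, lam, hier$counts[kid])
        relabel[kid] <- next_cluster
        next_cluster <- next_cluster + 1L
        stack <- c(stack, kid)   # both children exceed min size, so internal
      }
    } else {
      for (j in 1:2) {
        kid <- kids[j]
        if (big[j]) {
          relabel[kid] <- relabel[node]
          if (kid > n) stack <- c(stack, kid)
        } else {
          for (p in subtree_leaves(hier, kid, n)) add(relabel[node], p, lam, 1)
        }
      }
    }
  }
  list(edges = data.frame(parent = parent, child = child,
                          lambda = lambda, size = size),
       n_clusters = next_cluster - (n + 1L))
}

# Excess-of-mass cluster selection by stability; the root cluster (id n+1)
# is never selected. Returns the selected cluster ids.
select_eom <- function(cond, n) {
  ed <- cond$edges
  clusters <- sort(unique(c(n + 1L, ed$child[ed$size > 1])))
  birth <- stats::setNames(rep(0, length(clusters)), clusters)
  for (i in seq_len(nrow(ed))) {
    if (ed$size[i] > 1) birth[as.character(ed$child[i])] <- ed$lambda[i]
  }
  stability <- vapply(clusters, function(cl) {
    rows <- ed$parent == cl
    sum((pmin(ed$lambda[rows], .Machine$double.xmax) - birth[as.character(cl)]) *
          ed$size[rows])
  }, numeric(1))
  names(stability) <- clusters

  kids_of <- split(ed$child[ed$size > 1], ed$parent[ed$size > 1])
  descendants <- function(cl) {
    out <- integer(0)
    stack <- kids_of[[as.character(cl)]]
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      out <- c(out, v)
      stack <- c(stack, kids_of[[as.character(v)]])
    }
    out
  }

  is_cluster <- stats::setNames(rep(TRUE, length(clusters)), clusters)
  for (cl in sort(clusters[clusters != n + 1L], decreasing = TRUE)) {
    kk <- kids_of[[as.character(cl)]]
    sub <- if (length(kk)) sum(stability[as.character(kk)]) else 0
    if (sub > stability[as.character(cl)]) {
      is_cluster[as.character(cl)] <- FALSE
      stability[as.character(cl)] <- sub
    } else {
      for (d in descendants(cl)) is_cluster[as.character(d)] <- FALSE
    }
  }
  clusters[is_cluster & clusters != n + 1L]
}

# Assign each point to its lowest selected ancestor cluster (NA = noise).
label_points <- function(cond, selected, n) {
  ed <- cond$edges
  parent_of <- stats::setNames(ed$parent, ed$child)  # child -> parent (clusters & points)
  labels <- rep(NA_integer_, n)
  if (length(selected) == 0L) return(labels)
  lab_id <- stats::setNames(seq_along(sort(selected)), sort(selected))
  pt_rows <- ed$size == 1
  for (i in which(pt_rows)) {
    cl <- ed$parent[i]
    while (!(cl %in% selected) && !is.na(parent_of[as.character(cl)])) {
      cl <- parent_of[as.character(cl)]
    }
    if (cl %in% selected) labels[ed$child[i]] <- lab_id[[as.character(cl)]]
  }
  labels
}
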