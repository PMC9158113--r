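# Independent brute-force oracles, deliberately naive and separate from the
# package implementations they check.

# Silhouette widths by direct evaluation of the formula, one observation at a
# time (singletons get 0).
oracle_silhouette <- function(X, labels) {
  n <- nrow(X)
  s <- numeric(n)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) next
    a <- mean(vapply(own, function(j) d(i, j), 1))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      members <- which(labels == cl)
      b <- min(b, mean(vapply(members, function(j) d(i, j), 1)))
    }
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# Adjusted Rand index by enumerating all observation pairs.
oracle_ari <- function(truth, pred) {
  n <- length(truth)
  same_t <- outer(truth, truth, "==")[upper.tri(diag(n))]
  same_p <- outer(pred, pred, "==")[upper.tri(diag(n))]
  a <- sum(same_t & same_p)     # agreements: together in both
  d <- sum(!same_t & !same_p)   # agreements: apart in both
  total <- choose(n, 2)
  # expected index from the contingency marginals
  nij <- sum(same_t & same_p)
  ai <- sum(same_t)
  bi <- sum(same_p)
  expected <- ai * bi / total
  maximum <- (ai + bi) / 2
  (nij - expected) / (maximum - expected)
}

# Classification accuracy by exhaustive search over label permutations.
oracle_accuracy <- function(truth, pred) {
  truth <- as.integer(truth)
  pred_ids <- sort(unique(pred[!is.na(pred)]))
  truth_ids <- sort(unique(truth))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  m <- max(length(pred_ids), length(truth_ids))
  padded_truth <- c(truth_ids, rep(-seq_len(m), length.out = m - length(truth_ids)))
  best <- 0
  for (p in perms(seq_len(m))) {
    mapping <- stats::setNames(padded_truth[p[seq_along(pred_ids)]], pred_ids)
    correct <- sum(!is.na(pred) & truth == mapping[as.character(pred)], na.rm = TRUE)
    best <- max(best, correct)
  }
  best / length(truth)
}

# Shared tiny fixtures.
two_blob_data <- function(n_per = 30, delta = 10, seed = 1) {
  simulate_dataset(power_design(2, delta), 2 * n_per, seed = seed)
}

rigid_motion <- function(X, angle = 0.7, shift = c(3, -2)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(as.matrix(X) %*% R, 2, -shift)
}
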