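#' Clustered-or-not decision rule
#'
#' Parameters of the binary detection decision: a dataset is declared
#' "clustered" when the best silhouette score over the candidate-k grid
#' reaches `silhouette_threshold` (0.5 by convention); `strong_threshold`
#' (0.7) marks strong evidence. `k_grid` is the inclusive candidate range
#' for algorithms that require a prespecified cluster count (2..5 for the
#' power tables; 2..7 for the matched method comparison). `alpha` is the
#' fuzzy-silhouette exponent used for soft partitions.
#'
#' @param silhouette_threshold Detection threshold in (0, 1); default 0.5.
#' @param strong_threshold Strong-evidence threshold in (0, 1); default 0.7.
#' @param k_grid Integer vector of candidate cluster counts; default 2:5.
#' @param alpha Fuzzy-silhouette exponent (default 1).
#' @return A `decision_rule` object.
#' @export
decision_rule <- function(silhouette_threshold = 0.5, strong_threshold = 0.7,
                          k_grid = 2:5, alpha = 1) {
  if (silhouette_threshold <= 0 || silhouette_threshold >= 1 ||
      strong_threshold <= 0 || strong_threshold >= 1) {
    abort("Thresholds must lie in (0, 1).")
  }
  if (length(k_grid) == 0 || any(k_grid < 2)) {
    abort("`k_grid` must be a nonempty set of integers >= 2.")
  }
  structure(list(silhouette_threshold = silhouette_threshold,
                 strong_threshold = strong_threshold,
                 k_grid = sort(as.integer(k_grid)), alpha = alpha),
            class = "decision_rule")
}

#' @export
print.decision_rule <- function(x, ...) {
  cat(sprintf("<decision_rule> silhouette >= %g (strong: %g), k in %d..%d, alpha = %g\n",
              x$silhouette_threshold, x$strong_threshold,
              min(x$k_grid), max(x$k_grid), x$alpha))
  invisible(x)
}

# Fit one algorithm across the candidate-k grid and score every solution.
# Returns a tibble (k, score, bic) plus a list of partitions. Degenerate fits
# (fewer than 2 populated clusters, failed mixture fits) score NA.
score_k_grid <- function(X, algorithm, rule, seed = NULL, min_cluster_size = 5) {
  grid <- rule$k_grid[rule$k_grid <= nrow(X)]
  rows <- purrr::map(seq_along(grid), function(i) {
    k <- grid[i]
    kseed <- if (is.null(seed)) NULL else derive_seed(seed, k)
    # degenerate fits (e.g. k above the number of distinct points) score NA
    part <- tryCatch(switch(algorithm,
      kmeans = run_kmeans(X, k, seed = kseed),
      ward_euclidean = run_agglomerative(X, k, "ward_euclidean"),
      average_cosine = run_agglomerative(X, k, "average_cosine"),
      cmeans = run_cmeans(X, k, seed = kseed),
      gmm = run_gmm(X, k, seed = kseed)
    ), error = function(e) NULL)
    score <- NA_real_
    bic <- NA_real_
    if (!is.null(part)) {
      fuzzy <- inherits(part, "fuzzy_partition") || inherits(part, "mixture_fit")
      labels <- if (fuzzy) part$hard_labels else part$labels
      if (length(unique(labels[!is.na(labels)])) >= 2) {
        score <- tryCatch({
          if (fuzzy) fuzzy_silhouette(X, part, alpha = rule$alpha)$score
          else silhouette_score(X, labels)$score
        }, error = function(e) NA_real_)
      }
      if (inherits(part, "mixture_fit")) bic <- part$bic
    } else if (algorithm == "gmm") {
      warn(sprintf("gmm fit failed for k = %d; excluded from model selection.", k))
    }
    list(row = tibble(k = k, score = score, bic = bic), part = part)
  })
  list(per_k = dplyr::bind_rows(purrr::map(rows, "row")),
       partitions = purrr::map(rows, "part"))
}

#' One-shot cluster detection on a dataset
#'
#' Runs one clustering algorithm over the candidate-k grid, scores each
#' solution with the appropriate silhouette (plain for hard partitions,
#' fuzzy with the rule's `alpha` for c-means memberships and mixture
#' posteriors), and selects the best k by maximum score (ties go to the
#' smallest k). HDBSCAN is fit once and reports its own cluster count; if it
#' finds fewer than 2 clusters the verdict is "not clustered". The dataset
#' is declared clustered when the best score reaches the rule's threshold.
#' When ground-truth labels (`.cluster`) are present, the adjusted Rand
#' index and optimally matched classification accuracy of the selected
#' partition are evaluated as well.
#'
#' @param data Dataset tibble or numeric matrix; an optional `.cluster`
#'   column provides ground truth for accuracy metrics.
#' @param algorithm One of `"kmeans"`, `"ward_euclidean"`,
#'   `"average_cosine"`, `"cmeans"`, `"gmm"`, `"hdbscan"`.
#' @param rule A [decision_rule()].
#' @param seed Optional integer seed for the stochastic algorithms.
#' @param min_cluster_size HDBSCAN minimum cluster size (default 5).
#' @return A `clustering_outcome`: best k, best silhouette, the binary
#'   clustered/strong verdicts, the selected partition, the per-k score
#'   table, the BIC-minimising k (mixtures only), and ARI/accuracy/chance
#'   when ground truth is available. See [tidy()] and [glance()] methods.
#' @examples
#' d <- simulate_dataset(power_design(2, 6), n = 80, seed = 1)
#' detect_clustering(d, "kmeans", seed = 1)
#' @export
detect_clustering <- function(data, algorithm = c("kmeans", "ward_euclidean",
                                                  "average_cosine", "cmeans",
                                                  "gmm", "hdbscan"),
                              rule = decision_rule(), seed = NULL,
                              min_cluster_size = 5) {
  algorithm <- match.arg(algorithm)
  X <- feature_matrix(data)
  truth <- truth_labels(data)

  if (algorithm == "hdbscan") {
    part <- run_hdbscan(X, min_cluster_size = min_cluster_size)
    best_k <- part$n_clusters
    best_score <- if (best_k >= 2) {
      tryCatch(silhouette_score(X, part)$score, error = function(e) NA_real_)
    } else NA_real_
    per_k <- tibble(k = best_k, score = best_score, bic = NA_real_)
    best_part <- part
    bic_best_k <- NA_integer_
  } else {
    sg <- score_k_grid(X, algorithm, rule, seed = seed)
    per_k <- sg$per_k
    if (all(is.na(per_k$score))) {
      best_k <- NA_integer_
      best_score <- NA_real_
      best_part <- NULL
    } else {
      i <- which.max(per_k$score)  # ties resolve to the smallest k (grid ascending)
      best_k <- per_k$k[i]
      best_score <- per_k$score[i]
      best_part <- sg$partitions[[i]]
    }
    bic_best_k <- if (algorithm == "gmm" && any(!is.na(per_k$bic))) {
      per_k$k[which.min(per_k$bic)]
    } else NA_integer_
  }

  is_clustered <- isTRUE(best_score >= rule$silhouette_threshold)
  is_strong <- isTRUE(best_score >= rule$strong_threshold)

  ari <- accuracy <- chance <- NA_real_
  if (!is.null(truth) && !is.null(best_part)) {
    labels <- if (inherits(best_part, "hard_partition")) best_part$labels else best_part$hard_labels
    ari <- adjusted_rand(truth, labels)
    acc <- classification_accuracy(truth, labels)
    accuracy <- acc$accuracy
    chance <- acc$chance
  }

  structure(
    list(algorithm = algorithm, best_k = best_k, best_silhouette = best_score,
         is_clustered = is_clustered, is_strong = is_strong,
         partition = best_part, per_k = per_k, bic_best_k = bic_best_k,
         ari = ari, accuracy = accuracy, chance = chance, rule = rule),
    class = "clustering_outcome"
  )
}

#' @export
print.clustering_outcome <- function(x, ...) {
  verdict <- if (x$is_strong) "clustered (strong evidence)"
  else if (x$is_clustered) "clustered" else "not clustered"
  cat(sprintf("<clustering_outcome> %s: %s\n", x$algorithm, verdict))
  cat(sprintf("  best k = %s, silhouette = %s (thresholds %g / %g)\n",
              format(x$best_k), format(round(x$best_silhouette, 4)),
              x$rule$silhouette_threshold, x$rule$strong_threshold))
  if (!is.na(x$ari)) {
    cat(sprintf("  vs ground truth: ARI = %.3f, accuracy = %.3f (chance %.3f)\n",
                x$ari, x$accuracy, x$chance))
  }
  invisible(x)
}

#' @describeIn detect_clustering Per-candidate-k score table.
#' @param x A `clustering_outcome`.
#' @param ... Unused.
#' @export
tidy.clustering_outcome <- function(x, ...) {
  dplyr::mutate(x$per_k, selected = .data$k == x$best_k & !is.na(x$best_k))
}

#' @describeIn detect_clustering One-row summary of the outcome.
#' @export
glance.clustering_outcome <- function(x, ...) {
  tibble(algorithm = x$algorithm, best_k = x$best_k,
         best_silhouette = x$best_silhouette, is_clustered = x$is_clustered,
         is_strong = x$is_strong, bic_best_k = x$bic_best_k,
         ari = x$ari, accuracy = x$accuracy, chance = x$chance)
}
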