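# Monte-Carlo power engine.

#' Monte-Carlo power of a clustering pipeline for one design cell
#'
#' Repeatedly simulates datasets of size `n` from a population design, runs
#' [detect_clustering()] on each, and aggregates: `power` is the fraction of
#' iterations declared clustered (for single-subgroup designs this is the
#' false-positive rate); `k_accuracy` the fraction whose selected k equals
#' the true subgroup count; `mean_accuracy` the average optimally matched
#' classification accuracy of the selected partition; `mean_silhouette` the
#' average best silhouette. Each iteration draws its own child seed from the
#' cell seed, so every cell is independently reproducible.
#'
#' @param design A [population_spec()] (e.g. from [power_design()]).
#' @param n Sample size per iteration.
#' @param algorithm Clustering algorithm (see [detect_clustering()]).
#' @param rule A [decision_rule()].
#' @param n_iterations Number of Monte-Carlo iterations (>= 1; 100 for
#'   table-level estimates).
#' @param seed Integer master seed for the cell.
#' @param min_cluster_size HDBSCAN minimum cluster size.
#' @return One-row tibble (class `power_cell` semantics): `algorithm`,
#'   `k_true`, `delta`, `n`, `power`, `k_accuracy`, `mean_accuracy`,
#'   `mean_silhouette`, `n_iterations`, `seed`.
#' @examples
#' \donttest{
#' estimate_power(power_design(2, 4), n = 10, algorithm = "kmeans",
#'                n_iterations = 20, seed = 7)
#' }
#' @export
estimate_power <- function(design, n, algorithm = "kmeans",
                           rule = decision_rule(), n_iterations = 100,
                           seed = 1, min_cluster_size = 5) {
  stopifnot(inherits(design, "population_spec"))
  if (n_iterations < 1) abort("`n_iterations` must be >= 1.")
  k_true <- design$k
  delta <- design_separation(design)

  res <- purrr::map(seq_len(n_iterations), function(it) {
    d <- simulate_dataset(design, n, seed = derive_seed(seed, it, 1))
    out <- detect_clustering(d, algorithm, rule = rule,
                             seed = derive_seed(seed, it, 2),
                             min_cluster_size = min_cluster_size)
    tibble(detected = out$is_clustered,
           best_k = out$best_k %||% NA_integer_,
           score = out$best_silhouette,
           accuracy = out$accuracy)
  })
  res <- dplyr::bind_rows(res)

  tibble(
    algorithm = algorithm, k_true = k_true,
    delta = ifelse(is.na(delta), 0, delta), n = as.integer(n),
    power = mean(res$detected),
    k_accuracy = if (k_true >= 2) mean(res$best_k == k_true, na.rm = FALSE) else NA_real_,
    mean_accuracy = mean(res$accuracy, na.rm = TRUE),
    mean_silhouette = mean(res$score, na.rm = TRUE),
    n_iterations = as.integer(n_iterations), seed = as.integer(seed)
  )
}

#' Power table over an effect-size by sample-size grid
#'
#' Runs [estimate_power()] for every combination of centroid separation
#' `delta` and sample size `n` under one population shape, producing the
#' power-table summary (one row per cell). Cell seeds are derived from the
#' master seed by cell index, so any cell can be recomputed in isolation.
#'
#' @param k Number of subgroups (1 to 4, equidistant layout).
#' @param delta Vector of centroid separations.
#' @param n Vector of sample sizes.
#' @param weights Subgroup proportions (default equal; e.g. `c(0.1, 0.9)`).
#' @param covariance Covariance kind for the 2-feature populations
#'   (default `"none"`).
#' @inheritParams estimate_power
#' @return A `power_table` tibble, one row per (delta, n) cell, with the
#'   master seed and rule in attributes. See [autoplot.power_table()] and
#'   [format_power_table()].
#' @examples
#' \donttest{
#' power_grid(k = 2, delta = c(2, 4, 6), n = c(20, 40),
#'            algorithm = "kmeans", n_iterations = 10, seed = 1)
#' }
#' @export
power_grid <- function(k, delta, n, algorithm = "kmeans", weights = NULL,
                       covariance = "none", rule = decision_rule(),
                       n_iterations = 100, seed = 1, min_cluster_size = 5) {
  cells <- tidyr::expand_grid(delta = delta, n = n)
  out <- purrr::map(seq_len(nrow(cells)), function(i) {
    design <- power_design(k, cells$delta[i], weights = weights,
                           covariance = covariance,
                           seed = derive_seed(seed, i, 0))
    estimate_power(design, cells$n[i], algorithm = algorithm, rule = rule,
                   n_iterations = n_iterations, seed = derive_seed(seed, i),
                   min_cluster_size = min_cluster_size)
  })
  out <- dplyr::bind_rows(out)
  out$weights <- paste(format(100 * (weights %||% rep(1 / k, k)), trim = TRUE,
                              digits = 3), collapse = "/")
  structure(out, class = c("power_table", class(out)),
            master_seed = seed, rule = rule)
}

#' Format a power table in wide percentage layout
#'
#' Reshapes a long `power_table` into the conventional wide layout: one row
#' per sample size, one column per centroid separation, integer
#' percentages.
#'
#' @param x A `power_table` from [power_grid()].
#' @param metric Column to spread: `"power"` (default), `"k_accuracy"`, or
#'   `"mean_accuracy"`.
#' @return A wide tibble with `n` rows and one `delta = ...` column per
#'   separation value.
#' @export
format_power_table <- function(x, metric = "power") {
  stopifnot(metric %in% c("power", "k_accuracy", "mean_accuracy"))
  x |>
    dplyr::mutate(value = round(100 * .data[[metric]]),
                  delta_lab = paste0("delta=", .data$delta)) |>
    dplyr::select("algorithm", "k_true", "weights", "n", "delta_lab", "value") |>
    tidyr::pivot_wider(names_from = "delta_lab", values_from = "value") |>
    dplyr::arrange(.data$n)
}

#' Matched comparison of discrete, fuzzy, and mixture clustering
#'
#' For each centroid separation, simulates `n_iterations` datasets from an
#' equal-weight equidistant design and runs every requested method on the
#' *same* data per iteration: k-means scored with the plain silhouette,
#' c-means and Gaussian mixtures with the fuzzy silhouette (exponent from
#' the rule). For mixtures it additionally records whether the
#' BIC-minimising k equals the true subgroup count. With `k_true = 1` the
#' reported "power" is the false-positive rate.
#'
#' @param k_true True number of subgroups (1 to 4).
#' @param delta Vector of centroid separations (ignored beyond a single 0
#'   when `k_true = 1`).
#' @param n Sample size per iteration (default 120).
#' @param methods Subset of `c("kmeans", "cmeans", "gmm")`.
#' @param rule A [decision_rule()]; the method comparison conventionally
#'   uses `k_grid = 2:7`.
#' @inheritParams estimate_power
#' @return A `method_comparison` tibble: one row per (method, delta) with
#'   `power`, `k_accuracy`, `bic_k_accuracy` (mixtures), and
#'   `mean_silhouette`; the full per-iteration log (including the
#'   any-method union detection) is in attribute `"per_iteration"`.
#' @examples
#' \donttest{
#' compare_methods(k_true = 2, delta = 3, n_iterations = 10, seed = 1)
#' }
#' @export
compare_methods <- function(k_true, delta, n = 120,
                            methods = c("kmeans", "cmeans", "gmm"),
                            rule = decision_rule(k_grid = 2:7),
                            n_iterations = 100, seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (k_true == 1) delta <- 0
  log <- purrr::map(seq_along(delta), function(di) {
    design <- power_design(k_true, delta[di])
    purrr::map(seq_len(n_iterations), function(it) {
      d <- simulate_dataset(design, n, seed = derive_seed(seed, di, it, 1))
      X <- feature_matrix(d)
      purrr::map(methods, function(m) {
        sg <- score_k_grid(X, m, rule, seed = derive_seed(seed, di, it, 2))
        per_k <- sg$per_k
        ok <- !all(is.na(per_k$score))
        i <- if (ok) which.max(per_k$score) else NA_integer_
        tibble(
          method = m, delta = delta[di], iteration = it,
          best_k = if (ok) per_k$k[i] else NA_integer_,
          best_score = if (ok) per_k$score[i] else NA_real_,
          detected = ok && per_k$score[i] >= rule$silhouette_threshold,
          bic_best_k = if (m == "gmm" && any(!is.na(per_k$bic))) {
            per_k$k[which.min(per_k$bic)]
          } else NA_integer_
        )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  summary <- log |>
    dplyr::group_by(.data$method, .data$delta) |>
    dplyr::summarise(
      power = mean(.data$detected),
      k_accuracy = if (k_true >= 2) mean(.data$best_k == k_true, na.rm = TRUE) else NA_real_,
      bic_k_accuracy = if (k_true >= 2) mean(.data$bic_best_k == k_true, na.rm = TRUE) else NA_real_,
      mean_silhouette = mean(.data$best_score, na.rm = TRUE),
      n_iterations = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(k_true = k_true, n = as.integer(n), seed = as.integer(seed))

  structure(summary, class = c("method_comparison", class(summary)),
            per_iteration = log, rule = rule)
}

#' Union (any-method) detection rate from a method comparison
#'
#' Fraction of iterations in which at least one of the compared methods
#' reached the detection threshold on the shared dataset — with a
#' single-subgroup design, the combined false-positive rate.
#'
#' @param x A `method_comparison` from [compare_methods()].
#' @return Tibble with one row per delta: `any_power`.
#' @export
union_detection_rate <- function(x) {
  log <- attr(x, "per_iteration")
  log |>
    dplyr::group_by(.data$delta, .data$iteration) |>
    dplyr::summarise(any = any(.data$detected), .groups = "drop") |>
    dplyr::group_by(.data$delta) |>
    dplyr::summarise(any_power = mean(.data$any), .groups = "drop")
}
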