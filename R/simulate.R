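#' Generate a correlation matrix for a simulated population
#'
#' Three covariance models for unit-variance features: `"none"` gives the
#' identity (uncorrelated features); `"random"` draws every off-diagonal
#' uniformly from \[-0.3, 0.3\]; `"factor"` partitions the features into
#' `n_factors` contiguous, near-equal blocks, draws within-block correlation
#' magnitudes uniformly from \[0.4, 0.9\] with one random sign per block, and
#' between-block correlations uniformly from \[-0.3, 0.3\]. Randomly filled
#' correlation matrices can be indefinite, so the result is repaired to
#' positive semi-definiteness by clipping negative eigenvalues at zero,
#' reconstructing, and rescaling to unit diagonal (set `repair = FALSE` to
#' inspect the raw draw).
#'
#' @param kind One of `"none"`, `"random"`, `"factor"`.
#' @param n_features Number of features p.
#' @param n_factors Number of factor blocks when `kind = "factor"` (3 or 4
#'   typical); must not exceed `n_features`.
#' @param seed Optional integer seed.
#' @param repair Repair the matrix to positive semi-definite (default TRUE).
#' @return A p x p correlation matrix.
#' @examples
#' make_covariance("factor", n_features = 15, n_factors = 3, seed = 1)
#' @export
make_covariance <- function(kind = c("none", "random", "factor"), n_features,
                            n_factors = 3, seed = NULL, repair = TRUE) {
  kind <- match.arg(kind)
  if (n_features < 1) abort("`n_features` must be >= 1.")
  if (kind == "none") return(diag(n_features))
  if (kind == "factor" && n_factors > n_features) {
    abort("Invalid design: `n_factors` must not exceed `n_features`.")
  }

  R <- with_seed_(seed, {
    R <- diag(n_features)
    lo <- lower.tri(R)
    if (kind == "random") {
      R[lo] <- runif(sum(lo), -0.3, 0.3)
    } else {
      # contiguous, near-equal factor blocks
      block <- sort(rep_len(seq_len(n_factors), n_features))
      same <- outer(block, block, "==") & lo
      R[lo] <- runif(sum(lo), -0.3, 0.3)
      sign_of <- sample(c(-1, 1), n_factors, replace = TRUE)
      for (f in seq_len(n_factors)) {
        idx <- same & outer(block, block, function(a, b) a == f & b == f)
        R[idx] <- sign_of[f] * runif(sum(idx), 0.4, 0.9)
      }
    }
    R[upper.tri(R)] <- t(R)[upper.tri(R)]
    R
  })
  if (repair) R <- repair_psd(R)
  R
}

# Eigenvalue clipping at 0, reconstruction, rescale to unit diagonal.
repair_psd <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= 0) return(R)
  lam <- pmax(e$values, 0)
  S <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(S))
  S <- S / tcrossprod(d)
  diag(S) <- 1
  (S + t(S)) / 2
}

#' Deterministic subgroup sizes from weights
#'
#' Largest-remainder apportionment: each subgroup gets `floor(weight * n)`
#' observations and the remainder goes to the largest fractional parts
#' (ties broken by subgroup order), so sizes always sum to `n`. Sizes are
#' deterministic rather than multinomially drawn, matching fixed-percentage
#' population designs (e.g. a 10%/90% split of N = 100 is exactly 10 and 90).
#'
#' @param weights Positive subgroup proportions summing to 1.
#' @param n Total sample size.
#' @return Integer vector of subgroup sizes summing to `n`.
#' @export
subgroup_sizes <- function(weights, n) {
  raw <- weights * n
  sizes <- floor(raw)
  rem <- round(n - sum(sizes))
  if (rem > 0) {
    ord <- order(raw - sizes, decreasing = TRUE)
    sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1
  }
  if (any(sizes == 0)) {
    abort("Sizing error: every subgroup must receive at least one observation; increase `n`.")
  }
  as.integer(sizes)
}

#' Sample a labelled dataset from a population specification
#'
#' Draws each subgroup from its multivariate normal distribution (mean array
#' and correlation matrix from the spec; all feature SDs are 1) with
#' deterministic subgroup sizes ([subgroup_sizes()]). Observations are
#' returned in generation order, one block per subgroup.
#'
#' @param spec A [population_spec()].
#' @param n Total sample size (>= k, with every subgroup receiving at least
#'   one observation).
#' @param seed Optional integer seed; the same seed reproduces the dataset
#'   bit-for-bit.
#' @return A tibble with feature columns `f1..fp` and an integer
#'   ground-truth column `.cluster` (1..k), carrying the generating spec in
#'   attribute `"spec"`.
#' @examples
#' spec <- power_design(k = 2, delta = 4)
#' simulate_dataset(spec, n = 20, seed = 1)
#' @export
simulate_dataset <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (n < spec$k) abort("`n` must be at least the number of subgroups.")
  sizes <- subgroup_sizes(spec$weights, n)
  X <- with_seed_(seed, {
    do.call(rbind, lapply(seq_len(spec$k), function(i) {
      Xi <- MASS::mvrnorm(sizes[i], mu = spec$means[[i]], Sigma = spec$covariances[[i]])
      matrix(Xi, nrow = sizes[i])
    }))
  })
  colnames(X) <- paste0("f", seq_len(spec$n_features))
  out <- as_tibble(as.data.frame(X))
  out$.cluster <- rep(seq_len(spec$k), sizes)
  attr(out, "spec") <- spec
  attr(out, "seed") <- seed
  class(out) <- c("labelled_dataset", class(out))
  out
}

#' Write or read a labelled dataset as delimited text
#'
#' Datasets are exchanged as comma-separated text with a header row; the
#' ground-truth label column `.cluster` is written last when present.
#'
#' @param data A dataset tibble (features plus optional `.cluster`).
#' @param path File path.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns a tibble (with `.cluster` as integer when the file has it).
#' @export
write_dataset <- function(data, path) {
  df <- as.data.frame(data)
  if (".cluster" %in% names(df)) {
    df <- df[c(setdiff(names(df), ".cluster"), ".cluster")]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) abort(sprintf("Parse error: `%s` contains no observations.", path))
  bad <- !vapply(df, is.numeric, TRUE)
  if (any(bad)) {
    abort(sprintf("Parse error: non-numeric values in column(s) %s of `%s`.",
                  paste(names(df)[bad], collapse = ", "), path))
  }
  if (".cluster" %in% names(df)) df$.cluster <- as.integer(df$.cluster)
  as_tibble(df)
}
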