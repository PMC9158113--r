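# Internal helpers shared across modules.

# Deterministic child-seed derivation. Cells/iterations get independent,
# recomputable streams from one master seed; all values stay < 2^31 - 1.
# Each round mixes an LCG step with xorshift scrambles so that consecutive
# indices do not map to an arithmetic progression of seeds (which would risk
# correlated generator initialisations). Products stay below 2^53, so the
# double arithmetic is exact.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483629  # large prime < 2^31
  s <- as.numeric(seed) %% m
  for (i in idx) {
    s <- (s * 48271 + as.numeric(i) * 10007 + 1) %% m
    si <- as.integer(s)
    si <- bitwXor(si, bitwShiftR(si, 16))
    s <- (as.numeric(si) * 69069 + 3) %% m
    si <- as.integer(s)
    si <- bitwXor(si, bitwShiftR(si, 13))
    s <- as.numeric(si) %% m
  }
  as.integer(s)
}

# Run `expr` under a local RNG state seeded with `seed`; if seed is NULL the
# global RNG stream is used as-is.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Extract the numeric feature matrix from a labelled-dataset tibble, a plain
# data frame, or a matrix. The ground-truth column `.cluster` is dropped.
feature_matrix <- function(data) {
  if (is.matrix(data)) {
    storage.mode(data) <- "double"
    return(data)
  }
  df <- as.data.frame(data)
  df[[".cluster"]] <- NULL
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    abort("`data` must contain only numeric feature columns (besides `.cluster`).")
  }
  m
}

# Ground-truth labels if present, else NULL.
truth_labels <- function(data) {
  if (is.data.frame(data) && ".cluster" %in% names(data)) {
    as.integer(data[[".cluster"]])
  } else {
    NULL
  }
}

check_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s.", name, format(min)))
  }
  invisible(x)
}
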