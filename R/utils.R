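# Internal helpers shared across modules.

# Deterministic child-seed derivation so that the cohort -> patient -> site ->
# replicate random streams are hierarchical: redrawing one branch never
# perturbs its siblings. Arithmetic stays below 2^53 so it is exact in doubles.
derive_seed <- function(seed, ...) {
  s <- as.numeric(seed) %% 2147483629
  for (idx in c(...)) {
    s <- (s * 69069 + as.numeric(idx) * 1000003 + 1) %% 2147483629
  }
  as.integer(s) + 1L
}

# Run an expression under a local RNG state (does not disturb the caller's).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Column standardization with training-derived parameters. Constant columns
# get scale 1 so they map to zero rather than NaN.
standardize_fit <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

standardize_apply <- function(X, par) {
  sweep(sweep(X, 2, par$center, "-"), 2, par$scale, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Column medians via one radix sort of the whole matrix; orders of magnitude
# faster than apply(X, 2, median) on wide replicate stacks.
col_medians <- function(X) {
  n <- nrow(X)
  S <- matrix(X[order(col(X), X)], nrow = n)
  if (n %% 2 == 1) S[(n + 1) %/% 2, ] else (S[n %/% 2, ] + S[n %/% 2 + 1, ]) / 2
}
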