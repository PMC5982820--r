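## Internal helpers shared across modules.

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derived substream seed, kept below 2^31.
subSeed <- function(seed, offset) {
  (as.numeric(seed) * 1009 + offset * 9973) %% 2147483647
}

# Symmetric matrix square root via eigendecomposition (PSD-safe).
symSqrt <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  e$vectors %*% (sqrt(ev) * t(e$vectors))
}

# log-determinant from a Cholesky factor.
logDetChol <- function(R) 2 * sum(log(diag(R)))

# Stop with a classed error for consistent testing.
stopf <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Consistent experiment factor ordering: order of first appearance in the
# configuration / data, so simulated and fitted objects align.
experimentLevels <- function(x) {
  if (is.factor(x)) levels(x) else unique(as.character(x))
}
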