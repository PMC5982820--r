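## Factor-analytic covariance machinery.

# Parse "none" / "diag" / "fa<k>" into list(type, k).
parseStructure <- function(s) {
  if (s == "none") return(list(type = "none", k = 0L))
  if (s == "diag") return(list(type = "diag", k = 0L))
  k <- as.integer(sub("^fa", "", s))
  list(type = "fa", k = k)
}

# Number of free covariance parameters of one structure at p environments.
nStructureParams <- function(s, p) {
  st <- parseStructure(s)
  switch(st$type,
    none = 0L,
    diag = as.integer(p),
    fa = {
      k <- st$k
      if (k > p - 1)
        stopf("faGBLUP_spec_error",
              "FA order k = %d must be < p = %d (over-parameterized)", k, p)
      as.integer(p * k - k * (k - 1) / 2 + p)
    })
}

#' Count genetic covariance parameters of a model
#'
#' Counts the estimated across-environment genetic covariance parameters of
#' a model specification at p environments: a diagonal structure
#' contributes p variances per genetic component; an FA(k) structure
#' contributes pk loadings minus k(k-1)/2 identifiability constraints plus
#' p specific variances. Design and residual variances are not counted,
#' matching the usual reporting convention for model-ladder tables.
#'
#' @param spec a \linkS4class{ModelSpec} (or a length-2 character vector
#'   \code{c(additive, residualGenetic)}).
#' @param p number of environments.
#' @return integer parameter count.
#' @examples
#' countParameters(modelSpec("fa2", "fa2"), p = 8)  # 46
#' countParameters(c("fa1", "fa2"), p = 8)          # 39
#' @export
countParameters <- function(spec, p) {
  if (p < 1) stopf("faGBLUP_spec_error", "p must be >= 1")
  if (is.character(spec) && length(spec) == 2)
    spec <- modelSpec(spec[1], spec[2])
  stopifnot(is(spec, "ModelSpec"))
  nStructureParams(spec@additive, p) + nStructureParams(spec@residualGenetic, p)
}

#' Covariance matrix implied by a factor-analytic structure
#'
#' Returns \eqn{\Lambda \Lambda' + \mathrm{diag}(\psi)}, the p x p
#' across-environment covariance implied by the loadings and specific
#' variances. Always symmetric positive semidefinite.
#'
#' @param fa an \linkS4class{FAStructure}.
#' @return p x p numeric matrix.
#' @export
faCovariance <- function(fa) {
  stopifnot(is(fa, "FAStructure"))
  tcrossprod(fa@loadings) + diag(fa@specificVariances,
                                 nrow = length(fa@specificVariances))
}

## Parameter packing for one genetic structure -------------------------------
## Free parameters: FA loadings in column-major order skipping the
## constrained upper triangle, then log(psi); DIAG: log(sigma2_j).

structureParIndex <- function(s, p) {
  st <- parseStructure(s)
  if (st$type == "none") return(list(n = 0L))
  if (st$type == "diag") return(list(n = as.integer(p), st = st))
  k <- st$k
  free <- which(outer(seq_len(p), seq_len(k), ">=")) # column-major lower part
  list(n = as.integer(length(free) + p), st = st, free = free)
}

# Unpack a structure's parameter sub-vector into its G matrix (and parts).
unpackStructure <- function(s, p, theta) {
  st <- parseStructure(s)
  if (st$type == "none")
    return(list(G = matrix(0, p, p), fa = NULL))
  if (st$type == "diag") {
    v <- exp(theta)
    return(list(G = diag(v, nrow = p), fa = NULL, variances = v))
  }
  k <- st$k
  idx <- structureParIndex(s, p)
  L <- matrix(0, p, k)
  L[idx$free] <- theta[seq_along(idx$free)]
  psi <- exp(theta[length(idx$free) + seq_len(p)])
  fa <- faStructure(L, psi)
  list(G = faCovariance(fa), fa = fa, loadings = L, psi = psi)
}

# Derivative matrices dG/dtheta_r for a structure at the current parameters.
# Returns a list of p x p matrices in the packing order.
structureDerivs <- function(s, p, theta) {
  st <- parseStructure(s)
  if (st$type == "none") return(list())
  if (st$type == "diag") {
    v <- exp(theta)
    lapply(seq_len(p), function(j) {
      D <- matrix(0, p, p); D[j, j] <- v[j]; D
    })
  } else {
    k <- st$k
    idx <- structureParIndex(s, p)
    up <- unpackStructure(s, p, theta)
    L <- up$loadings
    derivs <- vector("list", idx$n)
    for (r in seq_along(idx$free)) {
      pos <- idx$free[r]
      a <- (pos - 1) %% p + 1
      b <- (pos - 1) %/% p + 1
      D <- matrix(0, p, p)
      D[a, ] <- D[a, ] + L[, b]
      D[, a] <- D[, a] + L[, b]
      D[a, a] <- 2 * L[a, b]
      derivs[[r]] <- D
    }
    for (j in seq_len(p)) {
      D <- matrix(0, p, p); D[j, j] <- up$psi[j]
      derivs[[length(idx$free) + j]] <- D
    }
    derivs
  }
}
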