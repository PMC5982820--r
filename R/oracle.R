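## Independent dense verification oracle for the REML engine. Uses the
## error-contrast (projection-matrix) form of the REML log-likelihood and
## builds the marginal covariance from explicitly materialized design
## matrices and Kronecker products -- a deliberately different code path
## from the fitting engines.

#' Dense REML log-likelihood oracle
#'
#' Evaluates the REML log-likelihood at given variance parameters directly
#' from the dense marginal covariance
#' \eqn{V = Z_g (G_a \otimes K) Z_g' + Z_g (G_{\bar a} \otimes I) Z_g' +
#' \sum_f \sigma^2_f Z_f Z_f' + R}
#' via an orthonormal basis A of the error-contrast space
#' (\eqn{A'X = 0}):
#' \deqn{\ell = -\tfrac12 [ (n-t)\log 2\pi + \log|A'VA| +
#'   y'A (A'VA)^{-1} A'y ].}
#' No optimization is performed. Intended for verification on instances
#' small enough for dense n x n algebra.
#'
#' @param data,K,spec as in \code{\link{remlFit}}.
#' @param parameters list with \code{Ga}, \code{Gabar} (p x p matrices or
#'   \linkS4class{FAStructure} objects), \code{design} (named variances in
#'   the order of the spec's design terms) and \code{residual} (named
#'   variances per residual group level).
#' @return REML log-likelihood value (same constant convention as
#'   \code{\link{remlFit}}).
#' @export
loglikOracle <- function(data, K, parameters, spec) {
  md <- assembleModelData(data, K, spec)
  if (md$n > 4000)
    stopf("faGBLUP_oracle_error",
          "oracle is dense; n = %d exceeds the supported size", md$n)
  asCov <- function(g) if (is(g, "FAStructure")) faCovariance(g) else
    as.matrix(g)
  p <- md$p
  mo <- length(md$obsLines)
  Ko <- md$Kall[md$obsIdx, md$obsIdx, drop = FALSE]

  ## Z_g: n x (m_o p), cell order lines-within-experiment (env-major).
  cellCol <- (md$jidx - 1L) * mo + md$iidx
  Zg <- matrix(0, md$n, mo * p)
  Zg[cbind(seq_len(md$n), cellCol)] <- 1

  V <- matrix(0, md$n, md$n)
  if (md$spec@additive != "none" || !is.null(parameters$Ga)) {
    Ga <- asCov(parameters$Ga)
    V <- V + Zg %*% kronecker(Ga, Ko) %*% t(Zg)
  }
  if (md$spec@residualGenetic != "none" || !is.null(parameters$Gabar)) {
    Gab <- asCov(parameters$Gabar)
    V <- V + Zg %*% kronecker(Gab, diag(mo)) %*% t(Zg)
  }
  if (length(md$designTerms)) {
    dv <- parameters$design
    for (i in seq_along(md$designTerms)) {
      tm <- md$designTerms[[i]]
      Zf <- matrix(0, md$n, tm$nlev)
      ok <- !is.na(tm$lev)
      Zf[cbind(which(ok), tm$lev[ok])] <- 1
      V <- V + dv[[i]] * tcrossprod(Zf)
    }
  }
  rv <- parameters$residual
  diag(V) <- diag(V) + rv[md$rgroup]

  n <- md$n; t <- md$t
  Q <- qr.Q(qr(md$X), complete = TRUE)
  A <- Q[, (t + 1):n, drop = FALSE]
  AVA <- crossprod(A, V) %*% A
  ch <- chol(AVA)
  Ay <- crossprod(A, md$y)
  quad <- sum(Ay * backsolve(ch, forwardsolve(t(ch), Ay)))
  -0.5 * ((n - t) * log(2 * pi) + logDetChol(ch) + quad)
}
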