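## remlFit: maximize the REML log-likelihood over all variance parameters
## and assemble the fitted-model object.

#' Fit the multi-environment genomic mixed model by REML
#'
#' Fits the single-stage model
#' \deqn{y = X\tau + Z_g u_a + Z_g u_{\bar a} + Z_u u + \eta,\quad
#'   \mathrm{var}(u_a) = G_a \otimes K,\ \mathrm{var}(u_{\bar a}) =
#'   G_{\bar a} \otimes I_m}
#' with diagonal or factor-analytic across-environment structures for the
#' two genetic components, one variance per declared design random term and
#' heterogeneous residual variances over the residual grouping. The REML
#' log-likelihood is maximized by L-BFGS-B on an unconstrained
#' parameterization (free loadings, log variances) with analytic gradients.
#'
#' Two exact computational routes are used: a dense marginal-covariance
#' evaluation for general unbalanced data, and a fast route exploiting the
#' eigendecomposition of K when the data are balanced (one record per line
#' per experiment, no design terms), which block-diagonalizes the
#' likelihood over the m eigencomponents. Both give identical likelihoods.
#'
#' Solutions (BLUPs) of both genetic components are returned for every
#' line of K in every experiment: lines without phenotype records are
#' predicted through their genomic relationships (their residual genetic
#' BLUPs are 0 by construction, as the identity kernel carries no
#' information across lines).
#'
#' @param data phenotype data.frame with columns \code{experiment},
#'   \code{line}, \code{value}, plus any design/grouping columns the spec
#'   references.
#' @param K a \linkS4class{RelationshipMatrix} covering all data lines
#'   (extra lines are allowed and receive genomic predictions).
#' @param spec a \linkS4class{ModelSpec}.
#' @param engine \code{"auto"} (default), \code{"dense"} or \code{"eigen"}.
#' @param computePEV retain the internals needed by \code{\link{pevBlock}}
#'   (default TRUE; turn off inside cross-validation loops).
#' @param maxit L-BFGS-B iteration cap (default 500); \code{maxit = 0}
#'   evaluates BLUPs and PEVs at the supplied \code{start} without
#'   optimization (fixed-parameter mode).
#' @param start optional numeric starting parameter vector (advanced).
#' @return a \linkS4class{FittedFAModel}.
#' @seealso \code{\link{pevBlock}}, \code{\link{extractGEBV}},
#'   \code{\link{loglikOracle}}
#' @export
remlFit <- function(data, K, spec, engine = c("auto", "dense", "eigen"),
                    computePEV = TRUE, maxit = 500, start = NULL) {
  engine <- match.arg(engine)
  md <- assembleModelData(data, K, spec)
  useEigen <- switch(engine,
    auto = eigenEligible(md),
    eigen = {
      if (!eigenEligible(md))
        stopf("faGBLUP_engine_error",
              "data/spec are not eligible for the eigen engine")
      TRUE
    },
    dense = FALSE)
  setup <- if (useEigen) eigenSetup(md) else denseSetup(md)
  sv <- startingValues(md)
  theta0 <- if (is.null(start)) sv$theta else start

  cache <- new.env(parent = emptyenv())
  evalAt <- function(theta) {
    if (!is.null(cache$theta) && identical(cache$theta, theta))
      return(cache$ev)
    ev <- if (useEigen) eigenEval(md, setup, theta)
          else denseEval(md, setup, theta)
    cache$theta <- theta
    cache$ev <- ev
    ev
  }
  fn <- function(theta) {
    ev <- evalAt(theta)
    if (is.null(ev)) return(1e10)
    -ev$value
  }
  gr <- function(theta) {
    ev <- evalAt(theta)
    if (is.null(ev)) return(numeric(length(theta)))
    if (useEigen) return(-eigenGradient(md, setup, theta, ev))
    if (is.null(ev$Pmat)) {
      Vinv <- chol2inv(ev$cholV)
      Ainv <- chol2inv(ev$cholA)
      ev$Pmat <- Vinv - ev$VinvX %*% Ainv %*% t(ev$VinvX)
      cache$ev <- ev
    }
    -denseGradient(md, setup, theta, ev)
  }

  if (maxit == 0) {
    ## fixed-parameter mode: evaluate BLUPs/PEVs at the supplied start.
    opt <- list(par = theta0, value = fn(theta0), convergence = 0L,
                counts = c(0L, 0L), message = "fixed parameters")
  } else {
    opt <- stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                        lower = sv$lower, upper = sv$upper,
                        control = list(maxit = maxit))
    ## restart on abnormal termination (line-search failures on flat
    ## likelihood ridges); L-BFGS-B resets its Hessian approximation.
    tries <- 0
    while (opt$convergence != 0 && tries < 2) {
      opt2 <- stats::optim(opt$par, fn, gr, method = "L-BFGS-B",
                           lower = sv$lower, upper = sv$upper,
                           control = list(maxit = maxit))
      improved <- opt2$value < opt$value - 1e-10
      if (opt2$convergence == 0 || improved) opt <- opt2
      if (!improved && opt$convergence != 0) break
      tries <- tries + 1
    }
  }
  converged <- opt$convergence == 0 && is.finite(opt$value) &&
    opt$value < 1e9
  if (!converged && is.finite(opt$value) && opt$value < 1e9) {
    ## accept a stationary point: projected gradient (bounds respected)
    ## numerically zero although the line search gave up.
    g <- gr(opt$par)
    atLow <- opt$par <= sv$lower + 1e-12 & g > 0
    atUp <- opt$par >= sv$upper - 1e-12 & g < 0
    g[atLow | atUp] <- 0
    if (max(abs(g)) < 1e-3 * max(1, abs(opt$value))) converged <- TRUE
  }

  ev <- if (useEigen) eigenEval(md, setup, opt$par)
        else denseEval(md, setup, opt$par, needP = computePEV)
  if (is.null(ev))
    stopf("faGBLUP_fit_error",
          "covariance became non-positive-definite at the returned optimum")
  pars <- ev$pars
  dn <- list(md$expLevels, md$expLevels)
  dimnames(pars$Ga) <- dimnames(pars$Gab) <- dn

  blup <- if (useEigen) eigenBlup(md, setup, ev)
          else denseBlup(md, setup, ev)

  internals <- list(engine = if (useEigen) "eigen" else "dense",
                    W = blup$W, obsIdx = md$obsIdx, p = md$p,
                    expLevels = md$expLevels, obsLines = md$obsLines)
  if (computePEV) {
    if (useEigen) {
      internals$setup <- setup[c("U", "d", "cvec", "mo", "Ko",
                                 "rgroupOfExp")]
      internals$ev <- list(Vinv = ev$Vinv, Ainv = ev$Ainv, pars = pars)
    } else {
      internals$cellT <- denseCellT(md, ev)
      internals$Ko <- setup$Ko
      internals$pars <- pars
    }
  }

  beta <- drop(ev$beta)
  names(beta) <- colnames(md$X)
  new("FittedFAModel", spec = spec, experiments = md$expLevels,
      lines = md$linesAll, observedLines = md$obsLines,
      Ga = pars$Ga, Gabar = pars$Gab,
      faAdditive = pars$faA, faResidual = pars$faB,
      designVariances = pars$design, residualVariances = pars$resid,
      fixedEffects = beta, loglik = ev$value,
      nParams = countParameters(spec, md$p), converged = converged,
      trace = list(counts = opt$counts, convergence = opt$convergence,
                   message = if (is.null(opt$message)) "" else opt$message),
      solutions = list(ua = blup$ua, uabar = blup$uabar),
      internals = internals)
}

#' Prediction error variance block of a fitted model
#'
#' Returns the m x m prediction error (co)variance matrix, over the
#' observed lines, of the average of the requested quantity over a set of
#' experiments: \code{type = "gv"} for total genotypic values
#' (\eqn{\hat u_a + \hat u_{\bar a}}), \code{type = "gebv"} for breeding
#' values (\eqn{\hat u_a}). A single experiment gives the per-experiment
#' PEV block used by \code{\link{appev}}; several experiments give the PEV
#' of the simple mean across them (used for cluster-level heritability).
#'
#' @param fit a \linkS4class{FittedFAModel} fitted with
#'   \code{computePEV = TRUE}.
#' @param experiments character vector of experiment labels (or integer
#'   indices).
#' @param type \code{"gv"} or \code{"gebv"}.
#' @return symmetric m x m matrix over the observed lines.
#' @export
pevBlock <- function(fit, experiments, type = c("gv", "gebv")) {
  type <- match.arg(type)
  it <- fit@internals
  if (is.null(it$W) || (is.null(it$cellT) && is.null(it$ev)))
    stopf("faGBLUP_pev_error",
          "fit was created with computePEV = FALSE; refit to query PEVs")
  if (is.numeric(experiments)) experiments <- it$expLevels[experiments]
  jset <- match(experiments, it$expLevels)
  if (anyNA(jset))
    stopf("faGBLUP_pev_error", "unknown experiment(s): %s",
          paste(experiments[is.na(jset)], collapse = ", "))
  mo <- length(it$obsLines)
  acc <- matrix(0, mo, mo)
  md <- list(p = it$p, obsLines = it$obsLines)
  for (j in jset) for (jp in jset) {
    blk <- if (it$engine == "eigen")
      eigenPevBlock(md, it$setup, it$ev, j, jp, type)
    else
      densePevBlock(md, list(Ko = it$Ko), list(pars = it$pars),
                    it$cellT, j, jp, type)
    acc <- acc + blk
  }
  acc <- acc / length(jset)^2
  acc <- (acc + t(acc)) / 2
  dimnames(acc) <- list(it$obsLines, it$obsLines)
  acc
}
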