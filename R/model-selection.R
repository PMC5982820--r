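## Model ladder: information criteria and likelihood-ratio tests across
## nested covariance structures.

#' Akaike's information criterion
#'
#' \code{AIC = 2 nParams - 2 loglik}, the convention used in model-ladder
#' tables where \code{nParams} counts the genetic covariance parameters.
#'
#' @param loglik REML log-likelihood.
#' @param nParams number of estimated (genetic covariance) parameters.
#' @return AIC value.
#' @examples
#' aic(4405.638, 32)  # -8747.276
#' @export
aic <- function(loglik, nParams) 2 * nParams - 2 * loglik

#' Likelihood-ratio test between nested fits
#'
#' Statistic \eqn{2(\ell_{full} - \ell_{reduced})} referred to a
#' chi-square distribution with \code{df} degrees of freedom (no boundary
#' mixture correction, which makes the test anti-conservative for variance
#' parameters on the boundary). A negative statistic marks a non-nested or
#' non-converged comparison and is flagged rather than hidden.
#'
#' @param loglikFull,loglikReduced REML log-likelihoods of the two models
#'   (same fixed effects).
#' @param df difference in parameter counts (>= 1).
#' @return list with \code{statistic}, \code{df}, \code{pValue},
#'   \code{flagged}.
#' @examples
#' lrt(4405.638, 4037.480, 16)$statistic  # 736.316
#' @export
lrt <- function(loglikFull, loglikReduced, df) {
  if (df < 1) stopf("faGBLUP_ms_error", "df must be >= 1")
  stat <- 2 * (loglikFull - loglikReduced)
  flagged <- stat < 0
  p <- if (flagged) NA_real_ else
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, pValue = p, flagged = flagged)
}

# Structure complexity rank: none < diag < fa1 < fa2 < ...
structureRank <- function(s) {
  st <- parseStructure(s)
  switch(st$type, none = 0L, diag = 1L, fa = 1L + st$k)
}

# Is the (additive, residual) pair `red` nested within `full`?
nestedIn <- function(red, full) {
  structureRank(red[1]) <= structureRank(full[1]) &&
    structureRank(red[2]) <= structureRank(full[2])
}

#' Fit a ladder of nested covariance structures
#'
#' Fits each (additive, residual genetic) structure pair with
#' \code{\link{remlFit}}, reports genetic parameter counts, AIC, and a
#' likelihood-ratio test of each model against the most complex previously
#' listed model nested within it. The minimum-AIC converged model is
#' selected as final. Fixed effects and design terms are shared across the
#' ladder (taken from \code{baseSpec}), so REML log-likelihoods are
#' comparable.
#'
#' @param data,K as in \code{\link{remlFit}}.
#' @param structures list of length-2 character vectors
#'   \code{c(additive, residualGenetic)}, ordered from simplest to most
#'   complex; default the DIAG/FA ladder
#'   \code{DIAG/DIAG, FA1/FA1, FA1/FA2, FA2/FA1, FA2/FA2}.
#' @param baseSpec a \linkS4class{ModelSpec} supplying the non-genetic
#'   parts (design random terms, residual grouping, fixed effects).
#' @param computePEV passed to the final refit only; ladder fits skip PEV.
#' @param maxit iteration cap per fit.
#' @return list with \code{table} (data.frame mirroring the usual ladder
#'   report), \code{fits} (list of \linkS4class{FittedFAModel}),
#'   \code{selected} (index of the minimum-AIC converged model).
#' @export
modelLadder <- function(data, K,
                        structures = list(c("diag", "diag"),
                                          c("fa1", "fa1"),
                                          c("fa1", "fa2"),
                                          c("fa2", "fa1"),
                                          c("fa2", "fa2")),
                        baseSpec = modelSpec(), computePEV = FALSE,
                        maxit = 500) {
  nmod <- length(structures)
  fits <- vector("list", nmod)
  rows <- vector("list", nmod)
  ids <- vapply(structures, function(s)
    paste(toupper(s[1]), toupper(s[2]), sep = "/"), character(1))
  p <- length(experimentLevels(data$experiment))
  for (i in seq_len(nmod)) {
    s <- structures[[i]]
    spec <- modelSpec(s[1], s[2], designRandom = baseSpec@designRandom,
                      designNesting = baseSpec@designNesting,
                      varianceGrouping = baseSpec@varianceGrouping,
                      residualGrouping = baseSpec@residualGrouping,
                      fixed = baseSpec@fixed)
    ## warm start from the most complex earlier converged nested model
    start <- NULL
    if (i > 1) {
      cand <- which(vapply(seq_len(i - 1), function(r)
        !is.null(fits[[r]]) && fits[[r]]@converged &&
          nestedIn(structures[[r]], s), logical(1)))
      if (length(cand)) {
        npc <- vapply(cand, function(r)
          countParameters(c(structures[[r]][1], structures[[r]][2]), p),
          integer(1))
        src <- fits[[cand[which.max(npc)]]]
        start <- tryCatch(
          warmStartTheta(assembleModelData(data, K, spec), src),
          error = function(e) NULL)
      }
    }
    fit <- tryCatch(remlFit(data, K, spec, computePEV = FALSE,
                            maxit = maxit, start = start),
                    error = function(e) e)
    if (!is.null(start) &&
        (inherits(fit, "error") || !fit@converged)) {
      cold <- tryCatch(remlFit(data, K, spec, computePEV = FALSE,
                               maxit = maxit),
                       error = function(e) e)
      if (!inherits(cold, "error") &&
          (inherits(fit, "error") || cold@loglik > fit@loglik ||
           (cold@converged && !fit@converged)))
        fit <- cold
    }
    failed <- inherits(fit, "error")
    fits[[i]] <- if (failed) NULL else fit
    np <- countParameters(spec, p)
    ll <- if (failed) NA_real_ else fit@loglik
    conv <- if (failed) FALSE else fit@converged
    ## reduced model: most complex earlier converged model nested in this.
    redIdx <- NA_integer_; lstat <- NA_real_; ldf <- NA_integer_
    lp <- NA_real_; flagged <- FALSE
    if (i > 1 && !failed) {
      cand <- which(vapply(seq_len(i - 1), function(r)
        !is.null(fits[[r]]) && nestedIn(structures[[r]], s) &&
          countParameters(c(structures[[r]][1], structures[[r]][2]), p) < np,
        logical(1)))
      if (length(cand)) {
        npc <- vapply(cand, function(r)
          countParameters(c(structures[[r]][1], structures[[r]][2]), p),
          integer(1))
        redIdx <- cand[which.max(npc)]
        ldf <- np - npc[which.max(npc)]
        cmp <- lrt(ll, fits[[redIdx]]@loglik, ldf)
        lstat <- cmp$statistic; lp <- cmp$pValue; flagged <- cmp$flagged
      }
    }
    rows[[i]] <- data.frame(
      model = ids[i], additive = toupper(s[1]),
      residual_genetic = toupper(s[2]),
      loglik = ll, aic = if (failed) NA_real_ else aic(ll, np),
      n_params = np, df = ldf,
      comparison = if (is.na(redIdx)) "" else paste("to", ids[redIdx]),
      lrt_statistic = lstat, p_value = lp,
      converged = conv, flagged = flagged, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- which(tab$converged & !is.na(tab$aic))
  selected <- if (length(ok)) ok[which.min(tab$aic[ok])] else NA_integer_
  if (!is.na(selected) && computePEV) {
    spec <- fits[[selected]]@spec
    start <- tryCatch(
      warmStartTheta(assembleModelData(data, K, spec), fits[[selected]]),
      error = function(e) NULL)
    fits[[selected]] <- remlFit(data, K, spec, computePEV = TRUE,
                                maxit = maxit, start = start)
  }
  list(table = tab, fits = fits, selected = selected)
}
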