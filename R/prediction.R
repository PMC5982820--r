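## Genetic summaries of a fitted model: GEBVs, GVs, between-environment
## correlations, environment clusters, APPEV-based heritabilities and
## variance partitions.

makeGeneticValues <- function(fit, clusters = NULL) {
  sol <- fit@solutions
  if (is.null(sol$ua))
    stopf("faGBLUP_pred_error", "fit carries no random-effect solutions")
  exps <- fit@experiments
  lines <- fit@lines
  gebv <- sol$ua
  gv <- sol$ua + sol$uabar
  values <- data.frame(
    line = rep(lines, times = length(exps)),
    experiment = rep(exps, each = length(lines)),
    gebv = as.vector(gebv), gv = as.vector(gv),
    stringsAsFactors = FALSE)
  if (is.null(clusters))
    clusters <- stats::setNames(rep("all", length(exps)), exps)
  clusters <- clusters[exps]
  cm <- list()
  for (cl in unique(clusters)) {
    member <- exps[clusters == cl]
    cm[[cl]] <- data.frame(
      line = lines, cluster = cl,
      gebv = rowMeans(gebv[, member, drop = FALSE]),
      gv = rowMeans(gv[, member, drop = FALSE]),
      stringsAsFactors = FALSE)
  }
  cm[["overall"]] <- data.frame(
    line = lines, cluster = "overall",
    gebv = rowMeans(gebv), gv = rowMeans(gv), stringsAsFactors = FALSE)
  clusterMeans <- do.call(rbind, cm)
  rownames(clusterMeans) <- NULL
  new("GeneticValues", values = values, clusterMeans = clusterMeans,
      clusters = clusters)
}

#' Extract genomic estimated breeding values
#'
#' GEBV for line i at experiment j is the additive BLUP
#' \eqn{\hat u_{a,ij}} of the fitted model; BLUPs exist for every
#' line-by-experiment cell, including untested lines (predicted through
#' the genomic relationship matrix). Cluster and overall columns are
#' simple arithmetic means over member experiments.
#'
#' @param fit a \linkS4class{FittedFAModel}.
#' @param clusters optional named character vector mapping experiment to
#'   cluster label (as from \code{\link{clusterEnvironments}}).
#' @return a \linkS4class{GeneticValues} (both \code{gebv} and \code{gv}
#'   columns are populated).
#' @export
extractGEBV <- function(fit, clusters = NULL) makeGeneticValues(fit, clusters)

#' Extract total genotypic values
#'
#' GV for line i at experiment j is the sum of the additive and residual
#' genetic BLUPs, \eqn{\hat u_{a,ij} + \hat u_{\bar a, ij}} -- the model's
#' best estimate of the line's total genotypic value in that environment.
#'
#' @inheritParams extractGEBV
#' @return a \linkS4class{GeneticValues}.
#' @export
extractGV <- function(fit, clusters = NULL) makeGeneticValues(fit, clusters)

#' Between-environment genetic correlation matrix
#'
#' Converts the fitted across-environment covariance of the requested
#' genetic component to a correlation matrix: \code{"additive"} from
#' \eqn{G_a}, \code{"residual"} from \eqn{G_{\bar a}}, \code{"total"} from
#' \eqn{G_a + G_{\bar a}} (commensurable because K is scaled to mean
#' diagonal 1).
#'
#' @param fit a \linkS4class{FittedFAModel}.
#' @param component \code{"total"}, \code{"additive"} or \code{"residual"}.
#' @return p x p correlation matrix with unit diagonal.
#' @export
envCorrelation <- function(fit,
                           component = c("total", "additive", "residual")) {
  component <- match.arg(component)
  G <- switch(component, additive = fit@Ga, residual = fit@Gabar,
              total = fit@Ga + fit@Gabar)
  zero <- diag(G) <= 0
  if (any(zero))
    stopf("faGBLUP_pred_error",
          "correlation undefined: zero %s variance in experiment(s) %s",
          component, paste(fit@experiments[zero], collapse = ", "))
  stats::cov2cor(G)
}

#' Agglomerative clustering of environments
#'
#' Hierarchical agglomerative clustering of environments on the
#' dissimilarity d = 1 - correlation, average linkage by default.
#'
#' @param corr p x p genetic correlation matrix (dimnames label the
#'   environments).
#' @param nClusters number of clusters to cut at (default 2); alternatively
#'   give \code{height}.
#' @param height dissimilarity cut height (overrides \code{nClusters}).
#' @param linkage \code{"average"}, \code{"complete"} or \code{"single"}.
#' @return list with \code{labels} (named character: experiment ->
#'   \code{"C<k>"}), \code{tree} (an \code{hclust} object) and
#'   \code{heights}.
#' @export
clusterEnvironments <- function(corr, nClusters = 2, height = NULL,
                                linkage = c("average", "complete",
                                            "single")) {
  linkage <- match.arg(linkage)
  p <- nrow(corr)
  if (is.null(height) && nClusters > p)
    stopf("faGBLUP_cluster_error",
          "nClusters = %d exceeds the number of environments p = %d",
          nClusters, p)
  d <- stats::as.dist(1 - corr)
  tree <- stats::hclust(d, method = linkage)
  cut <- if (!is.null(height)) stats::cutree(tree, h = height)
         else stats::cutree(tree, k = nClusters)
  labels <- stats::setNames(paste0("C", cut), names(cut))
  list(labels = labels, tree = tree, heights = tree$height)
}

#' Average pairwise prediction error variance
#'
#' The mean, over unordered line pairs (i, i'), of
#' \eqn{PEV_{ii} + PEV_{i'i'} - 2 PEV_{ii'}} -- the variance of pairwise
#' BLUP differences that enters the generalized heritability for
#' unbalanced data.
#'
#' @param pev symmetric PEV matrix over lines (from
#'   \code{\link{pevBlock}}).
#' @return scalar APPEV.
#' @export
appev <- function(pev) {
  pev <- as.matrix(pev)
  if (nrow(pev) != ncol(pev))
    stopf("faGBLUP_pred_error", "PEV block must be square")
  m <- nrow(pev)
  if (m < 2) stopf("faGBLUP_pred_error", "APPEV needs at least two lines")
  s <- sum(diag(pev))
  tot <- sum(pev)
  2 * (m * s - tot) / (m * (m - 1))
}

#' Broad-sense generalized heritability
#'
#' \eqn{H_j = 1 - APPEV_{GV,j} / (2(\sigma^2_{a,j} + \sigma^2_{\bar a,j}))}.
#' Values outside [0, 1] are reported raw with a warning (the clipped
#' value is attached as attribute \code{"clipped"}).
#'
#' @param appevGV average pairwise prediction error variance of GVs.
#' @param sigma2a,sigma2abar additive and residual genetic variances.
#' @return scalar H.
#' @export
heritabilityBroad <- function(appevGV, sigma2a, sigma2abar) {
  total <- sigma2a + sigma2abar
  if (total <= 0)
    stopf("faGBLUP_pred_error", "zero total genetic variance")
  H <- 1 - appevGV / (2 * total)
  if (H < 0 || H > 1) {
    warning(sprintf("broad-sense heritability %.4f outside [0, 1]", H))
    attr(H, "clipped") <- min(max(H, 0), 1)
  }
  H
}

#' Narrow-sense generalized heritability
#'
#' \eqn{h^2_j = 1 - APPEV_{GEBV,j} / (2\sigma^2_{a,j})}.
#'
#' @param appevGEBV average pairwise prediction error variance of GEBVs.
#' @param sigma2a additive genetic variance.
#' @return scalar h2 (raw; clipped value attached as attribute when
#'   outside [0, 1]).
#' @export
heritabilityNarrow <- function(appevGEBV, sigma2a) {
  if (sigma2a <= 0)
    stopf("faGBLUP_pred_error", "zero additive genetic variance")
  h2 <- 1 - appevGEBV / (2 * sigma2a)
  if (h2 < 0 || h2 > 1) {
    warning(sprintf("narrow-sense heritability %.4f outside [0, 1]", h2))
    attr(h2, "clipped") <- min(max(h2, 0), 1)
  }
  h2
}

#' Cluster-level genetic variances
#'
#' For each environment cluster, estimates the additive and residual
#' genetic variances as the average of the pairwise covariance estimates
#' between the member experiments (strictly off-diagonal by default; set
#' \code{includeDiagonal = TRUE} to average the full sub-block). A
#' singleton cluster falls back to that experiment's variance with a
#' warning.
#'
#' @param fit a \linkS4class{FittedFAModel}.
#' @param clusters named character vector mapping experiment to cluster
#'   label; an \code{"overall"} row over all experiments is always added.
#' @param includeDiagonal average diagonal variances as well (default
#'   FALSE).
#' @return data.frame with columns \code{cluster}, \code{n_experiments},
#'   \code{sigma2_a}, \code{sigma2_abar}.
#' @export
clusterVariances <- function(fit, clusters, includeDiagonal = FALSE) {
  exps <- fit@experiments
  clusters <- clusters[exps]
  avgCov <- function(G, member) {
    B <- G[member, member, drop = FALSE]
    if (length(member) == 1) {
      warning("singleton cluster: using the experiment's own variance")
      return(B[1, 1])
    }
    if (includeDiagonal) mean(B)
    else mean(B[row(B) != col(B)])
  }
  groups <- c(split(exps, clusters), list(overall = exps))
  out <- data.frame(cluster = names(groups),
                    n_experiments = lengths(groups),
                    sigma2_a = NA_real_, sigma2_abar = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(groups)) {
    out$sigma2_a[i] <- avgCov(fit@Ga, groups[[i]])
    out$sigma2_abar[i] <- avgCov(fit@Gabar, groups[[i]])
  }
  rownames(out) <- NULL
  out
}

#' Proportion of genetic variance that is additive
#'
#' @param sigma2a,sigma2abar nonnegative additive and residual genetic
#'   variances (vectorized).
#' @return \eqn{\sigma^2_a / (\sigma^2_a + \sigma^2_{\bar a})}.
#' @examples
#' proportionAdditive(0.00824, 0.01537)  # 0.3490 as in a two-component split
#' @export
proportionAdditive <- function(sigma2a, sigma2abar) {
  total <- sigma2a + sigma2abar
  if (any(total <= 0))
    stopf("faGBLUP_pred_error", "zero total genetic variance")
  sigma2a / total
}

#' Heritability table per experiment, cluster and overall
#'
#' Assembles the per-experiment genetic variances, APPEVs, broad- and
#' narrow-sense generalized heritabilities, and the corresponding
#' cluster-level and overall rows (cluster variances from average pairwise
#' covariances; cluster APPEV from the PEV of the cluster-mean BLUPs).
#'
#' @param fit a \linkS4class{FittedFAModel} (fitted with
#'   \code{computePEV = TRUE}).
#' @param clusters named character vector experiment -> cluster label;
#'   \code{NULL} puts all experiments in one cluster.
#' @return data.frame with one row per experiment, per cluster and an
#'   overall row: \code{unit}, \code{level}, \code{sigma2_a},
#'   \code{sigma2_abar}, \code{prop_additive}, \code{appev_gv},
#'   \code{appev_gebv}, \code{H}, \code{h2}.
#' @export
heritabilityTable <- function(fit, clusters = NULL) {
  exps <- fit@experiments
  if (is.null(clusters))
    clusters <- stats::setNames(rep("all", length(exps)), exps)
  ## nonpositive (cluster-averaged) variances make the corresponding
  ## heritability undefined: reported as NA with a warning, not an error.
  safeH <- function(agv, s2a, s2b) {
    if (!is.finite(s2a + s2b) || s2a + s2b <= 0) {
      warning("nonpositive total genetic variance; H undefined")
      return(NA_real_)
    }
    as.numeric(suppressWarnings(heritabilityBroad(agv, s2a, s2b)))
  }
  safeh2 <- function(ageb, s2a) {
    if (!is.finite(s2a) || s2a <= 0) {
      warning("nonpositive additive genetic variance; h2 undefined")
      return(NA_real_)
    }
    as.numeric(suppressWarnings(heritabilityNarrow(ageb, s2a)))
  }
  safeProp <- function(s2a, s2b)
    if (is.finite(s2a + s2b) && s2a + s2b > 0) s2a / (s2a + s2b)
    else NA_real_
  mkRow <- function(unit, level, member, s2a, s2b) {
    agv <- appev(pevBlock(fit, member, "gv"))
    ageb <- appev(pevBlock(fit, member, "gebv"))
    data.frame(unit = unit, level = level, sigma2_a = s2a,
               sigma2_abar = s2b,
               prop_additive = safeProp(s2a, s2b),
               appev_gv = agv, appev_gebv = ageb,
               H = safeH(agv, s2a, s2b), h2 = safeh2(ageb, s2a),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (j in exps)
    rows[[j]] <- mkRow(j, "experiment", j, fit@Ga[j, j], fit@Gabar[j, j])
  cv <- suppressWarnings(clusterVariances(fit, clusters))
  groups <- c(split(exps, clusters[exps]), list(overall = exps))
  for (i in seq_len(nrow(cv)))
    rows[[paste0("cl_", cv$cluster[i])]] <- mkRow(
      cv$cluster[i],
      if (cv$cluster[i] == "overall") "overall" else "cluster",
      groups[[cv$cluster[i]]], cv$sigma2_a[i], cv$sigma2_abar[i])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
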