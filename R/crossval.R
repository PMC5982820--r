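## Replicated fivefold cross-validation of GEBVs against full-data GVs,
## predictive-ability matrices and relative-accuracy statistics.

#' Build replicated cross-validation fold plans
#'
#' Randomly partitions the lines into \code{nFolds} subsets per replicate
#' (fold sizes differing by at most one; every line validated exactly once
#' per replicate). Each replicate derives its own substream from
#' \code{seed}, so plans are reproducible replicate by replicate.
#'
#' @param lineIds character vector of line ids.
#' @param nFolds folds per replicate (default 5).
#' @param nReplicates replicates (default 10).
#' @param seed master seed.
#' @return data.frame with columns \code{replicate}, \code{fold},
#'   \code{line}.
#' @examples
#' plan <- makeFolds(sprintf("L%03d", 1:358), seed = 1)
#' table(table(plan$fold[plan$replicate == 1]))  # fold sizes 71/72
#' @export
makeFolds <- function(lineIds, nFolds = 5, nReplicates = 10, seed = 1) {
  m <- length(lineIds)
  if (nFolds > m)
    stopf("faGBLUP_cv_error", "nFolds = %d exceeds the %d lines", nFolds, m)
  plans <- vector("list", nReplicates)
  sizes <- rep(m %/% nFolds, nFolds)
  extra <- m %% nFolds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  for (r in seq_len(nReplicates)) {
    ord <- withSeed(subSeed(seed, 100 + r), sample(lineIds))
    plans[[r]] <- data.frame(
      replicate = r,
      fold = rep(seq_len(nFolds), times = sizes),
      line = ord, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, plans)
  rownames(out) <- NULL
  out
}

# GEBV/GV matrices (lines x labels) extended with cluster-mean and overall
# columns.
extendWithClusters <- function(mat, exps, clusters) {
  full <- matrix(NA_real_, nrow(mat), length(exps),
                 dimnames = list(rownames(mat), exps))
  have <- intersect(colnames(mat), exps)
  full[, have] <- mat[, have]
  out <- full
  for (cl in unique(clusters)) {
    member <- exps[clusters == cl]
    out <- cbind(out, rowMeans(full[, member, drop = FALSE],
                               na.rm = TRUE))
    colnames(out)[ncol(out)] <- cl
  }
  cbind(out, overall = rowMeans(full, na.rm = TRUE))
}

#' Replicated cross-validation of genomic predictions
#'
#' For each fold of each replicate, all phenotype records of the
#' validation lines are removed (the lines stay in K, so their GEBVs are
#' predicted purely through genomic relationships), the model is refitted
#' (variance parameters re-estimated), and the validation lines' GEBVs per
#' training environment are correlated with the full-data GVs per
#' validation environment. Per-replicate values are fold averages;
#' reported means and sds are over replicates. Non-converged folds are
#' dropped with a log entry; more than 20% dropped folds fails the run.
#'
#' @param data,K,spec as in \code{\link{remlFit}}; \code{spec} should be
#'   the selected final model.
#' @param plan fold plan from \code{\link{makeFolds}} (default: fivefold,
#'   ten replicates from \code{seed}).
#' @param fullFit optional pre-computed full-data fit (with PEV) used for
#'   the reference GVs and the heritability denominators.
#' @param clusters optional named character vector experiment -> cluster
#'   (default: from clustering the full fit's total genetic correlations
#'   into two groups).
#' @param nFolds,nReplicates,seed used when \code{plan} is NULL.
#' @param holdoutEnvironment optional experiment label whose phenotype
#'   records are removed from every training fit (a crude
#'   untested-environment scenario; predictions for it then rely solely
#'   on its genetic correlations with the remaining environments).
#' @param maxit iteration cap per fold fit.
#' @return a \linkS4class{CVResult}.
#' @export
runCV <- function(data, K, spec, plan = NULL, fullFit = NULL,
                  clusters = NULL, nFolds = 5, nReplicates = 10,
                  seed = 1, holdoutEnvironment = NULL, maxit = 500) {
  if (is.null(fullFit))
    fullFit <- remlFit(data, K, spec, computePEV = TRUE, maxit = maxit)
  exps <- fullFit@experiments
  if (is.null(clusters)) {
    corr <- envCorrelation(fullFit, "total")
    clusters <- clusterEnvironments(corr, nClusters = 2)$labels
  }
  clusters <- clusters[exps]
  lines <- intersect(lineIds(K), unique(as.character(data$line)))
  if (is.null(plan))
    plan <- makeFolds(lines, nFolds = nFolds, nReplicates = nReplicates,
                      seed = seed)
  gvFull <- fullFit@solutions$ua + fullFit@solutions$uabar
  gvExt <- extendWithClusters(gvFull, exps, clusters)
  labels <- colnames(gvExt)
  nlab <- length(labels)

  reps <- sort(unique(plan$replicate))
  perRepCorr <- array(NA_real_, c(nlab, nlab, length(reps)),
                      dimnames = list(labels, labels, NULL))
  dropped <- 0L
  totalFolds <- 0L
  log <- character(0)
  for (ri in seq_along(reps)) {
    r <- reps[ri]
    folds <- sort(unique(plan$fold[plan$replicate == r]))
    foldCorrs <- array(NA_real_, c(nlab, nlab, length(folds)))
    for (fi in seq_along(folds)) {
      totalFolds <- totalFolds + 1L
      valLines <- plan$line[plan$replicate == r & plan$fold == folds[fi]]
      train <- data[!(as.character(data$line) %in% valLines), , drop = FALSE]
      if (!is.null(holdoutEnvironment))
        train <- train[as.character(train$experiment) !=
                         holdoutEnvironment, , drop = FALSE]
      fit <- tryCatch(remlFit(train, K, spec, computePEV = FALSE,
                              maxit = maxit),
                      error = function(e) e)
      if (inherits(fit, "error") || !fit@converged) {
        dropped <- dropped + 1L
        log <- c(log, sprintf("replicate %d fold %d dropped (%s)", r,
                              folds[fi],
                              if (inherits(fit, "error"))
                                conditionMessage(fit) else "no convergence"))
        next
      }
      gebvExt <- extendWithClusters(fit@solutions$ua, exps, clusters)
      for (a in seq_len(nlab)) for (b in seq_len(nlab))
        foldCorrs[a, b, fi] <- suppressWarnings(
          stats::cor(gebvExt[valLines, a], gvExt[valLines, b]))
    }
    perRepCorr[, , ri] <- apply(foldCorrs, c(1, 2), mean, na.rm = TRUE)
  }
  if (dropped > 0.2 * totalFolds)
    stopf("faGBLUP_cv_error",
          "%d of %d folds failed to converge (> 20%%)", dropped, totalFolds)

  abilityMatrix <- apply(perRepCorr, c(1, 2), mean, na.rm = TRUE)
  abilitySD <- apply(perRepCorr, c(1, 2), stats::sd, na.rm = TRUE)

  perReplicate <- do.call(rbind, lapply(seq_along(reps), function(ri) {
    g <- expand.grid(gebv_env = labels, gv_env = labels,
                     stringsAsFactors = FALSE)
    g$replicate <- reps[ri]
    g$correlation <- as.vector(perRepCorr[, , ri])
    g[, c("replicate", "gebv_env", "gv_env", "correlation")]
  }))

  ## Summary rows: within-unit predictive ability + relative accuracies.
  ht <- heritabilityTable(fullFit, clusters)
  units <- c(exps, unique(clusters), "overall")
  sm <- lapply(units, function(u) {
    pa <- abilityMatrix[u, u]
    sdpa <- abilitySD[u, u]
    hrow <- ht[ht$unit == u, , drop = FALSE]
    H <- hrow$H[1]; h2 <- hrow$h2[1]
    safeRel <- function(x, h) if (is.finite(h) && h > 0) x / sqrt(h)
                              else NA_real_
    data.frame(unit = u,
               level = hrow$level[1],
               predictive_ability = pa, sd = sdpa,
               H = H, h2 = h2,
               rapv = safeRel(pa, H), rapv_sd = safeRel(sdpa, H),
               rabv = safeRel(pa, h2), rabv_sd = safeRel(sdpa, h2),
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, sm)
  rownames(summary) <- NULL

  res <- new("CVResult", perReplicate = perReplicate,
             abilityMatrix = abilityMatrix, abilitySD = abilitySD,
             summary = summary, plan = plan, droppedFolds = dropped)
  attr(res, "log") <- log
  res
}

#' Relative accuracy against phenotypic value prediction
#'
#' \eqn{RAPV = corr(GEBV, GV) / \sqrt{H}}: the accuracy of untested-line
#' GEBVs relative to total genotypic value estimation with complete
#' phenotypic data.
#'
#' @param predictiveAbility correlation between validation GEBVs and
#'   full-data GVs.
#' @param H broad-sense generalized heritability in (0, 1].
#' @return RAPV value.
#' @examples
#' rapv(0.480, 0.778)  # 0.544
#' @export
rapv <- function(predictiveAbility, H) {
  if (any(H <= 0))
    stopf("faGBLUP_cv_error", "H must be positive")
  predictiveAbility / sqrt(H)
}

#' Relative accuracy against breeding value prediction
#'
#' \eqn{RABV = corr(GEBV, GV) / \sqrt{h^2}}: accuracy of untested-line
#' GEBVs relative to GEBVs based on complete data. Values above 1 are
#' permitted (analogous to relative efficiency of indirect selection).
#'
#' @param predictiveAbility correlation between validation GEBVs and
#'   full-data GVs.
#' @param h2 narrow-sense generalized heritability in (0, 1].
#' @return RABV value.
#' @examples
#' rabv(0.455, 0.181)  # 1.070
#' @export
rabv <- function(predictiveAbility, h2) {
  if (any(h2 <= 0))
    stopf("faGBLUP_cv_error", "h2 must be positive")
  predictiveAbility / sqrt(h2)
}

#' Predicted genetic gain per unit time relative to phenotypic selection
#'
#' Multiplies the relative accuracy of breeding value prediction by the
#' breeding-cycle time ratio (default 2: genomic selection halving the
#' cycle length), giving the predicted gain per unit of time relative to
#' selection on complete-data breeding values.
#'
#' @param rabv relative accuracy of breeding value prediction (>= 0).
#' @param cycleTimeRatio ratio of conventional to genomic cycle time
#'   (default 2).
#' @return relative gain (1 = parity with phenotypic selection).
#' @examples
#' gainPerTime(1.07)  # 2.14
#' @export
gainPerTime <- function(rabv, cycleTimeRatio = 2) {
  if (any(rabv < 0) || cycleTimeRatio <= 0)
    stopf("faGBLUP_cv_error",
          "rabv must be >= 0 and cycleTimeRatio positive")
  cycleTimeRatio * rabv
}
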