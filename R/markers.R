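## Marker quality control, imputation, genomic relationship matrix and PCA.

#' Marker quality control
#'
#' Removes, in order: monomorphic markers (all non-missing calls
#' identical), markers with minor allele frequency strictly below
#' \code{mafMin} (computed on non-missing calls; a marker at exactly
#' \code{mafMin} is retained), and, optionally, duplicated markers (columns
#' whose full dosage vectors, including the missing pattern, are identical
#' to an earlier column; the first occurrence is kept).
#'
#' @param markers a \linkS4class{MarkerMatrix}.
#' @param mafMin minimum minor allele frequency (default 0.05).
#' @param dropDuplicates remove duplicated marker columns (default TRUE).
#' @return list with elements \code{markers} (the filtered
#'   \linkS4class{MarkerMatrix}) and \code{report} (counts of markers
#'   removed per class and retained).
#' @examples
#' d <- matrix(c(0, 0, 0, 0, 1, 2), 3, 2,
#'   dimnames = list(paste0("L", 1:3), c("mono", "ok")))
#' filterMarkers(markerMatrix(d))$report
#' @export
filterMarkers <- function(markers, mafMin = 0.05, dropDuplicates = TRUE) {
  stopifnot(is(markers, "MarkerMatrix"))
  d <- markers@dosages
  nStart <- ncol(d)

  nNonMissing <- colSums(!is.na(d))
  if (any(nNonMissing == 0))
    stopf("faGBLUP_qc_error",
          "%d marker(s) have no non-missing calls", sum(nNonMissing == 0))

  mono <- apply(d, 2, function(x) {
    x <- x[!is.na(x)]
    length(unique(x)) <= 1
  })
  d <- d[, !mono, drop = FALSE]

  q <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(q, 1 - q)
  lowMaf <- maf < mafMin
  d <- d[, !lowMaf, drop = FALSE]

  nDup <- 0L
  if (dropDuplicates && ncol(d) > 0) {
    key <- apply(d, 2, function(x) paste(ifelse(is.na(x), "NA", x),
                                         collapse = ","))
    dup <- duplicated(key)
    nDup <- sum(dup)
    d <- d[, !dup, drop = FALSE]
  }

  if (ncol(d) == 0)
    stopf("faGBLUP_qc_error", "all %d markers were removed by QC", nStart)

  report <- list(input = nStart, monomorphic = sum(mono),
                 low_maf = sum(lowMaf), duplicated = nDup,
                 retained = ncol(d), maf_min = mafMin)
  list(markers = markerMatrix(d, imputed = markers@imputed), report = report)
}

#' Mean-dosage imputation of missing marker calls
#'
#' Replaces each missing dosage by the marker's mean dosage among
#' non-missing calls (fractional values permitted afterwards); non-missing
#' values are unchanged. This is a deliberately simple imputer: the
#' downstream model consumes markers only through the relationship matrix,
#' for which mean imputation is the standard centering-consistent choice.
#'
#' @param markers a \linkS4class{MarkerMatrix}.
#' @return an imputed \linkS4class{MarkerMatrix} with no missing values.
#' @export
imputeMissing <- function(markers) {
  stopifnot(is(markers, "MarkerMatrix"))
  d <- markers@dosages
  nNonMissing <- colSums(!is.na(d))
  if (any(nNonMissing == 0))
    stopf("faGBLUP_impute_error",
          "%d marker(s) are fully missing; run filterMarkers first",
          sum(nNonMissing == 0))
  if (!anyNA(d)) return(markerMatrix(d, imputed = TRUE))
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  markerMatrix(d, imputed = TRUE)
}

#' Genomic relationship matrix
#'
#' Computes the scaled genomic relationship matrix K from (imputed) marker
#' dosages: with W the column-centered dosage matrix and
#' \eqn{c = \sum_j 2 q_j (1 - q_j)} (allele frequencies \eqn{q_j} from the
#' observed dosage means), the raw matrix is \eqn{G_0 = W W' / c}; it is
#' then rescaled so the mean diagonal equals 1, and a small ridge
#' (\code{ridge} times the mean diagonal) is added to the diagonal to
#' guarantee invertibility inside REML.
#'
#' @param markers an imputed \linkS4class{MarkerMatrix} (no missing values).
#' @param ridge ridge fraction added to the diagonal (default 1e-6).
#' @return a \linkS4class{RelationshipMatrix}.
#' @export
computeGRM <- function(markers, ridge = 1e-6) {
  stopifnot(is(markers, "MarkerMatrix"))
  d <- markers@dosages
  if (anyNA(d))
    stopf("faGBLUP_grm_error", "markers contain missing values; impute first")
  if (nrow(d) < 2)
    stopf("faGBLUP_grm_error", "at least two lines are required")
  q <- colMeans(d) / 2
  cdenom <- sum(2 * q * (1 - q))
  if (cdenom <= 0)
    stopf("faGBLUP_grm_error",
          "zero denominator: all markers are monomorphic")
  W <- sweep(d, 2, 2 * q)
  G0 <- tcrossprod(W) / cdenom
  if (!is.finite(mean(diag(G0))) || mean(diag(G0)) <= 0)
    stopf("faGBLUP_grm_error",
          "markers carry no variance (all monomorphic)")
  G0 <- G0 / mean(diag(G0))
  ridgeValue <- ridge * mean(diag(G0))
  diag(G0) <- diag(G0) + ridgeValue
  relationshipMatrix(G0, ridge = ridgeValue)
}

#' Principal component analysis of a relationship matrix
#'
#' Eigendecomposition of K: returns the leading eigenvalues, eigenvectors,
#' PC scores (eigenvectors scaled by the square root of their eigenvalues)
#' and the proportion of the total eigenvalue sum captured, ordered by
#' decreasing eigenvalue.
#'
#' @param K a \linkS4class{RelationshipMatrix}.
#' @param nComponents number of leading components to return.
#' @return list with \code{values} (all eigenvalues), \code{vectors},
#'   \code{scores} (m x nComponents), \code{proportion} (per returned
#'   component) and \code{cumulativeProportion}.
#' @export
pcaGRM <- function(K, nComponents = 2) {
  stopifnot(is(K, "RelationshipMatrix"))
  m <- nrow(K@values)
  if (nComponents > m)
    stopf("faGBLUP_pca_error",
          "nComponents = %d exceeds the number of lines m = %d",
          nComponents, m)
  e <- eigen(K@values, symmetric = TRUE)
  total <- sum(e$values)
  sel <- seq_len(nComponents)
  scores <- e$vectors[, sel, drop = FALSE] %*%
    diag(sqrt(pmax(e$values[sel], 0)), nrow = nComponents)
  rownames(scores) <- rownames(K@values)
  colnames(scores) <- paste0("PC", sel)
  list(values = e$values,
       vectors = e$vectors[, sel, drop = FALSE],
       scores = scores,
       proportion = e$values[sel] / total,
       cumulativeProportion = cumsum(e$values[sel]) / total)
}
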