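#' @import methods
NULL

#' Line identifiers
#'
#' Accessor for the ordered line (genotype) identifiers of an object.
#'
#' @param x an object with lines (a \linkS4class{MarkerMatrix},
#'   \linkS4class{RelationshipMatrix} or \linkS4class{FittedFAModel}).
#' @return character vector of line ids.
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))

#' Marker identifiers
#'
#' @param x a \linkS4class{MarkerMatrix}.
#' @return character vector of marker ids.
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' Dosage matrix
#'
#' Accessor for the line-by-marker allele dosage matrix (0/1/2, possibly
#' fractional after imputation, \code{NA} where missing).
#'
#' @param x a \linkS4class{MarkerMatrix}.
#' @return numeric matrix, lines in rows.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' Relationship matrix values
#'
#' @param x a \linkS4class{RelationshipMatrix} or \linkS4class{FittedFAModel}.
#' @return symmetric numeric matrix with line ids as dimnames.
#' @export
setGeneric("kinship", function(x) standardGeneric("kinship"))

#' Factor loadings
#'
#' @param x a \linkS4class{FAStructure}.
#' @return the p x k loading matrix.
#' @export
setGeneric("loadings", function(x) standardGeneric("loadings"))

#' Environment-specific variances
#'
#' @param x a \linkS4class{FAStructure}.
#' @return length-p numeric vector of specific variances.
#' @export
setGeneric("specificVariances", function(x) standardGeneric("specificVariances"))

#' Random-effect solutions of a fitted model
#'
#' Returns the BLUPs of the additive (\code{ua}) and residual genetic
#' (\code{uabar}) line-within-environment effects as m x p matrices.
#'
#' @param x a \linkS4class{FittedFAModel}.
#' @return list with matrices \code{ua} and \code{uabar} (lines x experiments).
#' @export
setGeneric("geneticSolutions", function(x) standardGeneric("geneticSolutions"))

#' Estimated variance components
#'
#' @param x a \linkS4class{FittedFAModel}.
#' @return list with elements \code{Ga}, \code{Gabar} (p x p genetic
#'   covariance matrices), \code{design} and \code{residual} (named numeric).
#' @export
setGeneric("varianceComponents", function(x) standardGeneric("varianceComponents"))
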