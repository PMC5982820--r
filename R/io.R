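## Readers and writers for the package's external text formats. All
## formats are tab-delimited text or structured text (YAML/JSON), so
## fixtures and reports remain diffable and portable.

#' Write / read a marker matrix
#'
#' Tab-delimited text: first column \code{line}, remaining columns one per
#' marker with integer (or imputed fractional) dosages; missing calls are
#' \code{NA}.
#'
#' @param markers a \linkS4class{MarkerMatrix}.
#' @param path file path.
#' @return \code{writeMarkers}: the path, invisibly; \code{readMarkers}:
#'   a \linkS4class{MarkerMatrix}.
#' @export
writeMarkers <- function(markers, path) {
  d <- dosages(markers)
  df <- data.frame(line = rownames(d), d, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMarkers
#' @export
readMarkers <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  d <- as.matrix(df[, -1, drop = FALSE])
  rownames(d) <- df$line
  imputed <- any(!is.na(d) & d != round(d))
  markerMatrix(d, imputed = imputed)
}

#' Write / read a phenotype table
#'
#' Tab-delimited plot-level records with the two-phase design columns
#' (\code{experiment}, \code{year}, \code{site}, \code{irrigation},
#' \code{line}, \code{replicate}, \code{bay}, \code{row}, \code{range},
#' \code{lab_day}, \code{carousel}, \code{well}, \code{value}); only
#' \code{experiment}, \code{line} and \code{value} are mandatory.
#'
#' @param phenotypes data.frame of plot records.
#' @param path file path.
#' @return \code{writePhenotypes}: the path, invisibly;
#'   \code{readPhenotypes}: the data.frame.
#' @export
writePhenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writePhenotypes
#' @export
readPhenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = NA)
  miss <- setdiff(requiredPhenotypeColumns, names(df))
  if (length(miss))
    stopf("faGBLUP_io_error", "phenotype file lacks column(s): %s",
          paste(miss, collapse = ", "))
  for (cl in setdiff(names(df), "value")) df[[cl]] <- as.character(df[[cl]])
  df
}

#' Write / read a relationship matrix
#'
#' Square tab-delimited matrix: header row of line ids, first column
#' \code{line} repeating them.
#'
#' @param K a \linkS4class{RelationshipMatrix}.
#' @param path file path.
#' @param ridge ridge bookkeeping value restored on read (default 0).
#' @return \code{writeRelationshipMatrix}: the path, invisibly;
#'   \code{readRelationshipMatrix}: a \linkS4class{RelationshipMatrix}.
#' @export
writeRelationshipMatrix <- function(K, path) {
  v <- kinship(K)
  df <- data.frame(line = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRelationshipMatrix
#' @export
readRelationshipMatrix <- function(path, ridge = 0) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$line
  relationshipMatrix(v, ridge = ridge)
}

#' Write / read generating parameters
#'
#' YAML serialization of a \linkS4class{TrueParameters} object (loadings
#' as row lists, specific variances, design variances, per-year residual
#' variances and experiment means).
#'
#' @param truth a \linkS4class{TrueParameters}.
#' @param path file path.
#' @return \code{writeTruth}: the path, invisibly; \code{readTruth}: a
#'   \linkS4class{TrueParameters}.
#' @export
writeTruth <- function(truth, path) {
  ser <- function(fa) list(
    loadings = apply(loadings(fa), 1, as.numeric, simplify = FALSE),
    specific_variances = as.numeric(specificVariances(fa)))
  obj <- list(
    additive = ser(truth@additive),
    residual_genetic = ser(truth@residualGenetic),
    design_variances = as.list(truth@designVariances),
    residual_variance_by_year = as.list(truth@residualVarianceByYear),
    experiment_means = as.numeric(truth@experimentMeans))
  yaml::write_yaml(obj, path, precision = 12)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  obj <- yaml::read_yaml(path)
  des <- function(x) faStructure(
    do.call(rbind, lapply(x$loadings, as.numeric)),
    as.numeric(x$specific_variances))
  trueParameters(
    additive = des(obj$additive),
    residualGenetic = des(obj$residual_genetic),
    designVariances = unlist(obj$design_variances),
    residualVarianceByYear = unlist(obj$residual_variance_by_year),
    experimentMeans = as.numeric(obj$experiment_means))
}

# Square labelled matrix (correlations, ability matrices) as TSV.
writeSquareMatrix <- function(M, path) {
  df <- data.frame(id = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readSquareMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df$id
  M
}

#' Export an environment cluster tree as newick
#'
#' Converts the agglomerative merge tree from
#' \code{\link{clusterEnvironments}} to newick text (branch lengths are
#' the merge dissimilarities).
#'
#' @param tree an \code{hclust} object.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeClusterTree <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
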