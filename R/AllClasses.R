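#' MarkerMatrix: line-by-marker dosage matrix
#'
#' Holds biallelic SNP dosages (0, 1, 2 copies of the counted allele) for a
#' set of lines, with \code{NA} marking missing calls. After mean-dosage
#' imputation the entries may be fractional (flagged by \code{imputed}).
#'
#' @slot dosages numeric matrix, lines in rows, markers in columns; dimnames
#'   carry the line and marker ids.
#' @slot imputed logical; \code{TRUE} once fractional imputed dosages are
#'   permitted.
#' @export
setClass("MarkerMatrix",
  representation(dosages = "matrix", imputed = "logical"),
  prototype(imputed = FALSE))

setValidity("MarkerMatrix", function(object) {
  d <- object@dosages
  if (is.null(rownames(d)) || is.null(colnames(d)))
    return("dosages must have line ids as rownames and marker ids as colnames")
  if (anyDuplicated(rownames(d))) return("line ids must be unique")
  if (anyDuplicated(colnames(d))) return("marker ids must be unique")
  v <- d[!is.na(d)]
  if (length(v) && (min(v) < 0 || max(v) > 2))
    return("dosages must lie in [0, 2]")
  if (!object@imputed && length(v) && any(v != round(v)))
    return("non-imputed dosages must be integers 0/1/2")
  TRUE
})

#' Construct a MarkerMatrix
#'
#' @param dosages numeric matrix of dosages with line rownames and marker
#'   colnames (0/1/2 or \code{NA}).
#' @param imputed logical, allow fractional (imputed) dosages.
#' @return a \linkS4class{MarkerMatrix}.
#' @examples
#' m <- markerMatrix(matrix(c(0, 1, 2, NA), 2, 2,
#'   dimnames = list(c("L1", "L2"), c("M1", "M2"))))
#' nLines(m)
#' @export
markerMatrix <- function(dosages, imputed = FALSE) {
  storage.mode(dosages) <- "double"
  new("MarkerMatrix", dosages = dosages, imputed = imputed)
}

#' @describeIn markerMatrix number of lines
#' @param x a MarkerMatrix.
#' @export
nLines <- function(x) nrow(x@dosages)

#' @describeIn markerMatrix number of markers
#' @export
nMarkers <- function(x) ncol(x@dosages)

#' @rdname lineIds
#' @export
setMethod("lineIds", "MarkerMatrix", function(x) rownames(x@dosages))

#' @rdname markerIds
#' @export
setMethod("markerIds", "MarkerMatrix", function(x) colnames(x@dosages))

#' @rdname dosages
#' @export
setMethod("dosages", "MarkerMatrix", function(x) x@dosages)

setMethod("show", "MarkerMatrix", function(object) {
  d <- object@dosages
  cat("MarkerMatrix:", nrow(d), "lines x", ncol(d), "markers\n")
  cat("  missing calls:", sum(is.na(d)),
      sprintf("(%.2f%%)", 100 * mean(is.na(d))), "\n")
  cat("  imputed:", object@imputed, "\n")
})

#' RelationshipMatrix: genomic relationship matrix among lines
#'
#' A symmetric, positive semidefinite relationship matrix K scaled so the
#' mean diagonal is 1, with a small documented ridge added to the diagonal
#' to guarantee invertibility inside REML.
#'
#' @slot values symmetric numeric matrix with line ids as dimnames.
#' @slot ridge the ridge constant that was added to the diagonal.
#' @export
setClass("RelationshipMatrix",
  representation(values = "matrix", ridge = "numeric"),
  prototype(ridge = 0))

setValidity("RelationshipMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("K must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    return("K must carry identical line ids as row and column names")
  if (anyDuplicated(rownames(v))) return("line ids must be unique")
  if (max(abs(v - t(v))) > 1e-8 * max(1, max(abs(v))))
    return("K must be symmetric")
  if (any(diag(v) <= 0)) return("diagonal entries of K must be positive")
  TRUE
})

#' Construct a RelationshipMatrix
#'
#' @param values symmetric numeric matrix with line ids as dimnames.
#' @param ridge ridge already included on the diagonal (bookkeeping only).
#' @return a \linkS4class{RelationshipMatrix}.
#' @export
relationshipMatrix <- function(values, ridge = 0) {
  values <- (values + t(values)) / 2
  new("RelationshipMatrix", values = values, ridge = ridge)
}

#' @rdname lineIds
#' @export
setMethod("lineIds", "RelationshipMatrix", function(x) rownames(x@values))

#' @rdname kinship
#' @export
setMethod("kinship", "RelationshipMatrix", function(x) x@values)

setMethod("show", "RelationshipMatrix", function(object) {
  cat("RelationshipMatrix:", nrow(object@values), "lines\n")
  cat("  mean diagonal:", format(mean(diag(object@values)), digits = 6),
      " ridge:", format(object@ridge, digits = 3), "\n")
})

#' FAStructure: factor-analytic covariance structure
#'
#' Parameterizes a p x p covariance matrix among environments as
#' \eqn{\Lambda \Lambda' + \mathrm{diag}(\psi)} with a p x k loading matrix
#' \eqn{\Lambda} and environment-specific variances \eqn{\psi \ge 0}. For
#' identifiability the upper triangle of \eqn{\Lambda} is constrained to
#' zero (\eqn{\Lambda_{ij} = 0} for \eqn{j > i}).
#'
#' @slot loadings p x k numeric matrix.
#' @slot specificVariances length-p nonnegative numeric vector.
#' @export
setClass("FAStructure",
  representation(loadings = "matrix", specificVariances = "numeric"))

setValidity("FAStructure", function(object) {
  L <- object@loadings
  psi <- object@specificVariances
  if (nrow(L) != length(psi))
    return("loadings rows and specificVariances length must agree")
  if (any(psi < 0)) return("specific variances must be nonnegative")
  k <- ncol(L)
  if (k >= 2) {
    for (j in 2:k) {
      up <- seq_len(j - 1)
      if (any(abs(L[up, j]) > 1e-12))
        return("identifiability: loadings[i, j] must be 0 for j > i")
    }
  }
  TRUE
})

#' Construct an FAStructure
#'
#' @param loadings p x k loading matrix (upper triangle zero).
#' @param specificVariances length-p nonnegative vector.
#' @return an \linkS4class{FAStructure}.
#' @examples
#' fa <- faStructure(matrix(c(1, 0.8), 2, 1), c(0.1, 0.2))
#' faCovariance(fa)
#' @export
faStructure <- function(loadings, specificVariances) {
  loadings <- as.matrix(loadings)
  new("FAStructure", loadings = loadings,
      specificVariances = as.numeric(specificVariances))
}

#' @rdname loadings
#' @export
setMethod("loadings", "FAStructure", function(x) x@loadings)

#' @rdname specificVariances
#' @export
setMethod("specificVariances", "FAStructure", function(x) x@specificVariances)

setMethod("show", "FAStructure", function(object) {
  cat("FAStructure: p =", nrow(object@loadings),
      " k =", ncol(object@loadings), "\n")
})

#' ModelSpec: declarative specification of the variance model
#'
#' Describes the single-stage multi-environment mixed model
#' \deqn{y = X\tau + Z_g u_a + Z_g u_{\bar a} + Z_u u + \eta}
#' where the additive effects \eqn{u_a} have covariance
#' \eqn{G_a \otimes K} (genomic kernel) and the residual genetic effects
#' \eqn{u_{\bar a}} have covariance \eqn{G_{\bar a} \otimes I_m} (identity
#' kernel), each p x p across-environment matrix being \code{"diag"} or
#' factor analytic \code{"fa<k>"}. Design random terms (replicate, bay,
#' laboratory day, ...) get one variance each; the residual is heterogeneous
#' over the levels of \code{residualGrouping}.
#'
#' @slot additive covariance structure for the additive component:
#'   \code{"diag"}, \code{"fa1"}, \code{"fa2"}, ... or \code{"none"}.
#' @slot residualGenetic structure for the residual genetic component.
#' @slot designRandom character vector of design-factor column names.
#' @slot designNesting named character; for each design factor, the column
#'   whose levels nest it (\code{"experiment"} for field factors,
#'   \code{"year"} for laboratory factors). Factors absent from this map are
#'   nested in \code{"experiment"}.
#' @slot varianceGrouping \code{"single"} (one variance per factor) or
#'   \code{"scope"} (one variance per factor per nesting level).
#' @slot residualGrouping column defining heterogeneous residual variances
#'   (default \code{"year"}, the laboratory-phase year); \code{"none"} for a
#'   single residual variance.
#' @slot fixed character vector of fixed-effect factors (always contains
#'   \code{"experiment"}).
#' @export
setClass("ModelSpec",
  representation(additive = "character", residualGenetic = "character",
                 designRandom = "character", designNesting = "character",
                 varianceGrouping = "character", residualGrouping = "character",
                 fixed = "character"),
  prototype(additive = "fa1", residualGenetic = "fa1",
            designRandom = character(0), designNesting = character(0),
            varianceGrouping = "single", residualGrouping = "year",
            fixed = "experiment"))

setValidity("ModelSpec", function(object) {
  ok <- function(s) grepl("^(none|diag|fa[1-9][0-9]*)$", s)
  if (length(object@additive) != 1 || !ok(object@additive))
    return("additive structure must be 'none', 'diag' or 'fa<k>'")
  if (length(object@residualGenetic) != 1 || !ok(object@residualGenetic))
    return("residualGenetic structure must be 'none', 'diag' or 'fa<k>'")
  if (object@additive == "none" && object@residualGenetic == "none")
    return("at least one genetic component must be present")
  if (!object@varianceGrouping %in% c("single", "scope"))
    return("varianceGrouping must be 'single' or 'scope'")
  if (!"experiment" %in% object@fixed)
    return("fixed effects must include 'experiment'")
  TRUE
})

#' Construct a ModelSpec
#'
#' @param additive structure of the additive (genomic-kernel) component:
#'   \code{"diag"}, \code{"fa1"}, \code{"fa2"}, ... or \code{"none"}.
#' @param residualGenetic structure of the residual genetic
#'   (identity-kernel) component.
#' @param designRandom character vector of design random factors (columns of
#'   the phenotype table), e.g. \code{c("replicate", "lab_day")}.
#' @param designNesting named character mapping design factors to their
#'   nesting column (\code{"experiment"} or \code{"year"}); defaults to
#'   \code{"experiment"} for unmapped factors.
#' @param varianceGrouping \code{"single"} or \code{"scope"}; see
#'   \linkS4class{ModelSpec}.
#' @param residualGrouping column for heterogeneous residual variances
#'   (default \code{"year"}); \code{"none"} for homogeneous.
#' @param fixed fixed-effect factors; \code{"experiment"} is always included.
#' @return a \linkS4class{ModelSpec}.
#' @examples
#' modelSpec("fa2", "fa2", designRandom = c("replicate", "lab_day"),
#'           designNesting = c(lab_day = "year"))
#' @export
modelSpec <- function(additive = "fa1", residualGenetic = "fa1",
                      designRandom = character(0),
                      designNesting = character(0),
                      varianceGrouping = "single",
                      residualGrouping = "year",
                      fixed = "experiment") {
  fixed <- union("experiment", fixed)
  new("ModelSpec", additive = additive, residualGenetic = residualGenetic,
      designRandom = as.character(designRandom), designNesting = designNesting,
      varianceGrouping = varianceGrouping,
      residualGrouping = residualGrouping, fixed = fixed)
}

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec: additive =", object@additive,
      "/ residual genetic =", object@residualGenetic, "\n")
  if (length(object@designRandom))
    cat("  design random:", paste(object@designRandom, collapse = ", "),
        sprintf("(%s variance grouping)", object@varianceGrouping), "\n")
  cat("  residual grouping:", object@residualGrouping, "\n")
})

#' FittedFAModel: a converged REML fit
#'
#' Result of \code{\link{remlFit}}: estimated covariance structures, REML
#' log-likelihood, fixed-effect estimates, BLUPs of both genetic components
#' for every line-by-experiment cell, and the internals needed to form
#' prediction error variance (PEV) blocks.
#'
#' @slot spec the \linkS4class{ModelSpec} that was fitted.
#' @slot experiments ordered experiment labels (length p).
#' @slot lines ordered line ids (all lines of K, length m).
#' @slot observedLines lines with at least one phenotype record.
#' @slot Ga,Gabar estimated p x p genetic covariance matrices.
#' @slot faAdditive,faResidual the \linkS4class{FAStructure} estimates when
#'   the corresponding structure is factor analytic (else \code{NULL}).
#' @slot designVariances,residualVariances named estimated variances.
#' @slot fixedEffects named fixed-effect estimates.
#' @slot loglik REML log-likelihood at convergence.
#' @slot nParams number of estimated genetic covariance parameters.
#' @slot converged logical convergence flag.
#' @slot trace optimizer iteration log.
#' @slot solutions list with m x p BLUP matrices \code{ua}, \code{uabar}.
#' @slot internals engine internals used for PEV queries.
#' @export
setClass("FittedFAModel",
  representation(spec = "ModelSpec", experiments = "character",
                 lines = "character", observedLines = "character",
                 Ga = "matrix", Gabar = "matrix",
                 faAdditive = "ANY", faResidual = "ANY",
                 designVariances = "numeric", residualVariances = "numeric",
                 fixedEffects = "numeric", loglik = "numeric",
                 nParams = "integer", converged = "logical",
                 trace = "list", solutions = "list", internals = "list"))

setMethod("show", "FittedFAModel", function(object) {
  cat("FittedFAModel:", object@spec@additive, "/",
      object@spec@residualGenetic, "\n")
  cat("  p =", length(object@experiments), "experiments, m =",
      length(object@lines), "lines\n")
  cat("  REML loglik:", format(object@loglik, digits = 8),
      " genetic parameters:", object@nParams,
      " converged:", object@converged, "\n")
})

#' @rdname geneticSolutions
#' @export
setMethod("geneticSolutions", "FittedFAModel", function(x) x@solutions)

#' @rdname varianceComponents
#' @export
setMethod("varianceComponents", "FittedFAModel", function(x)
  list(Ga = x@Ga, Gabar = x@Gabar, design = x@designVariances,
       residual = x@residualVariances))

#' @rdname lineIds
#' @export
setMethod("lineIds", "FittedFAModel", function(x) x@lines)

#' REML log-likelihood of a fit
#'
#' @param fit a \linkS4class{FittedFAModel}.
#' @return the REML log-likelihood at convergence.
#' @export
remlLogLik <- function(fit) fit@loglik

#' GeneticValues: GEBV and GV tables from a fitted model
#'
#' Per line-by-experiment genomic estimated breeding values
#' (GEBV = additive BLUP) and total genotypic values (GV = additive plus
#' residual genetic BLUP), with simple-mean aggregates over environment
#' clusters and over all experiments.
#'
#' @slot values data.frame with columns \code{line}, \code{experiment},
#'   \code{gebv}, \code{gv}.
#' @slot clusterMeans data.frame with columns \code{line}, \code{cluster},
#'   \code{gebv}, \code{gv}; includes an \code{"overall"} row set.
#' @slot clusters named character mapping experiment to cluster label.
#' @export
setClass("GeneticValues",
  representation(values = "data.frame", clusterMeans = "data.frame",
                 clusters = "character"))

setMethod("show", "GeneticValues", function(object) {
  cat("GeneticValues:", nrow(object@values), "line x experiment cells,",
      length(unique(object@clusters)), "clusters\n")
})

#' Extract the long table of a GeneticValues object
#'
#' @param gv a \linkS4class{GeneticValues}.
#' @param what \code{"values"} for the per-experiment table or
#'   \code{"clusterMeans"} for cluster/overall averages.
#' @return data.frame.
#' @export
geneticValuesTable <- function(gv, what = c("values", "clusterMeans")) {
  what <- match.arg(what)
  slot(gv, what)
}

#' CVResult: replicated cross-validation summary
#'
#' @slot perReplicate long data.frame with one row per
#'   (replicate, GEBV environment, GV environment): the fold-averaged
#'   Pearson correlation between validation-set GEBVs and full-data GVs.
#' @slot abilityMatrix mean predictive-ability matrix (GEBV environment x
#'   GV environment, including cluster and overall rows/columns).
#' @slot abilitySD standard deviation over replicates, same layout.
#' @slot summary per experiment/cluster data.frame with predictive ability,
#'   H, h2, RAPV, RABV and their sds.
#' @slot plan the fold plan data.frame used.
#' @slot droppedFolds number of non-converged folds excluded.
#' @export
setClass("CVResult",
  representation(perReplicate = "data.frame", abilityMatrix = "matrix",
                 abilitySD = "matrix", summary = "data.frame",
                 plan = "data.frame", droppedFolds = "integer"))

setMethod("show", "CVResult", function(object) {
  cat("CVResult:", length(unique(object@plan$replicate)), "replicates x",
      length(unique(object@plan$fold)), "folds\n")
  cat("  dropped (non-converged) folds:", object@droppedFolds, "\n")
})

#' SimulationConfig: dimensions and design of a simulated trial
#'
#' The default configuration emulates the motivating study: 358 lines,
#' 4,162 post-QC SNP markers, p = 8 experiments (2 years x 2 sites x 2
#' irrigation treatments), a split-plot field phase with 2 replicates and a
#' partially replicated laboratory phase with replication level 1.20 (20%
#' of field plots assayed twice).
#'
#' @slot nLines,nMarkers,nChromosomes counts.
#' @slot mafRange length-2 numeric in (0, 0.5]: range of simulated minor
#'   allele frequencies.
#' @slot experiments data.frame with columns \code{year}, \code{site},
#'   \code{irrigation} (one row per experiment).
#' @slot fieldReps replicates per experiment in the field phase.
#' @slot labReplicationRate laboratory replication level (>= 1); 1.2 means
#'   20% of field plots measured twice.
#' @slot missingRate marker missing-call rate applied before QC.
#' @slot nDroppedLines number of lines, drawn at random, whose records
#'   are removed from the last year (emulating lines excluded from a
#'   follow-up season); default 0.
#' @slot seed master seed; all stochastic draws derive from it.
#' @export
setClass("SimulationConfig",
  representation(nLines = "integer", nMarkers = "integer",
                 nChromosomes = "integer", mafRange = "numeric",
                 experiments = "data.frame", fieldReps = "integer",
                 labReplicationRate = "numeric", missingRate = "numeric",
                 nDroppedLines = "integer", seed = "integer"),
  prototype(nDroppedLines = 0L))

setValidity("SimulationConfig", function(object) {
  if (object@nLines < 2) return("nLines must be >= 2")
  if (object@nMarkers < 1 || object@nChromosomes < 1)
    return("nMarkers and nChromosomes must be positive")
  if (nrow(object@experiments) < 1)
    return("at least one experiment is required")
  if (length(object@mafRange) != 2 || any(object@mafRange <= 0) ||
      any(object@mafRange > 0.5) || diff(object@mafRange) < 0)
    return("mafRange must be increasing within (0, 0.5]")
  if (object@labReplicationRate < 1)
    return("labReplicationRate must be >= 1")
  if (object@fieldReps < 1) return("fieldReps must be >= 1")
  if (object@missingRate < 0 || object@missingRate >= 1)
    return("missingRate must be in [0, 1)")
  if (object@nDroppedLines < 0 || object@nDroppedLines >= object@nLines)
    return("nDroppedLines must be in [0, nLines)")
  TRUE
})

#' TrueParameters: generating parameters of the trial simulator
#'
#' Houses the across-environment factor-analytic structures of the additive
#' and residual genetic components, the design-factor variances, the
#' per-year residual variances and the experiment means used to simulate
#' phenotypes.
#'
#' @slot additive,residualGenetic \linkS4class{FAStructure} objects (p rows
#'   each); a diagonal truth is expressed as zero loadings.
#' @slot designVariances named nonnegative numeric (replicate, bay, row,
#'   range, lab_day, carousel, well); absent names mean variance 0.
#' @slot residualVarianceByYear named nonnegative numeric, one per year.
#' @slot experimentMeans length-p numeric vector of fixed experiment means.
#' @export
setClass("TrueParameters",
  representation(additive = "FAStructure", residualGenetic = "FAStructure",
                 designVariances = "numeric",
                 residualVarianceByYear = "numeric",
                 experimentMeans = "numeric"))

setValidity("TrueParameters", function(object) {
  p <- nrow(object@additive@loadings)
  if (nrow(object@residualGenetic@loadings) != p)
    return("additive and residual structures must have the same p")
  if (length(object@experimentMeans) != p)
    return("experimentMeans must have length p")
  if (any(object@designVariances < 0))
    return("design variances must be nonnegative")
  if (any(object@residualVarianceByYear < 0))
    return("residual variances must be nonnegative")
  TRUE
})
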