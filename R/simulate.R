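## Synthetic-data generator: marker genotypes and two-phase multi-environment
## phenotype tables whose statistical structure matches the analysis model.

#' Default experiment layout
#'
#' Two years x two sites x two irrigation treatments = 8 experiments, the
#' layout of the motivating multi-environment trial.
#'
#' @param years,sites,irrigations label vectors crossed to form experiments.
#' @return data.frame with columns \code{experiment}, \code{year},
#'   \code{site}, \code{irrigation}.
#' @export
defaultExperiments <- function(years = c("2009", "2010"),
                               sites = c("YANA", "COLE"),
                               irrigations = c("IRR", "RFD")) {
  g <- expand.grid(irrigation = irrigations, site = sites, year = years,
                   stringsAsFactors = FALSE)[, c("year", "site", "irrigation")]
  g$experiment <- paste0(substr(g$year, 3, 4), g$site, "_", g$irrigation)
  g[, c("experiment", "year", "site", "irrigation")]
}

#' Construct a SimulationConfig
#'
#' Defaults emulate the motivating study's dimensions: 358 lines, 4,162
#' post-QC SNPs over 21 chromosomes, 8 experiments, a split-plot field
#' phase with 2 replicates and a partially replicated laboratory phase at
#' replication level 1.20.
#'
#' @param nLines,nMarkers,nChromosomes simulated dimensions.
#' @param mafRange range of minor allele frequencies, within (0, 0.5].
#' @param experiments data.frame as from \code{\link{defaultExperiments}}.
#' @param fieldReps field replicates per experiment.
#' @param labReplicationRate laboratory replication level (>= 1).
#' @param missingRate marker missing-call rate applied before QC.
#' @param nDroppedLines number of randomly chosen lines excluded from the
#'   last year's records (default 0).
#' @param seed master seed; all stochastic draws derive from it via named
#'   substreams so each stage is independently reproducible.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nLines = 358, nMarkers = 4162,
                             nChromosomes = 21, mafRange = c(0.05, 0.5),
                             experiments = defaultExperiments(),
                             fieldReps = 2, labReplicationRate = 1.2,
                             missingRate = 0.01, nDroppedLines = 0,
                             seed = 1) {
  new("SimulationConfig", nLines = as.integer(nLines),
      nMarkers = as.integer(nMarkers), nChromosomes = as.integer(nChromosomes),
      mafRange = as.numeric(mafRange), experiments = experiments,
      fieldReps = as.integer(fieldReps),
      labReplicationRate = as.numeric(labReplicationRate),
      missingRate = as.numeric(missingRate),
      nDroppedLines = as.integer(nDroppedLines), seed = as.integer(seed))
}

#' Construct a TrueParameters object
#'
#' @param additive,residualGenetic \linkS4class{FAStructure} truths for the
#'   two genetic components (p rows each).
#' @param designVariances named nonnegative variances for design factors
#'   (\code{replicate}, \code{bay}, \code{row}, \code{range},
#'   \code{lab_day}, \code{carousel}, \code{well}); omitted factors get 0.
#' @param residualVarianceByYear named nonnegative variances, one per year.
#' @param experimentMeans length-p fixed experiment means.
#' @return a \linkS4class{TrueParameters}.
#' @export
trueParameters <- function(additive, residualGenetic,
                           designVariances = numeric(0),
                           residualVarianceByYear,
                           experimentMeans) {
  new("TrueParameters", additive = additive,
      residualGenetic = residualGenetic,
      designVariances = designVariances,
      residualVarianceByYear = residualVarianceByYear,
      experimentMeans = as.numeric(experimentMeans))
}

#' Default generating parameters
#'
#' Builds a two-cluster truth emulating the drought-trial structure: the
#' 2009 rainfed experiments form a water-deficit cluster, all others a
#' well-watered cluster. Both genetic components are rank-2 factor
#' structures giving within-cluster genetic correlations near 0.9 and
#' cross-cluster correlations near 0.2; variance magnitudes follow the
#' motivating study's scale (additive about 0.012, residual genetic about
#' 0.030). Laboratory and field design variances, unreported in the source
#' study, are set to small plausible values documented in the vignette.
#'
#' @param experiments data.frame as from \code{\link{defaultExperiments}}.
#' @param additiveVar,residualGeneticVar per-experiment genetic variances.
#' @param withinCor,betweenCor target within- and cross-cluster genetic
#'   correlations.
#' @return a \linkS4class{TrueParameters}.
#' @export
defaultTrueParameters <- function(experiments = defaultExperiments(),
                                  additiveVar = 0.012,
                                  residualGeneticVar = 0.030,
                                  withinCor = 0.9, betweenCor = 0.2) {
  p <- nrow(experiments)
  deficit <- experiments$irrigation == "RFD" &
    experiments$year == sort(unique(experiments$year))[1]
  if (!any(deficit) || all(deficit))
    deficit <- rep(c(FALSE, TRUE), length.out = p)  # degenerate layouts
  twoClusterFA <- function(v, within, between) {
    s <- sqrt(v)
    a <- sqrt(within)                 # shared-factor loading, cluster 1
    cross <- between / a              # cluster-2 loading on factor 1
    b <- sqrt(max(within - cross^2, 0.01))
    L <- matrix(0, p, 2)
    L[!deficit, 1] <- s * a
    L[deficit, 1] <- s * cross
    L[deficit, 2] <- s * b
    psi <- rep(v, p) - rowSums(L^2)
    faStructure(L, pmax(psi, 1e-4))
  }
  years <- sort(unique(experiments$year))
  rv <- stats::setNames(seq(0.020, 0.024, length.out = length(years)), years)
  means <- 1.2 - 0.15 * (experiments$irrigation == "RFD") +
    0.05 * (experiments$year == years[length(years)]) +
    0.02 * (experiments$site == experiments$site[1])
  trueParameters(
    additive = twoClusterFA(additiveVar, withinCor, betweenCor),
    residualGenetic = twoClusterFA(residualGeneticVar, withinCor, betweenCor),
    designVariances = c(replicate = 0.004, bay = 0.004, row = 0.002,
                        range = 0.002, lab_day = 0.006, carousel = 0.002,
                        well = 0.001),
    residualVarianceByYear = rv,
    experimentMeans = means)
}

#' Simulate marker genotypes
#'
#' Draws independent biallelic markers: per-marker allele frequencies are
#' uniform on \code{mafRange} and line dosages are Binomial(2, q). No
#' linkage disequilibrium or population structure is simulated, matching a
#' panel with no obvious genetic clustering. Missing calls are planted at
#' \code{missingRate} before any QC.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{MarkerMatrix}.
#' @examples
#' mk <- simulateMarkers(simulationConfig(nLines = 20, nMarkers = 50,
#'                                        missingRate = 0, seed = 7))
#' nMarkers(mk)
#' @export
simulateMarkers <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  m <- config@nLines; nm <- config@nMarkers
  withSeed(subSeed(config@seed, 1), {
    q <- stats::runif(nm, config@mafRange[1], config@mafRange[2])
    d <- matrix(stats::rbinom(m * nm, 2, rep(q, each = m)), m, nm)
    if (config@missingRate > 0) {
      nMiss <- round(config@missingRate * length(d))
      if (nMiss > 0) d[sample(length(d), nMiss)] <- NA
    }
    chr <- rep(seq_len(config@nChromosomes), length.out = nm)
    chr <- sort(chr)
    dimnames(d) <- list(sprintf("L%04d", seq_len(m)),
                        sprintf("S%02d_%05d", chr,
                                stats::ave(chr, chr, FUN = seq_along)))
    markerMatrix(d)
  })
}

# Draw an m x p genetic-effect matrix with covariance G (across columns)
# and kernel Ksqrt Ksqrt' (across rows): U = Ksqrt Z Gsqrt.
drawGenetic <- function(Ksqrt, G, m, p) {
  Gs <- symSqrt(G)
  Z <- matrix(stats::rnorm(m * p), m, p)
  if (is.null(Ksqrt)) Z %*% Gs else Ksqrt %*% Z %*% Gs
}

#' Simulate a two-phase multi-environment trial
#'
#' Draws additive effects \eqn{u_a \sim N(0, G_a \otimes K)} and residual
#' genetic effects \eqn{u_{\bar a} \sim N(0, G_{\bar a} \otimes I_m)},
#' independent design-factor effects and within-year residuals, and
#' assembles plot-level records for a split-plot field phase (irrigation as
#' the main-plot factor, lines randomized within replicates) followed by a
#' partially replicated laboratory phase (a fraction
#' \code{labReplicationRate - 1} of field plots, chosen uniformly at
#' random, is measured twice; samples are pooled per year and laid out over
#' measurement days, carousels and wells).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param truth a \linkS4class{TrueParameters} with p matching
#'   \code{config}.
#' @param K a \linkS4class{RelationshipMatrix} for the additive kernel
#'   (dimension \code{nLines}); \code{NULL} uses the identity.
#' @return data.frame with columns \code{experiment}, \code{year},
#'   \code{site}, \code{irrigation}, \code{line}, \code{replicate},
#'   \code{bay}, \code{row}, \code{range}, \code{lab_day}, \code{carousel},
#'   \code{well}, \code{value}. The simulated genetic-effect matrices are
#'   attached as \code{attr(, "genetic")} (list \code{ua}, \code{uabar},
#'   lines x experiments) for parameter-recovery studies.
#' @export
simulateTrial <- function(config, truth = NULL, K = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  if (is.null(truth))
    truth <- defaultTrueParameters(config@experiments)
  stopifnot(is(truth, "TrueParameters"))
  exps <- config@experiments
  p <- nrow(exps)
  m <- config@nLines
  if (nrow(truth@additive@loadings) != p)
    stopf("faGBLUP_param_error",
          "truth has p = %d but config declares %d experiments",
          nrow(truth@additive@loadings), p)
  Ga <- faCovariance(truth@additive)
  Gab <- faCovariance(truth@residualGenetic)
  for (nm in c("additive", "residualGenetic")) {
    G <- if (nm == "additive") Ga else Gab
    if (min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stopf("faGBLUP_param_error",
            "implied %s covariance is not positive semidefinite", nm)
  }
  lines <- if (!is.null(K)) lineIds(K) else sprintf("L%04d", seq_len(m))
  if (!is.null(K) && nrow(kinship(K)) != m)
    stopf("faGBLUP_param_error",
          "K has %d lines but config declares nLines = %d",
          nrow(kinship(K)), m)
  Ksqrt <- if (!is.null(K)) symSqrt(kinship(K)) else NULL

  withSeed(subSeed(config@seed, 2), {
    ua <- drawGenetic(Ksqrt, Ga, m, p)
    uabar <- drawGenetic(NULL, Gab, m, p)
    dimnames(ua) <- dimnames(uabar) <- list(lines, exps$experiment)

    dv <- function(nm) {
      v <- truth@designVariances
      if (nm %in% names(v)) v[[nm]] else 0
    }
    effectStore <- new.env(parent = emptyenv())
    levelEffect <- function(factor, level, sd) {
      key <- paste(factor, level, sep = "\r")
      if (is.null(effectStore[[key]]))
        effectStore[[key]] <- stats::rnorm(1, 0, sd)
      effectStore[[key]]
    }

    ## Field phase: one plot per line per replicate per experiment.
    nRanges <- ceiling(sqrt(m))
    nRows <- ceiling(m / nRanges)
    fp <- vector("list", p * config@fieldReps)
    kf <- 0
    for (j in seq_len(p)) {
      for (r in seq_len(config@fieldReps)) {
        ord <- sample.int(m)   # randomized allocation within the replicate
        pos <- seq_len(m)
        kf <- kf + 1
        fp[[kf]] <- data.frame(
          experiment = exps$experiment[j], year = exps$year[j],
          site = exps$site[j], irrigation = exps$irrigation[j],
          line = lines[ord],
          replicate = paste0(exps$year[j], exps$site[j], "_R", r),
          bay = paste0(exps$experiment[j], "_R", r),
          row = paste0(exps$experiment[j], "_R", r, "_row",
                       (pos - 1) %% nRows + 1),
          range = paste0(exps$experiment[j], "_R", r, "_rng",
                         (pos - 1) %/% nRows + 1),
          expIndex = j, stringsAsFactors = FALSE)
      }
    }
    plots <- do.call(rbind, fp)
    if (config@nDroppedLines > 0) {
      lastYear <- utils::tail(sort(unique(plots$year)), 1)
      droppedLines <- sample(lines, config@nDroppedLines)
      plots <- plots[!(plots$year == lastYear &
                         plots$line %in% droppedLines), , drop = FALSE]
    }
    plots$plotId <- seq_len(nrow(plots))
    fieldEffect <- numeric(nrow(plots))
    for (fac in c("replicate", "bay", "row", "range")) {
      sd <- sqrt(dv(fac))
      fieldEffect <- fieldEffect + vapply(plots[[fac]], function(lv)
        levelEffect(fac, lv, sd), numeric(1))
    }
    plots$fieldEffect <- fieldEffect

    ## Laboratory phase: per-year pooled p-rep layout.
    labRecords <- vector("list", 0)
    for (yr in unique(plots$year)) {
      py <- plots[plots$year == yr, ]
      nPlots <- nrow(py)
      nLab <- round(config@labReplicationRate * nPlots)
      nDup <- nLab - nPlots
      dupIdx <- if (nDup > 0) sample(nPlots, nDup) else integer(0)
      idx <- c(seq_len(nPlots), dupIdx)
      idx <- idx[sample.int(length(idx))]      # randomized lab order
      slot <- seq_along(idx)
      well <- (slot - 1) %% 30 + 1
      carousel <- (slot - 1) %/% 30 %% 5 + 1
      day <- (slot - 1) %/% 150 + 1
      rec <- py[idx, ]
      rec$lab_day <- paste0(yr, "_D", day)
      rec$carousel <- paste0(yr, "_D", day, "_C", carousel)
      rec$well <- paste0(yr, "_W", well)
      labRecords[[length(labRecords) + 1]] <- rec
    }
    rec <- do.call(rbind, labRecords)

    labEffect <- numeric(nrow(rec))
    for (fac in c("lab_day", "carousel", "well")) {
      sd <- sqrt(dv(fac))
      labEffect <- labEffect + vapply(rec[[fac]], function(lv)
        levelEffect(fac, lv, sd), numeric(1))
    }
    resSD <- sqrt(truth@residualVarianceByYear[as.character(rec$year)])
    li <- match(rec$line, lines)
    cellIdx <- cbind(li, rec$expIndex)
    rec$value <- truth@experimentMeans[rec$expIndex] +
      ua[cellIdx] + uabar[cellIdx] + rec$fieldEffect + labEffect +
      stats::rnorm(nrow(rec), 0, resSD)

    out <- rec[, c("experiment", "year", "site", "irrigation", "line",
                   "replicate", "bay", "row", "range", "lab_day",
                   "carousel", "well", "value")]
    rownames(out) <- NULL
    attr(out, "genetic") <- list(ua = ua, uabar = uabar)
    out
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: markers, QC + imputation + relationship matrix, and
#' the two-phase phenotype table, all from one configuration.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param truth optional \linkS4class{TrueParameters}; default
#'   \code{\link{defaultTrueParameters}}.
#' @return list with \code{markers} (raw), \code{qc} (QC report),
#'   \code{K} (\linkS4class{RelationshipMatrix}), \code{phenotypes}
#'   (data.frame), \code{truth} and \code{genetic} (true effect matrices).
#' @export
simulateDataset <- function(config, truth = NULL) {
  if (is.null(truth)) truth <- defaultTrueParameters(config@experiments)
  markers <- simulateMarkers(config)
  flt <- filterMarkers(markers)
  K <- computeGRM(imputeMissing(flt$markers))
  phen <- simulateTrial(config, truth, K)
  list(markers = markers, qc = flt$report, K = K, phenotypes = phen,
       truth = truth, genetic = attr(phen, "genetic"))
}

#' Write simulation fixtures to disk
#'
#' Emits the marker, phenotype, relationship-matrix and truth files in the
#' package's external text formats (see the I/O functions); all files
#' round-trip through the package readers. The target directory is checked
#' for writability before any file is created, so a failure leaves no
#' partial output.
#'
#' @param sim list as returned by \code{\link{simulateDataset}} (elements
#'   \code{markers}, \code{phenotypes}, and optionally \code{K},
#'   \code{truth}).
#' @param dir output directory (created if absent).
#' @return named character vector of written paths.
#' @export
writeFixtures <- function(sim, dir) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE, showWarnings = FALSE))
      stopf("faGBLUP_io_error", "cannot create directory '%s'", dir)
  if (file.access(dir, 2) != 0)
    stopf("faGBLUP_io_error", "directory '%s' is not writable", dir)
  paths <- c()
  if (!is.null(sim$markers)) {
    paths["markers"] <- file.path(dir, "markers.tsv")
    writeMarkers(sim$markers, paths["markers"])
  }
  if (!is.null(sim$phenotypes)) {
    paths["phenotypes"] <- file.path(dir, "phenotypes.tsv")
    writePhenotypes(sim$phenotypes, paths["phenotypes"])
  }
  if (!is.null(sim$K)) {
    paths["kinship"] <- file.path(dir, "kinship.tsv")
    writeRelationshipMatrix(sim$K, paths["kinship"])
  }
  if (!is.null(sim$truth)) {
    paths["truth"] <- file.path(dir, "truth.yaml")
    writeTruth(sim$truth, paths["truth"])
  }
  paths
}
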