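## End-to-end orchestration: simulate (or read) -> QC -> relationship
## matrix -> model ladder -> final fit -> genetic values, correlations,
## clusters, heritabilities -> cross-validation -> report bundle.

#' Default run configuration
#'
#' \code{preset = "small"} (the default) analyses a simulated dataset of
#' 120 lines x 4 experiments with the full two-phase design -- sized so a
#' complete run (ladder, prediction, cross-validation) finishes in
#' minutes. \code{preset = "full"} uses the study-scale conditions
#' (358 lines, 4,162 markers, 8 experiments) and is compute-intensive.
#'
#' @param preset \code{"small"} or \code{"full"}.
#' @param seed master seed.
#' @return a run-configuration list accepted by
#'   \code{\link{runFullAnalysis}} with sections \code{simulation}
#'   (\code{config}, \code{truth}), \code{model} (\code{structures},
#'   \code{designRandom}, \code{designNesting}, \code{residualGrouping}),
#'   \code{clustering} and \code{cv}. Replace \code{simulation} with an
#'   \code{input} section (paths \code{markers}, \code{phenotypes},
#'   optional \code{kinship}) to analyse real files.
#' @export
defaultRunConfig <- function(preset = c("small", "full"), seed = 1) {
  preset <- match.arg(preset)
  if (preset == "small") {
    exps <- defaultExperiments(sites = "YANA")
    simcfg <- simulationConfig(nLines = 120, nMarkers = 600,
                               experiments = exps, seed = seed)
    structures <- list(c("diag", "diag"), c("fa1", "fa1"), c("fa2", "fa2"))
    cv <- list(nFolds = 5, nReplicates = 2)
  } else {
    simcfg <- simulationConfig(seed = seed)
    structures <- list(c("diag", "diag"), c("fa1", "fa1"),
                       c("fa1", "fa2"), c("fa2", "fa1"), c("fa2", "fa2"))
    cv <- list(nFolds = 5, nReplicates = 10)
  }
  list(
    simulation = list(config = simcfg,
                      truth = defaultTrueParameters(simcfg@experiments)),
    model = list(
      structures = structures,
      designRandom = c("replicate", "bay", "row", "range",
                       "lab_day", "carousel", "well"),
      designNesting = c(lab_day = "year", carousel = "year", well = "year"),
      varianceGrouping = "single",
      residualGrouping = "year"),
    clustering = list(nClusters = 2, component = "total",
                      linkage = "average"),
    cv = cv,
    seed = seed)
}

validateRunConfig <- function(config) {
  hasInput <- !is.null(config$input)
  hasSim <- !is.null(config$simulation)
  if (hasInput == hasSim)
    stopf("faGBLUP_config_error",
          "exactly one of 'input' and 'simulation' must be present")
  if (is.null(config$seed)) config$seed <- 1
  if (is.null(config$model)) config$model <- defaultRunConfig()$model
  if (is.null(config$clustering))
    config$clustering <- defaultRunConfig()$clustering
  if (is.null(config$cv)) config$cv <- list(nFolds = 5, nReplicates = 2)
  config
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (simulation or file input), marker
#' QC and imputation, relationship matrix, the model ladder with AIC/LRT
#' selection, the final-model REML fit, genetic values (GEBV/GV),
#' between-environment correlation matrices and environment clustering,
#' the heritability table, and replicated cross-validation. All tabular
#' artifacts are written as tab-delimited text under \code{outputDir}
#' together with a JSON run manifest; a stage failure is recorded in the
#' bundle and the completed stages are kept.
#'
#' @param config configuration list (see \code{\link{defaultRunConfig}}).
#' @param outputDir directory for artifacts (created if needed);
#'   \code{NULL} skips writing.
#' @return invisible bundle list with elements \code{qc}, \code{K},
#'   \code{ladder}, \code{fit}, \code{geneticValues}, \code{correlations},
#'   \code{clustering}, \code{heritability}, \code{cv}, \code{manifest}
#'   and, on failure, \code{failure}.
#' @export
runFullAnalysis <- function(config = defaultRunConfig(), outputDir = NULL) {
  config <- validateRunConfig(config)
  bundle <- list()
  warningsSeen <- character(0)
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warningsSeen <<- c(warningsSeen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  fail <- function(stage, e) {
    bundle$failure <<- list(stage = stage, message = conditionMessage(e))
  }

  ## Stage 1: data
  ok <- tryCatch({
    if (!is.null(config$simulation)) {
      sim <- collect(simulateDataset(config$simulation$config,
                                     config$simulation$truth))
      bundle$qc <- sim$qc
      bundle$K <- sim$K
      phen <- sim$phenotypes
      bundle$genetic <- sim$genetic
    } else {
      markers <- readMarkers(config$input$markers)
      flt <- collect(filterMarkers(markers))
      bundle$qc <- flt$report
      bundle$K <- if (!is.null(config$input$kinship))
        readRelationshipMatrix(config$input$kinship)
      else computeGRM(imputeMissing(flt$markers))
      phen <- readPhenotypes(config$input$phenotypes)
    }
    bundle$phenotypes <- phen
    TRUE
  }, error = function(e) { fail("data", e); FALSE })
  if (!ok) return(invisible(bundle))

  baseSpec <- modelSpec(
    designRandom = config$model$designRandom %||% character(0),
    designNesting = config$model$designNesting %||% character(0),
    varianceGrouping = config$model$varianceGrouping %||% "single",
    residualGrouping = config$model$residualGrouping %||% "year")

  ## Stage 2: ladder + final fit
  ok <- tryCatch({
    lad <- collect(modelLadder(phen, bundle$K,
                               structures = config$model$structures,
                               baseSpec = baseSpec, computePEV = TRUE))
    bundle$ladder <- lad$table
    if (is.na(lad$selected))
      stopf("faGBLUP_fit_error", "no ladder model converged")
    bundle$fit <- lad$fits[[lad$selected]]
    bundle$selectedModel <- lad$table$model[lad$selected]
    TRUE
  }, error = function(e) { fail("ladder", e); FALSE })
  if (!ok) return(invisible(bundle))

  ## Stage 3: prediction summaries
  ok <- tryCatch({
    corrs <- list(
      additive = collect(envCorrelation(bundle$fit, "additive")),
      residual = collect(envCorrelation(bundle$fit, "residual")),
      total = collect(envCorrelation(bundle$fit, "total")))
    bundle$correlations <- corrs
    cl <- clusterEnvironments(
      corrs[[config$clustering$component %||% "total"]],
      nClusters = config$clustering$nClusters %||% 2,
      linkage = config$clustering$linkage %||% "average")
    bundle$clustering <- cl
    bundle$geneticValues <- extractGV(bundle$fit, cl$labels)
    bundle$heritability <- collect(heritabilityTable(bundle$fit, cl$labels))
    TRUE
  }, error = function(e) { fail("prediction", e); FALSE })
  if (!ok) return(invisible(bundle))

  ## Stage 4: cross-validation
  ok <- tryCatch({
    bundle$cv <- collect(runCV(
      phen, bundle$K, bundle$fit@spec,
      fullFit = bundle$fit, clusters = bundle$clustering$labels,
      nFolds = config$cv$nFolds %||% 5,
      nReplicates = config$cv$nReplicates %||% 2,
      seed = subSeed(config$seed, 7)))
    TRUE
  }, error = function(e) { fail("cv", e); FALSE })

  bundle$manifest <- list(
    package = "faGBLUP",
    version = as.character(utils::packageVersion("faGBLUP")),
    seed = config$seed,
    selected_model = bundle$selectedModel,
    stages_completed = intersect(
      c("qc", "K", "ladder", "fit", "geneticValues", "correlations",
        "clustering", "heritability", "cv"), names(bundle)),
    warnings = warningsSeen,
    cv_dropped_folds = if (!is.null(bundle$cv)) bundle$cv@droppedFolds
                       else NA_integer_)

  if (!is.null(outputDir)) writeBundle(bundle, outputDir)
  invisible(bundle)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write all bundle artifacts as delimited text / JSON.
writeBundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$qc))
    jsonlite::write_json(bundle$qc, file.path(dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$K))
    writeRelationshipMatrix(bundle$K, file.path(dir, "kinship.tsv"))
  if (!is.null(bundle$ladder)) {
    w(bundle$ladder, "ladder.tsv")
    jsonlite::write_json(bundle$ladder, file.path(dir, "ladder.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(bundle$fit)) {
    fit <- bundle$fit
    jsonlite::write_json(list(
      additive_structure = fit@spec@additive,
      residual_structure = fit@spec@residualGenetic,
      loglik = fit@loglik, n_params = fit@nParams,
      converged = fit@converged,
      Ga = fit@Ga, Gabar = fit@Gabar,
      design_variances = as.list(fit@designVariances),
      residual_variances = as.list(fit@residualVariances),
      fixed_effects = as.list(fit@fixedEffects)),
      file.path(dir, "fit_report.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(bundle$geneticValues)) {
    w(bundle$geneticValues@values, "genetic_values.tsv")
    w(bundle$geneticValues@clusterMeans, "genetic_values_clusters.tsv")
  }
  if (!is.null(bundle$correlations))
    for (nm in names(bundle$correlations))
      writeSquareMatrix(bundle$correlations[[nm]],
                        file.path(dir, paste0("correlation_", nm, ".tsv")))
  if (!is.null(bundle$clustering)) {
    writeClusterTree(bundle$clustering$tree,
                     file.path(dir, "cluster_tree.nwk"))
    w(data.frame(experiment = names(bundle$clustering$labels),
                 cluster = unname(bundle$clustering$labels)),
      "cluster_assignments.tsv")
  }
  if (!is.null(bundle$heritability)) w(bundle$heritability,
                                       "heritability.tsv")
  if (!is.null(bundle$cv)) {
    w(bundle$cv@perReplicate, "cv_per_replicate.tsv")
    writeSquareMatrix(bundle$cv@abilityMatrix,
                      file.path(dir, "cv_ability_matrix.tsv"))
    writeSquareMatrix(bundle$cv@abilitySD,
                      file.path(dir, "cv_ability_sd.tsv"))
    w(bundle$cv@summary, "cv_summary.tsv")
    jsonlite::write_json(bundle$cv@summary,
                         file.path(dir, "cv_summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$failure))
    jsonlite::write_json(bundle$failure, file.path(dir, "failure.json"),
                         auto_unbox = TRUE)
  invisible(dir)
}

#' Render report tables from a bundle
#'
#' Formats the model-ladder table and the heritability / predictive
#' accuracy table as aligned text, with the column semantics of the usual
#' multi-environment genomic-selection reports (structure pair, REML
#' log-likelihood, AIC, parameter counts, LRTs; and per experiment/cluster
#' variances, proportion additive, H, h2, predictive ability, RAPV, RABV).
#' Missing stages render as placeholders.
#'
#' @param bundle result of \code{\link{runFullAnalysis}}.
#' @return named list of character vectors (lines), elements
#'   \code{ladder} and \code{accuracy}.
#' @export
reportTables <- function(bundle) {
  out <- list()
  if (is.null(bundle$ladder)) {
    out$ladder <- "(ladder unavailable)"
  } else {
    t1 <- bundle$ladder
    hdr <- sprintf("%-12s %12s %12s %8s %4s %-14s %10s %10s",
                   "Model", "LogLik", "AIC", "Params", "df",
                   "Comparison", "LRT", "P")
    rows <- vapply(seq_len(nrow(t1)), function(i) sprintf(
      "%-12s %12.3f %12.3f %8d %4s %-14s %10s %10s",
      t1$model[i], t1$loglik[i], t1$aic[i], t1$n_params[i],
      ifelse(is.na(t1$df[i]), "", as.character(t1$df[i])),
      t1$comparison[i],
      ifelse(is.na(t1$lrt_statistic[i]), "",
             sprintf("%.2f", t1$lrt_statistic[i])),
      ifelse(is.na(t1$p_value[i]), "",
             format(t1$p_value[i], digits = 3))), character(1))
    out$ladder <- c(hdr, rows)
  }
  if (is.null(bundle$heritability) || is.null(bundle$cv)) {
    out$accuracy <- "(accuracy table unavailable)"
  } else {
    sm <- bundle$cv@summary
    ht <- bundle$heritability
    hdr <- sprintf("%-14s %9s %9s %7s %6s %6s %8s %8s %8s",
                   "Unit", "sigma2_a", "sigma2_ab", "propAdd",
                   "H", "h2", "predAb", "RAPV", "RABV")
    rows <- vapply(seq_len(nrow(sm)), function(i) {
      u <- sm$unit[i]
      hrow <- ht[ht$unit == u, ][1, ]
      sprintf("%-14s %9.5f %9.5f %6.1f%% %6.3f %6.3f %8.3f %8.3f %8.3f",
              u, hrow$sigma2_a, hrow$sigma2_abar,
              100 * hrow$prop_additive, hrow$H, hrow$h2,
              sm$predictive_ability[i], sm$rapv[i], sm$rabv[i])
    }, character(1))
    out$accuracy <- c(hdr, rows)
  }
  out
}
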