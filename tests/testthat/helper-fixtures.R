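# Shared simulation fixtures, built in code at test time.

p2exps <- function() defaultExperiments(sites = "YANA",
                                        irrigations = "IRR")[, ]
p4exps <- function() defaultExperiments(sites = "YANA")

p6exps <- function() {
  g <- expand.grid(site = c("ALPH", "BETA", "GAMA"),
                   year = c("2009", "2010"), stringsAsFactors = FALSE)
  data.frame(experiment = paste0(substr(g$year, 3, 4), g$site),
             year = g$year, site = g$site,
             irrigation = "IRR", stringsAsFactors = FALSE)
}

# Balanced one-record-per-cell simulation (fast eigen-path territory).
balancedConfig <- function(m, exps, seed, nMarkers = 60 + 2 * m) {
  simulationConfig(nLines = m, nMarkers = nMarkers, experiments = exps,
                   fieldReps = 1, labReplicationRate = 1,
                   missingRate = 0, seed = seed)
}

# FA1/FA1 truth with moderate signal and no design-factor variance.
fa1Truth <- function(exps, addVar = 0.30, resVar = 0.20,
                     residualVar = 0.35) {
  p <- nrow(exps)
  lamA <- sqrt(addVar) * seq(0.85, 1.15, length.out = p)
  lamB <- sqrt(resVar) * seq(1.1, 0.9, length.out = p)
  years <- sort(unique(exps$year))
  trueParameters(
    additive = faStructure(matrix(lamA, p, 1), rep(0.2 * addVar, p)),
    residualGenetic = faStructure(matrix(lamB, p, 1), rep(0.2 * resVar, p)),
    designVariances = numeric(0),
    residualVarianceByYear = stats::setNames(rep(residualVar,
                                                 length(years)), years),
    experimentMeans = seq(1, 1.2, length.out = p))
}

# Truth with all genetic variance switched off.
nullTruth <- function(exps, residualVar = 0.4) {
  p <- nrow(exps)
  years <- sort(unique(exps$year))
  trueParameters(
    additive = faStructure(matrix(0, p, 1), rep(0, p)),
    residualGenetic = faStructure(matrix(0, p, 1), rep(0, p)),
    designVariances = numeric(0),
    residualVarianceByYear = stats::setNames(rep(residualVar,
                                                 length(years)), years),
    experimentMeans = rep(1, p))
}

# Diagonal (uncorrelated-across-environment) truth.
diagTruth <- function(exps, addVar = 0.30, resVar = 0.20,
                      residualVar = 0.5) {
  p <- nrow(exps)
  years <- sort(unique(exps$year))
  trueParameters(
    additive = faStructure(matrix(0, p, 1), rep(addVar, p)),
    residualGenetic = faStructure(matrix(0, p, 1), rep(resVar, p)),
    designVariances = numeric(0),
    residualVarianceByYear = stats::setNames(rep(residualVar,
                                                 length(years)), years),
    experimentMeans = rep(1, p))
}

# A random small model/data instance for engine verification: varies size,
# structures, balance and design terms deterministically with the seed.
randomSmallInstance <- function(seed) {
  set.seed(seed)
  p <- sample(2:4, 1)
  exps <- if (p == 2) p2exps() else p4exps()[seq_len(p), ]
  m <- sample(12:30, 1)
  twoPhase <- runif(1) < 0.5
  cfg <- simulationConfig(
    nLines = m, nMarkers = 80, experiments = exps,
    fieldReps = if (twoPhase) 2 else 1,
    labReplicationRate = if (twoPhase) 1.2 else 1,
    missingRate = 0, seed = seed)
  truth <- defaultTrueParameters(exps, additiveVar = 0.3,
                                 residualGeneticVar = 0.2)
  sim <- simulateDataset(cfg, truth)
  sa <- sample(c("diag", "fa1"), 1)
  sb <- sample(c("diag", "fa1"), 1)
  spec <- modelSpec(sa, sb,
                    designRandom = if (twoPhase) c("replicate", "lab_day")
                                   else character(0),
                    designNesting = c(lab_day = "year"),
                    residualGrouping = sample(c("year", "none"), 1))
  list(data = sim$phenotypes, K = sim$K, spec = spec, m = m, p = p,
       twoPhase = twoPhase)
}

# Zero-additive truth: residual genetic and residual variance remain, so
# full-data GVs are informative while GEBVs carry no signal.
nullAdditiveTruth <- function(exps, resVar = 0.4, residualVar = 0.3) {
  p <- nrow(exps)
  years <- sort(unique(exps$year))
  lamB <- sqrt(0.7 * resVar)
  trueParameters(
    additive = faStructure(matrix(0, p, 1), rep(0, p)),
    residualGenetic = faStructure(matrix(lamB, p, 1),
                                  rep(0.3 * resVar, p)),
    designVariances = numeric(0),
    residualVarianceByYear = stats::setNames(rep(residualVar,
                                                 length(years)), years),
    experimentMeans = rep(1, p))
}

# Two planted environment clusters with an explicit membership mask:
# within-cluster genetic correlation `within`, cross-cluster `between`.
plantedTwoClusterTruth <- function(exps, deficit, addVar = 0.4,
                                   resVar = 0.15, within = 0.9,
                                   between = 0.1, residualVar = 0.3) {
  p <- nrow(exps)
  twoClusterFA <- function(v) {
    s <- sqrt(v)
    a <- sqrt(within)
    cross <- between / a
    b <- sqrt(max(within - cross^2, 0.01))
    L <- matrix(0, p, 2)
    L[!deficit, 1] <- s * a
    L[deficit, 1] <- s * cross
    L[deficit, 2] <- s * b
    faStructure(L, pmax(rep(v, p) - rowSums(L^2), 1e-4))
  }
  years <- sort(unique(exps$year))
  trueParameters(
    additive = twoClusterFA(addVar),
    residualGenetic = twoClusterFA(resVar),
    designVariances = numeric(0),
    residualVarianceByYear = stats::setNames(rep(residualVar,
                                                 length(years)), years),
    experimentMeans = rep(1, p))
}
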