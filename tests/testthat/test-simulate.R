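test_that("zero-variance truth reproduces experiment means exactly and the
           trial is deterministic under the seed", {
  exps <- p4exps()
  cfg <- simulationConfig(nLines = 10, nMarkers = 50, experiments = exps,
                          fieldReps = 2, labReplicationRate = 1.2,
                          missingRate = 0, seed = 21)
  mu <- c(1.1, 0.9, 1.3, 1.0)
  truth <- trueParameters(
    additive = faStructure(matrix(0, 4, 1), rep(0, 4)),
    residualGenetic = faStructure(matrix(0, 4, 1), rep(0, 4)),
    residualVarianceByYear = c("2009" = 0, "2010" = 0),
    experimentMeans = mu)
  phen <- simulateTrial(cfg, truth)
  expect_equal(phen$value,
               mu[match(phen$experiment, exps$experiment)])
  phen2 <- simulateTrial(cfg, truth)
  expect_identical(phen, phen2)
})

test_that("rank-1 additive truth with zero specific variance gives
           perfectly correlated effects across experiments", {
  exps <- p4exps()
  cfg <- balancedConfig(400, exps, seed = 31)
  truth <- trueParameters(
    additive = faStructure(matrix(0.5, 4, 1), rep(0, 4)),
    residualGenetic = faStructure(matrix(0, 4, 1), rep(0, 4)),
    residualVarianceByYear = c("2009" = 0.1, "2010" = 0.1),
    experimentMeans = rep(0, 4))
  phen <- simulateTrial(cfg, truth)
  ua <- attr(phen, "genetic")$ua
  cors <- cor(ua)
  expect_true(all(abs(cors - 1) < 1e-10))
})

test_that("simulated genetic components recover their generating
           across-experiment covariances (moment check)", {
  exps <- p4exps()
  cfg <- balancedConfig(2000, exps, seed = 41, nMarkers = 300)
  truth <- defaultTrueParameters(exps, additiveVar = 0.4,
                                 residualGeneticVar = 0.25)
  K <- computeGRM(imputeMissing(simulateMarkers(cfg)))
  phen <- simulateTrial(cfg, truth, K)
  gen <- attr(phen, "genetic")
  GaTrue <- faCovariance(truth@additive)
  GbTrue <- faCovariance(truth@residualGenetic)
  # residual genetic: iid across lines, plain sample covariance
  empB <- cov(gen$uabar)
  seB <- sqrt((GbTrue^2 + outer(diag(GbTrue), diag(GbTrue))) / 2000)
  expect_true(all(abs(empB - GbTrue) < 3.5 * seB + 0.01))
  # additive: var(vec) = Ga x K, so ua' K^{-1} ua / m estimates Ga with
  # Wishart-type standard errors
  empA <- t(gen$ua) %*% solve(kinship(K), gen$ua) / 2000
  seA <- sqrt((GaTrue^2 + outer(diag(GaTrue), diag(GaTrue))) / 2000)
  expect_true(all(abs(empA - GaTrue) < 3.5 * seA + 0.01))
})

test_that("additive effects propagate the kinship structure
           (cov(u_i, u_j) proportional to K_ij)", {
  exps <- p2exps()
  m <- 2000
  cfg <- balancedConfig(m, exps, seed = 51, nMarkers = 150)
  lam <- 0.6
  truth <- trueParameters(
    additive = faStructure(matrix(lam, 2, 1), rep(0, 2)),
    residualGenetic = faStructure(matrix(0, 2, 1), rep(0, 2)),
    residualVarianceByYear = c("2009" = 0.1, "2010" = 0.1),
    experimentMeans = rep(0, 2))
  K <- computeGRM(imputeMissing(simulateMarkers(cfg)))
  phen <- simulateTrial(cfg, truth, K)
  ua <- attr(phen, "genetic")$ua[, 1]
  # regression of pairwise products u_i u_j on K_ij has slope ~ lambda^2
  Kv <- kinship(K)
  ut <- tcrossprod(ua)
  sel <- upper.tri(Kv)
  slope <- coef(lm(ut[sel] ~ Kv[sel]))[2]
  expect_gt(slope, lam^2 * 0.6)
  expect_lt(slope, lam^2 * 1.5)
})

test_that("two-phase design bookkeeping: lab record counts and plot
           coverage match the replication level", {
  exps <- p4exps()
  cfg <- simulationConfig(nLines = 37, nMarkers = 50, experiments = exps,
                          fieldReps = 2, labReplicationRate = 1.2,
                          missingRate = 0, seed = 61)
  phen <- simulateTrial(cfg)
  nFieldPlots <- 37 * 2 * 4
  plotKey <- paste(phen$experiment, phen$line, phen$replicate,
                   phen$row, phen$range)
  # every field plot appears at least once in the lab phase
  expect_equal(length(unique(plotKey)), nFieldPlots)
  # lab records per year = round(rate x field plots of that year);
  # the total is the sum of the per-year laboratory designs
  nLabByYear <- integer(0)
  for (yr in unique(phen$year)) {
    nPlotsYr <- length(unique(plotKey[phen$year == yr]))
    expect_equal(sum(phen$year == yr), round(1.2 * nPlotsYr))
    nLabByYear <- c(nLabByYear, round(1.2 * nPlotsYr))
  }
  expect_equal(nrow(phen), sum(nLabByYear))
  # split-plot labels: replicate blocks shared across irrigation,
  # bays nested within experiment
  expect_true(all(table(phen$replicate[!duplicated(plotKey)]) >= 37))
  expect_identical(length(unique(phen$bay)), 4L * 2L)
})

test_that("a dimension mismatch between truth and config is a parameter
           error", {
  cfg <- balancedConfig(10, p4exps(), seed = 1)
  badTruth <- fa1Truth(p2exps())
  expect_error(simulateTrial(cfg, badTruth),
               class = "faGBLUP_param_error")
})

test_that("optional line dropping removes the lines from the last year
           only", {
  exps <- p4exps()
  cfg <- simulationConfig(nLines = 20, nMarkers = 30, experiments = exps,
                          fieldReps = 1, labReplicationRate = 1,
                          missingRate = 0, nDroppedLines = 5, seed = 71)
  phen <- simulateTrial(cfg)
  byYear <- table(phen$year)
  expect_equal(unname(byYear[["2009"]]), 20 * 2)
  expect_equal(unname(byYear[["2010"]]), 15 * 2)
  dropped <- setdiff(unique(phen$line[phen$year == "2009"]),
                     unique(phen$line[phen$year == "2010"]))
  expect_identical(length(dropped), 5L)
  expect_error(simulationConfig(nLines = 10, nDroppedLines = 10),
               "nDroppedLines")
})
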