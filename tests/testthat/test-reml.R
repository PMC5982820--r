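test_that("the two engines and the projection-form oracle evaluate the
           same REML log-likelihood", {
  exps <- p4exps()
  cfg <- balancedConfig(25, exps, seed = 71)
  sim <- simulateDataset(cfg, fa1Truth(exps))
  spec <- modelSpec("fa1", "fa1")
  md <- faGBLUP:::assembleModelData(sim$phenotypes, sim$K, spec)
  sde <- faGBLUP:::denseSetup(md)
  see <- faGBLUP:::eigenSetup(md)
  th <- faGBLUP:::startingValues(md)$theta
  evD <- faGBLUP:::denseEval(md, sde, th)
  evE <- faGBLUP:::eigenEval(md, see, th)
  expect_equal(evD$value, evE$value, tolerance = 1e-10)
  pars <- faGBLUP:::unpackParams(md, th)
  orc <- loglikOracle(sim$phenotypes, sim$K,
                      list(Ga = pars$Ga, Gabar = pars$Gab,
                           design = pars$design, residual = pars$resid),
                      spec)
  expect_lt(abs(orc - evD$value), 1e-8)
})

test_that("analytic gradients match central finite differences in both
           engines", {
  exps <- p4exps()
  # unbalanced two-phase instance with design terms: dense engine
  cfg <- simulationConfig(nLines = 15, nMarkers = 60, experiments = exps,
                          fieldReps = 2, labReplicationRate = 1.2,
                          missingRate = 0, seed = 81)
  sim <- simulateDataset(cfg)
  spec <- modelSpec("fa1", "diag", designRandom = c("replicate", "lab_day"),
                    designNesting = c(lab_day = "year"))
  md <- faGBLUP:::assembleModelData(sim$phenotypes, sim$K, spec)
  sde <- faGBLUP:::denseSetup(md)
  th <- faGBLUP:::startingValues(md)$theta
  ev <- faGBLUP:::denseEval(md, sde, th, needP = TRUE)
  g <- faGBLUP:::denseGradient(md, sde, th, ev)
  fd <- fdGradient(function(x) faGBLUP:::denseEval(md, sde, x)$value, th)
  expect_equal(g, fd, tolerance = 1e-5)
  # balanced instance: eigen engine
  cfg2 <- balancedConfig(20, exps, seed = 82)
  sim2 <- simulateDataset(cfg2, fa1Truth(exps))
  spec2 <- modelSpec("fa1", "fa1")
  md2 <- faGBLUP:::assembleModelData(sim2$phenotypes, sim2$K, spec2)
  see <- faGBLUP:::eigenSetup(md2)
  th2 <- faGBLUP:::startingValues(md2)$theta
  ev2 <- faGBLUP:::eigenEval(md2, see, th2)
  g2 <- faGBLUP:::eigenGradient(md2, see, th2, ev2)
  fd2 <- fdGradient(function(x) faGBLUP:::eigenEval(md2, see, x)$value, th2)
  expect_equal(g2, fd2, tolerance = 1e-5)
})

test_that("the oracle accepts an FA structure or its explicit covariance
           interchangeably and reduces to the iid closed form", {
  exps <- p2exps()
  cfg <- balancedConfig(15, exps, seed = 91)
  sim <- simulateDataset(cfg, fa1Truth(exps))
  spec <- modelSpec("fa1", "diag")
  fa <- faStructure(matrix(c(0.4, 0.3), 2, 1), c(0.05, 0.08))
  pars1 <- list(Ga = fa, Gabar = diag(c(0.1, 0.2)),
                design = numeric(0), residual = c("2009" = 0.3,
                                                  "2010" = 0.25))
  pars2 <- pars1
  pars2$Ga <- faCovariance(fa)
  ll1 <- loglikOracle(sim$phenotypes, sim$K, pars1, spec)
  ll2 <- loglikOracle(sim$phenotypes, sim$K, pars2, spec)
  expect_equal(ll1, ll2, tolerance = 1e-10)
  # all structural variances ~0: iid Gaussian REML log-likelihood
  s2 <- 0.37
  parsIID <- list(Ga = diag(1e-12, 2), Gabar = diag(1e-12, 2),
                  design = numeric(0),
                  residual = c("2009" = s2, "2010" = s2))
  specIID <- modelSpec("diag", "diag", residualGrouping = "none")
  parsIID$residual <- c(all = s2)
  llIID <- loglikOracle(sim$phenotypes, sim$K, parsIID, specIID)
  y <- sim$phenotypes$value
  X <- model.matrix(~ 0 + factor(sim$phenotypes$experiment,
                                 levels = unique(sim$phenotypes$experiment)))
  n <- length(y); t <- ncol(X)
  rss <- sum(lm.fit(X, y)$residuals^2)
  llClosed <- -0.5 * ((n - t) * log(2 * pi) + (n - t) * log(s2) +
                        rss / s2)
  expect_equal(llIID, llClosed, tolerance = 1e-6)
})

test_that("REML matches the balanced one-way ANOVA closed form with an
           identity kernel", {
  m <- 30; r <- 4
  set.seed(101)
  ids <- sprintf("L%02d", 1:m)
  Id <- diag(m); dimnames(Id) <- list(ids, ids)
  K <- relationshipMatrix(Id)
  g <- rnorm(m, 0, sqrt(0.5))
  data <- data.frame(
    experiment = "E1", year = "2009",
    line = rep(ids, each = r),
    value = 10 + rep(g, each = r) + rnorm(m * r, 0, sqrt(0.3)))
  spec <- modelSpec("diag", "none", residualGrouping = "none")
  fit <- remlFit(data, K, spec)
  expect_true(fit@converged)
  aov1 <- anova(lm(value ~ line, data))
  msb <- aov1["line", "Mean Sq"]; mse <- aov1["Residuals", "Mean Sq"]
  expect_equal(unname(fit@residualVariances), mse, tolerance = 1e-5)
  expect_equal(unname(diag(fit@Ga)), (msb - mse) / r, tolerance = 1e-4)
})

test_that("fixed-parameter limits of the BLUPs behave as theory says", {
  exps <- p2exps()
  cfg <- balancedConfig(15, exps, seed = 111)
  sim <- simulateDataset(cfg, fa1Truth(exps))
  spec <- modelSpec("diag", "diag", residualGrouping = "none")
  md <- faGBLUP:::assembleModelData(sim$phenotypes, sim$K, spec)
  sv <- faGBLUP:::startingValues(md)
  # additive variance -> 0: additive BLUPs -> 0
  th <- sv$theta
  th[1:2] <- log(1e-12)
  fit0 <- remlFit(sim$phenotypes, sim$K, spec, maxit = 0, start = th)
  expect_lt(max(abs(geneticSolutions(fit0)$ua)), 1e-9)
  # identity kernel and equal variances: the two components get equal BLUPs
  idm <- diag(15)
  dimnames(idm) <- list(lineIds(sim$K), lineIds(sim$K))
  Kid <- relationshipMatrix(idm)
  thEq <- sv$theta
  thEq[3:4] <- thEq[1:2]
  fitEq <- remlFit(sim$phenotypes, Kid, spec, maxit = 0, start = thEq)
  expect_equal(geneticSolutions(fitEq)$ua, geneticSolutions(fitEq)$uabar,
               tolerance = 1e-10)
})

test_that("BLUP solutions and PEV blocks match the dense
           mixed-model-equation oracle", {
  inst <- randomSmallInstance(7)
  fit <- remlFit(inst$data, inst$K, inst$spec)
  vc <- varianceComponents(fit)
  orc <- mmeOracle(inst$data, inst$K, inst$spec, vc)
  expect_equal(fit@solutions$ua[orc$obsLines, ], orc$ua,
               tolerance = 1e-7)
  if (!is.null(orc$uabar))
    expect_equal(fit@solutions$uabar[orc$obsLines, ], orc$uabar,
                 tolerance = 1e-7)
  for (j in c(1, fit@internals$p)) {
    expect_equal(unname(pevBlock(fit, j, "gebv")),
                 unname(mmePevBlock(orc, j, "gebv")), tolerance = 1e-7)
    expect_equal(unname(pevBlock(fit, j, "gv")),
                 unname(mmePevBlock(orc, j, "gv")), tolerance = 1e-7)
  }
})

test_that("PEV of additive BLUPs never exceeds the prior variance
           (shrinkage bound)", {
  exps <- p4exps()
  cfg <- balancedConfig(30, exps, seed = 121)
  sim <- simulateDataset(cfg, fa1Truth(exps))
  fit <- remlFit(sim$phenotypes, sim$K, modelSpec("fa1", "fa1"))
  Kd <- diag(kinship(sim$K))[fit@observedLines]
  for (j in seq_along(fit@experiments)) {
    pev <- diag(pevBlock(fit, j, "gebv"))
    prior <- fit@Ga[j, j] * Kd
    expect_true(all(pev <= prior + 1e-8))
  }
})

test_that("data simulated without genetic signal yields near-zero genetic
           variance estimates", {
  exps <- p4exps()
  cfg <- simulationConfig(nLines = 200, nMarkers = 400, experiments = exps,
                          fieldReps = 2, labReplicationRate = 1,
                          missingRate = 0, seed = 131)
  sim <- simulateDataset(cfg, nullTruth(exps))
  fit <- remlFit(sim$phenotypes, sim$K,
                 modelSpec("diag", "diag", residualGrouping = "none"))
  resid <- mean(fit@residualVariances)
  expect_lt(mean(diag(fit@Ga)), 0.05 * resid)
  expect_lt(mean(diag(fit@Gabar)), 0.05 * resid)
})

test_that("lines absent from the phenotype records still receive genomic
           GEBV predictions but zero residual genetic BLUPs", {
  exps <- p2exps()
  cfg <- balancedConfig(25, exps, seed = 141)
  sim <- simulateDataset(cfg, fa1Truth(exps))
  drop <- lineIds(sim$K)[1:5]
  sub <- sim$phenotypes[!(sim$phenotypes$line %in% drop), ]
  fit <- remlFit(sub, sim$K, modelSpec("fa1", "fa1"))
  sol <- geneticSolutions(fit)
  expect_true(all(abs(sol$ua[drop, ]) > 0))
  expect_true(all(sol$uabar[drop, ] == 0))
  expect_identical(nrow(sol$ua), 25L)
  # data lines missing from K are rejected up front
  bad <- sub
  bad$line[1] <- "UNKNOWN"
  expect_error(remlFit(bad, sim$K, modelSpec("fa1", "fa1")),
               class = "faGBLUP_data_error")
})
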