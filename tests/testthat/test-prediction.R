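fitSmall <- local({
  value <- NULL
  function() {
    if (is.null(value)) {
      exps <- p4exps()
      cfg <- balancedConfig(40, exps, seed = 151)
      sim <- simulateDataset(cfg, defaultTrueParameters(
        exps, additiveVar = 0.3, residualGeneticVar = 0.2))
      value <<- list(sim = sim,
                     fit = remlFit(sim$phenotypes, sim$K,
                                   modelSpec("fa1", "fa1")))
    }
    value
  }
})

test_that("GEBV and GV tables satisfy their defining identities", {
  fs <- fitSmall()
  fit <- fs$fit
  clusters <- clusterEnvironments(envCorrelation(fit, "total"))$labels
  gv <- extractGV(fit, clusters)
  tab <- geneticValuesTable(gv)
  sol <- geneticSolutions(fit)
  m <- length(lineIds(fit)); p <- length(fit@experiments)
  expect_identical(nrow(tab), m * p)
  # gv - gebv reproduces the residual genetic BLUP exactly
  expect_equal(tab$gv - tab$gebv,
               as.vector(sol$uabar), tolerance = 1e-12)
  expect_equal(tab$gebv, as.vector(sol$ua), tolerance = 1e-12)
  # cluster means are arithmetic means over member experiments
  cm <- geneticValuesTable(gv, "clusterMeans")
  cl1 <- names(clusters)[clusters == clusters[1]]
  l1 <- lineIds(fit)[3]
  expect_equal(cm$gebv[cm$line == l1 & cm$cluster == clusters[1]],
               mean(sol$ua[l1, cl1]))
  expect_equal(cm$gv[cm$line == l1 & cm$cluster == "overall"],
               mean(sol$ua[l1, ] + sol$uabar[l1, ]))
})

test_that("GEBVs recover simulated additive effects and GVs track total
           genetic values when residual genetic variance dominates", {
  exps <- p4exps()
  cfg <- balancedConfig(150, exps, seed = 161, nMarkers = 400)
  truth <- fa1Truth(exps, addVar = 0.45, resVar = 0.5,
                    residualVar = 0.25)
  sim <- simulateDataset(cfg, truth)
  fit <- remlFit(sim$phenotypes, sim$K, modelSpec("fa1", "fa1"))
  sol <- geneticSolutions(fit)
  uaTrue <- sim$genetic$ua
  gTrue <- sim$genetic$ua + sim$genetic$uabar
  corGEBV <- cor(as.vector(sol$ua), as.vector(uaTrue))
  expect_gt(corGEBV, 0.3)
  # total genotypic BLUPs track total genetic values better than the
  # additive part alone when residual genetic variance dominates
  gvHat <- sol$ua + sol$uabar
  expect_gt(cor(as.vector(gvHat), as.vector(gTrue)),
            cor(as.vector(sol$ua), as.vector(gTrue)))
})

test_that("envCorrelation converts fitted covariances per component", {
  fs <- fitSmall()
  fit <- fs$fit
  for (comp in c("additive", "residual", "total")) {
    C <- envCorrelation(fit, comp)
    expect_equal(diag(C), rep(1, 4), ignore_attr = TRUE)
    expect_true(all(C >= -1 - 1e-12 & C <= 1 + 1e-12))
  }
  G <- fit@Ga + fit@Gabar
  Cslow <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    Cslow[i, j] <- G[i, j] / sqrt(G[i, i] * G[j, j])
  expect_equal(unname(envCorrelation(fit, "total")), Cslow,
               tolerance = 1e-12)
  # rank-1 equal loadings: all correlations 1
  f2 <- fit
  f2@Ga <- faCovariance(faStructure(matrix(0.5, 4, 1), rep(0, 4)))
  dimnames(f2@Ga) <- dimnames(fit@Ga)
  expect_true(all(abs(envCorrelation(f2, "additive") - 1) < 1e-12))
})

test_that("clusterEnvironments matches a naive agglomerative oracle and
           recovers planted blocks", {
  # planted two-block correlation structure
  corr <- matrix(0.1, 4, 4)
  corr[1:2, 1:2] <- 0.9; corr[3:4, 3:4] <- 0.9
  diag(corr) <- 1
  dimnames(corr) <- list(letters[1:4], letters[1:4])
  cl <- clusterEnvironments(corr, nClusters = 2)
  expect_true(samePartition(cl$labels, c(1, 1, 2, 2)))
  # p = 2: single merge at 1 - corr
  c2 <- matrix(c(1, 0.6, 0.6, 1), 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  cl2 <- clusterEnvironments(c2, nClusters = 2)
  expect_equal(cl2$heights, 0.4, tolerance = 1e-12)
  # random PSD correlation vs the O(p^3) oracle, all linkages
  set.seed(9)
  A <- matrix(rnorm(36), 6)
  R <- cov2cor(tcrossprod(A) + diag(6))
  dimnames(R) <- list(LETTERS[1:6], LETTERS[1:6])
  for (lk in c("average", "complete", "single")) {
    cl6 <- clusterEnvironments(R, nClusters = 3, linkage = lk)
    orc <- naiveAgglomerative(1 - R, k = 3, linkage = lk)
    expect_equal(cl6$heights, orc$heights, tolerance = 1e-10)
    expect_true(samePartition(cl6$labels, orc$labels))
  }
  expect_error(clusterEnvironments(corr, nClusters = 9),
               class = "faGBLUP_cluster_error")
})

test_that("appev equals the brute-force mean over line pairs", {
  expect_equal(appev(matrix(0, 5, 5)), 0)
  expect_equal(appev(diag(0.3, 7)), 0.6)     # c * I gives 2c
  set.seed(10)
  A <- matrix(rnorm(36), 6)
  pev <- tcrossprod(A) / 6
  acc <- 0; np <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    acc <- acc + pev[i, i] + pev[j, j] - 2 * pev[i, j]
    np <- np + 1
  }
  expect_equal(appev(pev), acc / np, tolerance = 1e-12)
  expect_error(appev(matrix(0, 2, 3)), class = "faGBLUP_pred_error")
})

test_that("generalized heritabilities follow 1 - APPEV / (2 sigma^2) with
           boundary behavior and warnings", {
  expect_equal(as.numeric(heritabilityBroad(0, 0.2, 0.3)), 1)
  expect_equal(as.numeric(heritabilityBroad(2 * 0.5, 0.2, 0.3)), 0)
  expect_equal(as.numeric(heritabilityNarrow(0, 0.2)), 1)
  expect_equal(as.numeric(heritabilityNarrow(0.4, 0.2)), 0)
  expect_warning(h <- heritabilityBroad(1.5, 0.2, 0.3), "outside")
  expect_equal(attr(h, "clipped"), 0)
  expect_error(heritabilityBroad(0.1, 0, 0), class = "faGBLUP_pred_error")
  # balanced replicated design with identity kernel: H tracks the
  # classical r-replicate line-mean heritability
  m <- 60; r <- 3
  set.seed(171)
  ids <- sprintf("L%02d", 1:m)
  Id <- diag(m); dimnames(Id) <- list(ids, ids)
  s2g <- 0.5; s2e <- 0.4
  data <- data.frame(
    experiment = "E1", year = "2009", line = rep(ids, each = r),
    value = 5 + rep(rnorm(m, 0, sqrt(s2g)), each = r) +
      rnorm(m * r, 0, sqrt(s2e)))
  fit <- remlFit(data, relationshipMatrix(Id),
                 modelSpec("diag", "none", residualGrouping = "none"))
  H <- heritabilityBroad(appev(pevBlock(fit, 1, "gv")),
                         fit@Ga[1, 1], 0)
  sg <- fit@Ga[1, 1]; se <- fit@residualVariances[[1]]
  expect_equal(as.numeric(H), sg / (sg + se / r), tolerance = 0.05)
})

test_that("cluster-level variances average the pairwise covariances", {
  fs <- fitSmall()
  fit <- fs$fit
  exps <- fit@experiments
  clusters <- setNames(c("A", "A", "A", "B"), exps)
  cv <- suppressWarnings(clusterVariances(fit, clusters))
  mem <- exps[1:3]
  off <- fit@Ga[mem, mem][row(diag(3)) != col(diag(3))]
  expect_equal(cv$sigma2_a[cv$cluster == "A"], mean(off))
  # singleton falls back to the experiment's own variance with a warning
  w <- testthat::capture_warnings(
    cvB <- clusterVariances(fit, clusters))
  expect_match(w, "singleton", all = FALSE)
  expect_equal(cvB$sigma2_a[cvB$cluster == "B"], fit@Ga[4, 4])
  # constant off-diagonal covariance: cluster variance equals it
  f2 <- fit
  G <- matrix(0.07, 4, 4); diag(G) <- 0.2
  dimnames(G) <- dimnames(fit@Ga)
  f2@Ga <- G
  cv2 <- suppressWarnings(clusterVariances(f2, clusters))
  expect_equal(cv2$sigma2_a[cv2$cluster == "A"], 0.07)
  # two experiments: the single pairwise covariance
  cl2 <- setNames(c("X", "X", "Y", "Y"), exps)
  cv3 <- clusterVariances(f2, cl2)
  expect_equal(cv3$sigma2_a[cv3$cluster == "X"], 0.07)
  # includeDiagonal switch averages the full block
  cv4 <- clusterVariances(f2, cl2, includeDiagonal = TRUE)
  expect_equal(cv4$sigma2_a[cv4$cluster == "X"], mean(G[1:2, 1:2]))
})

test_that("proportionAdditive partitions the genetic variance", {
  expect_equal(proportionAdditive(0.3, 0), 1)
  expect_equal(round(proportionAdditive(0.00824, 0.01537), 4), 0.349)
  expect_error(proportionAdditive(0, 0), class = "faGBLUP_pred_error")
})

test_that("heritabilityTable is internally consistent across levels", {
  fs <- fitSmall()
  fit <- fs$fit
  clusters <- clusterEnvironments(envCorrelation(fit, "total"))$labels
  # a cluster-averaged additive covariance can be nonpositive on a small
  # fit; that row's h2 is NA with a warning
  ht <- suppressWarnings(heritabilityTable(fit, clusters))
  expect_setequal(ht$unit[ht$level == "experiment"], fit@experiments)
  expect_true("overall" %in% ht$unit)
  fe <- ht[ht$level == "experiment", ]
  expect_equal(fe$prop_additive,
               fe$sigma2_a / (fe$sigma2_a + fe$sigma2_abar))
  expect_equal(fe$H, 1 - fe$appev_gv / (2 * (fe$sigma2_a + fe$sigma2_abar)))
  expect_equal(fe$h2, 1 - fe$appev_gebv / (2 * fe$sigma2_a))
})

test_that("environment clustering recovers planted groups across
           replicate simulations", {
  exps <- p4exps()
  deficit <- exps$irrigation == "RFD"
  hits <- 0
  for (i in 1:10) {
    cfg <- balancedConfig(100, exps, seed = 700 + i, nMarkers = 300)
    sim <- simulateDataset(cfg, plantedTwoClusterTruth(
      exps, deficit, residualVar = 0.05))
    fit <- remlFit(sim$phenotypes, sim$K, modelSpec("fa2", "fa2"))
    cl <- clusterEnvironments(envCorrelation(fit, "total"))$labels
    hits <- hits + samePartition(cl[exps$experiment],
                                 ifelse(deficit, 1, 2))
  }
  expect_gte(hits, 9)
})
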