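test_that("simulateMarkers respects the configured dimensions, MAF range
           and seed determinism", {
  cfg <- simulationConfig(nLines = 100, nMarkers = 500,
                          mafRange = c(0.05, 0.5), missingRate = 0,
                          seed = 11)
  mk <- simulateMarkers(cfg)
  expect_identical(dim(dosages(mk)), c(100L, 500L))
  q <- colMeans(dosages(mk)) / 2
  maf <- pmin(q, 1 - q)
  # sampling MAF within the configured window up to binomial noise at m=100
  expect_true(all(maf > 0.05 - 3 * sqrt(0.05 * 0.95 / 200)))
  mk2 <- simulateMarkers(cfg)
  expect_identical(dosages(mk), dosages(mk2))
  # law of large numbers at q = 0.5: mean dosage -> 1
  big <- simulateMarkers(simulationConfig(nLines = 5000, nMarkers = 40,
                                          mafRange = c(0.5, 0.5),
                                          missingRate = 0, seed = 2))
  expect_true(all(abs(colMeans(dosages(big)) - 1) <
                    4 * sqrt(0.5 / 5000) + 1e-12))
})

test_that("filterMarkers removes monomorphic, low-MAF and duplicated
           markers with an accurate report", {
  # monomorphic column removed by definition
  d <- cbind(mono = rep(0, 100), keep = rep(c(0, 1, 2), length.out = 100))
  rownames(d) <- sprintf("L%03d", 1:100)
  out <- filterMarkers(markerMatrix(d))
  expect_identical(out$report$monomorphic, 1L)
  expect_identical(markerIds(out$markers), "keep")

  # boundary: MAF 0.04 removed, MAF exactly 0.05 retained
  d2 <- cbind(low = c(rep(1, 8), rep(0, 92)),     # minor count 8 -> 0.04
              edge = c(rep(1, 10), rep(0, 90)),   # minor count 10 -> 0.05
              keep = rep(c(0, 2), 50))
  rownames(d2) <- sprintf("L%03d", 1:100)
  out2 <- filterMarkers(markerMatrix(d2), mafMin = 0.05)
  expect_identical(sort(markerIds(out2$markers)), c("edge", "keep"))
  expect_identical(out2$report$low_maf, 1L)

  # planted removal classes on a random fixture, recounted independently
  set.seed(3)
  m <- 50
  base <- matrix(rbinom(m * 185, 2, runif(185, 0.25, 0.5)), m, 185)
  dup <- base[, 1:5]                                    # 5 duplicates
  mono <- matrix(rep(c(0, 1, 2), each = m), m, 3)       # 3 monomorphic
  low <- matrix(rbinom(m * 7, 2, 0.02), m, 7)           # 7 below MAF
  low[1, ] <- pmax(low[1, ], 1)                         # not monomorphic
  d3 <- cbind(base, dup, mono, low)
  colnames(d3) <- sprintf("M%03d", seq_len(ncol(d3)))
  rownames(d3) <- sprintf("L%03d", seq_len(m))
  stopifnot(ncol(d3) == 200)
  out3 <- filterMarkers(markerMatrix(d3), mafMin = 0.05)
  # independent recount with straightforward loops
  isMono <- apply(d3, 2, function(x) length(unique(x)) == 1)
  q <- colMeans(d3) / 2
  isLow <- !isMono & pmin(q, 1 - q) < 0.05
  keyOf <- apply(d3, 2, paste, collapse = ",")
  isDup <- rep(FALSE, ncol(d3))
  seen <- character(0)
  for (j in which(!isMono & !isLow)) {
    if (keyOf[j] %in% seen) isDup[j] <- TRUE else seen <- c(seen, keyOf[j])
  }
  expect_identical(out3$report$monomorphic, sum(isMono))
  expect_identical(out3$report$low_maf, sum(isLow))
  expect_identical(out3$report$duplicated, sum(isDup))
  expect_identical(out3$report$retained,
                   ncol(d3) - sum(isMono) - sum(isLow) - sum(isDup))

  # removing everything is an explicit error
  allmono <- markerMatrix(matrix(0, 10, 3, dimnames = list(
    sprintf("L%02d", 1:10), sprintf("M%d", 1:3))))
  expect_error(filterMarkers(allmono), class = "faGBLUP_qc_error")
})

test_that("imputeMissing fills missing calls with marker means and
           preserves observed values", {
  d <- matrix(c(0, 2, NA, 1, 1, 1), 3, 2,
              dimnames = list(c("a", "b", "c"), c("m1", "m2")))
  imp <- imputeMissing(markerMatrix(d))
  expect_equal(dosages(imp)[3, 1], 1.0)       # mean of 0 and 2
  expect_equal(dosages(imp)[1:2, 1], c(a = 0, b = 2))
  # identity on complete data
  full <- markerMatrix(matrix(c(0, 1, 2, 2), 2, 2, dimnames = list(
    c("a", "b"), c("m1", "m2"))))
  expect_equal(dosages(imputeMissing(full)), dosages(full))
  # column means unchanged by mean imputation
  set.seed(5)
  d2 <- matrix(rbinom(600, 2, 0.3), 30, 20,
               dimnames = list(sprintf("L%02d", 1:30),
                               sprintf("M%02d", 1:20)))
  d2na <- d2
  d2na[sample(length(d2), 30)] <- NA
  imp2 <- imputeMissing(markerMatrix(d2na))
  expect_equal(colMeans(dosages(imp2)),
               colMeans(d2na, na.rm = TRUE), tolerance = 1e-12)
  # fully-missing marker instructs filtering first
  dbad <- matrix(c(1, 0, NA, NA), 2, 2, dimnames = list(
    c("a", "b"), c("m1", "m2")))
  expect_error(imputeMissing(markerMatrix(dbad)),
               class = "faGBLUP_impute_error")
})

test_that("computeGRM builds the scaled centered cross-product matrix", {
  # identical genotypes: off-diagonal equals both diagonals (no ridge)
  d <- rbind(a = c(0, 1, 2, 1), b = c(0, 1, 2, 1), c = c(2, 1, 0, 1))
  colnames(d) <- sprintf("M%d", 1:4)
  K <- computeGRM(markerMatrix(d), ridge = 0)
  v <- kinship(K)
  expect_equal(v["a", "b"], v["a", "a"])
  expect_equal(v["a", "b"], v["b", "b"])
  # scaling: mean diagonal exactly 1 before ridge
  set.seed(8)
  d2 <- matrix(rbinom(20 * 100, 2, runif(100, 0.1, 0.5)), 20, 100,
               dimnames = list(sprintf("L%02d", 1:20),
                               sprintf("M%03d", 1:100)))
  K2 <- computeGRM(markerMatrix(d2), ridge = 0)
  expect_equal(mean(diag(kinship(K2))), 1, tolerance = 1e-10)
  # brute-force double-loop oracle
  q <- colMeans(d2) / 2
  W <- sweep(d2, 2, 2 * q)
  cdenom <- sum(2 * q * (1 - q))
  G0 <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20)
    G0[i, j] <- sum(W[i, ] * W[j, ]) / cdenom
  G0 <- G0 / mean(diag(G0))
  expect_equal(unname(kinship(K2)), G0, tolerance = 1e-10)
  # monomorphic-only input has a zero denominator
  dm <- matrix(1, 5, 4, dimnames = list(sprintf("L%d", 1:5),
                                        sprintf("M%d", 1:4)))
  expect_error(computeGRM(markerMatrix(dm, imputed = TRUE)),
               class = "faGBLUP_grm_error")
})

test_that("the QC -> impute -> GRM pipeline is invariant to marker order
           and allele-label flips", {
  set.seed(13)
  d <- matrix(rbinom(25 * 120, 2, runif(120, 0.1, 0.5)), 25, 120,
              dimnames = list(sprintf("L%02d", 1:25),
                              sprintf("M%03d", 1:120)))
  d[sample(length(d), 40)] <- NA
  run <- function(dd) {
    flt <- filterMarkers(markerMatrix(dd))
    kinship(computeGRM(imputeMissing(flt$markers)))
  }
  K1 <- run(d)
  K2 <- run(d[, sample(ncol(d))])
  expect_equal(K1, K2, tolerance = 1e-12)
  dflip <- d
  flip <- sample(ncol(d), 30)
  dflip[, flip] <- 2 - dflip[, flip]
  expect_equal(K1, run(dflip), tolerance = 1e-12)
})

test_that("off-diagonal relatedness of unrelated lines shrinks like
           1/sqrt(n_markers)", {
  offsd <- function(nm, seed) {
    mk <- simulateMarkers(simulationConfig(nLines = 40, nMarkers = nm,
                                           missingRate = 0, seed = seed))
    v <- kinship(computeGRM(imputeMissing(mk)))
    sd(v[upper.tri(v)])
  }
  r <- mean(sapply(1:4, function(s) offsd(100, s) / offsd(400, s)))
  expect_gt(r, 1.6)
  expect_lt(r, 2.4)
})

test_that("pcaGRM matches a full eigendecomposition and handles edge
           spectra", {
  ids <- sprintf("L%02d", 1:12)
  Id <- diag(12)
  dimnames(Id) <- list(ids, ids)
  Ki <- relationshipMatrix(Id)
  pc <- pcaGRM(Ki, 2)
  expect_equal(pc$cumulativeProportion[2], 2 / 12, tolerance = 1e-12)
  # rank-1 matrix: first component carries everything
  v <- matrix(rnorm(12), dimnames = list(ids, NULL))
  V1 <- tcrossprod(v) + diag(1e-9, 12)
  dimnames(V1) <- list(ids, ids)
  K1 <- relationshipMatrix(V1)
  expect_equal(pcaGRM(K1, 1)$proportion[1], 1, tolerance = 1e-6)
  # random PSD fixture vs brute-force spectrum
  set.seed(4)
  A <- matrix(rnorm(144), 12)
  Kr <- relationshipMatrix((tcrossprod(A) / 12) |>
                             `dimnames<-`(list(ids, ids)))
  pc3 <- pcaGRM(Kr, 3)
  ev <- eigen(kinship(Kr), symmetric = TRUE)$values
  expect_equal(pc3$proportion, (ev / sum(ev))[1:3], tolerance = 1e-10)
  expect_error(pcaGRM(Ki, 13), class = "faGBLUP_pca_error")
})
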