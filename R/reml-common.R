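## Shared REML machinery: model-frame assembly, parameter packing,
## starting values. The two computational engines (dense marginal
## covariance; eigendecomposition of K for balanced data) plug into this.

requiredPhenotypeColumns <- c("experiment", "line", "value")

# Validate the phenotype table against K and the spec; build the model
# frame used by both engines.
assembleModelData <- function(data, K, spec) {
  stopifnot(is.data.frame(data), is(K, "RelationshipMatrix"),
            is(spec, "ModelSpec"))
  miss <- setdiff(requiredPhenotypeColumns, names(data))
  if (length(miss))
    stopf("faGBLUP_data_error", "phenotype table lacks column(s): %s",
          paste(miss, collapse = ", "))
  linesAll <- lineIds(K)
  unknown <- setdiff(unique(as.character(data$line)), linesAll)
  if (length(unknown))
    stopf("faGBLUP_data_error",
          "%d line(s) in the data are absent from K (e.g. %s)",
          length(unknown), unknown[1])
  expLevels <- experimentLevels(data$experiment)
  p <- length(expLevels)
  fa <- parseStructure(spec@additive)
  fb <- parseStructure(spec@residualGenetic)
  for (st in list(fa, fb))
    if (st$type == "fa" && st$k > p - 1)
      stopf("faGBLUP_spec_error",
            "FA order k = %d requires at least k + 1 = %d environments",
            st$k, st$k + 1)

  jidx <- match(as.character(data$experiment), expLevels)
  obsLines <- linesAll[linesAll %in% unique(as.character(data$line))]
  iidx <- match(as.character(data$line), obsLines)
  y <- as.numeric(data$value)
  n <- length(y)

  ## Fixed effects: experiment cell means plus any further declared factors.
  extra <- setdiff(spec@fixed, "experiment")
  df <- data.frame(experiment = factor(as.character(data$experiment),
                                       levels = expLevels))
  form <- "~ 0 + experiment"
  for (f in extra) {
    if (!f %in% names(data))
      stopf("faGBLUP_data_error", "fixed factor '%s' not in data", f)
    df[[f]] <- factor(as.character(data[[f]]))
    form <- paste(form, "+", f)
  }
  X <- if (p == 1 && !length(extra)) {
    matrix(1, n, 1, dimnames = list(NULL, paste0("experiment",
                                                 expLevels)))
  } else {
    stats::model.matrix(stats::as.formula(form), df)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("faGBLUP_data_error",
          "singular fixed-effect design; aliased column(s): %s",
          paste(aliased, collapse = ", "))
  }

  ## Design random terms. Each declared factor is nested within its scope
  ## column; under "single" grouping it carries one variance, under
  ## "scope" grouping one variance per scope level.
  designTerms <- list()
  for (f in spec@designRandom) {
    if (!f %in% names(data))
      stopf("faGBLUP_data_error", "design factor '%s' not in data", f)
    scopeCol <- if (f %in% names(spec@designNesting))
      spec@designNesting[[f]] else "experiment"
    if (!scopeCol %in% names(data))
      stopf("faGBLUP_data_error",
            "nesting column '%s' for factor '%s' not in data", scopeCol, f)
    lev <- interaction(data[[scopeCol]], data[[f]], drop = TRUE)
    if (spec@varianceGrouping == "single") {
      designTerms[[f]] <- list(id = f, lev = as.integer(lev),
                               nlev = nlevels(lev))
    } else {
      for (s in unique(as.character(data[[scopeCol]]))) {
        sel <- as.character(data[[scopeCol]]) == s
        l2 <- rep(NA_integer_, n)
        sub <- droplevels(lev[sel])
        l2[sel] <- as.integer(sub)
        designTerms[[paste(f, s, sep = ":")]] <-
          list(id = paste(f, s, sep = ":"), lev = l2, nlev = nlevels(sub))
      }
    }
  }

  ## Heterogeneous residual grouping.
  if (spec@residualGrouping == "none" ||
      !spec@residualGrouping %in% names(data)) {
    rgroupLevels <- "all"
    rgroup <- rep(1L, n)
  } else {
    rg <- factor(as.character(data[[spec@residualGrouping]]))
    rgroupLevels <- levels(rg)
    rgroup <- as.integer(rg)
  }

  list(y = y, n = n, X = X, t = ncol(X),
       expLevels = expLevels, p = p, jidx = jidx,
       linesAll = linesAll, obsLines = obsLines,
       obsIdx = match(obsLines, linesAll), iidx = iidx,
       Kall = kinship(K),
       designTerms = designTerms,
       rgroup = rgroup, rgroupLevels = rgroupLevels,
       spec = spec)
}

## Whole-model parameter packing ---------------------------------------------

buildParIndex <- function(md) {
  p <- md$p
  spec <- md$spec
  nA <- structureParIndex(spec@additive, p)$n
  nB <- structureParIndex(spec@residualGenetic, p)$n
  nD <- length(md$designTerms)
  nR <- length(md$rgroupLevels)
  list(p = p,
       addSeg = seq_len(nA),
       resSeg = nA + seq_len(nB),
       designSeg = nA + nB + seq_len(nD),
       residSeg = nA + nB + nD + seq_len(nR),
       n = nA + nB + nD + nR)
}

# theta -> named component list.
unpackParams <- function(md, theta) {
  pi <- buildParIndex(md)
  spec <- md$spec
  a <- unpackStructure(spec@additive, md$p, theta[pi$addSeg])
  b <- unpackStructure(spec@residualGenetic, md$p, theta[pi$resSeg])
  dv <- exp(theta[pi$designSeg])
  names(dv) <- names(md$designTerms)
  rv <- exp(theta[pi$residSeg])
  names(rv) <- md$rgroupLevels
  list(Ga = a$G, Gab = b$G, faA = a$fa, faB = b$fa,
       design = dv, resid = rv)
}

# Deterministic starting values from per-experiment phenotype variances.
startingValues <- function(md) {
  p <- md$p
  spec <- md$spec
  v <- vapply(seq_len(p), function(j) {
    yj <- md$y[md$jidx == j]
    if (length(yj) > 1) stats::var(yj) else 1
  }, numeric(1))
  v <- pmax(v, 1e-8)
  vbar <- mean(v)
  nD <- length(md$designTerms)
  shares <- c(gen = 0.25, design = if (nD > 0) 0.15 else 0,
              resid = if (nD > 0) 0.35 else 0.5)

  packStructure <- function(s, vv) {
    st <- parseStructure(s)
    if (st$type == "none") return(numeric(0))
    if (st$type == "diag") return(log(shares["gen"] * vv))
    k <- st$k
    L <- matrix(0, p, k)
    L[, 1] <- sqrt(0.7 * shares["gen"] * vv)
    if (k >= 2)
      for (cdx in 2:k)
        L[cdx:p, cdx] <- 0.15 * sqrt(vv[cdx:p]) * (-1)^(seq.int(cdx, p))
    idx <- structureParIndex(s, p)
    c(L[idx$free], log(0.3 * shares["gen"] * vv))
  }
  thetaA <- packStructure(spec@additive, v)
  thetaB <- packStructure(spec@residualGenetic, v)
  thetaD <- rep(log(shares["design"] * vbar / max(nD, 1) + 1e-10), nD)
  rv <- vapply(seq_along(md$rgroupLevels), function(g) {
    yg <- md$y[md$rgroup == g]
    max(stats::var(yg), 1e-8)
  }, numeric(1))
  thetaR <- log(pmax(shares["resid"] * rv, 1e-9))
  theta <- c(thetaA, thetaB, thetaD, thetaR)

  ## Box constraints: loadings free within a generous window, log-variances
  ## bounded below (psi floor) and above.
  pi <- buildParIndex(md)
  lower <- rep(-Inf, pi$n); upper <- rep(Inf, pi$n)
  isLoad <- rep(FALSE, pi$n)
  markStructure <- function(seg, s) {
    st <- parseStructure(s)
    if (st$type == "fa") {
      nfree <- length(structureParIndex(s, p)$free)
      isLoad[seg[seq_len(nfree)]] <<- TRUE
    }
  }
  markStructure(pi$addSeg, spec@additive)
  markStructure(pi$resSeg, spec@residualGenetic)
  lb <- log(1e-8 * max(vbar, 1e-6))
  ub <- log(1e5 * max(vbar, 1e-6))
  lower[!isLoad] <- lb; upper[!isLoad] <- ub
  lim <- 50 * sqrt(max(v))
  lower[isLoad] <- -lim; upper[isLoad] <- lim
  list(theta = theta, lower = lower, upper = upper)
}

## Warm starts ---------------------------------------------------------------

# Best rank-k factor approximation of a covariance matrix, rotated so the
# loading matrix is lower-trapezoidal (the identifiability constraint).
faFromCovariance <- function(G, k, psiFloor) {
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  ev <- pmax(e$values[seq_len(k)], psiFloor)
  L <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev), nrow = k)
  if (k >= 2) {
    qrt <- qr(t(L))
    L <- t(qr.R(qrt))     # same LL', upper triangle zero
  }
  psi <- pmax(diag(G) - rowSums(L^2), psiFloor)
  list(L = L, psi = psi)
}

# Build a starting parameter vector for `md` from a previously fitted
# (usually simpler, nested) model sharing the same non-genetic terms.
warmStartTheta <- function(md, fromFit) {
  p <- md$p
  sv <- startingValues(md)
  floorv <- exp(min(sv$lower[is.finite(sv$lower)]))
  packFrom <- function(s, G, srcFa) {
    st <- parseStructure(s)
    if (st$type == "none") return(numeric(0))
    if (st$type == "diag") return(log(pmax(diag(G), floorv)))
    idx <- structureParIndex(s, p)
    if (!is.null(srcFa) && ncol(srcFa@loadings) == st$k)
      return(c(srcFa@loadings[idx$free],
               log(pmax(srcFa@specificVariances, floorv))))
    fa <- faFromCovariance(G, st$k, floorv)
    c(fa$L[idx$free], log(fa$psi))
  }
  theta <- c(packFrom(md$spec@additive, fromFit@Ga, fromFit@faAdditive),
             packFrom(md$spec@residualGenetic, fromFit@Gabar,
                      fromFit@faResidual),
             log(pmax(fromFit@designVariances, floorv)),
             log(pmax(fromFit@residualVariances, floorv)))
  if (length(theta) != length(sv$theta)) return(NULL)
  pmin(pmax(theta, sv$lower), sv$upper)
}
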