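## Dense-marginal-covariance REML engine. Handles arbitrary unbalanced
## two-phase designs by forming V = Zg (Ga x K) Zg' + Zg (Gab x I) Zg'
##   + sum_f sigma2_f Zf Zf' + R directly (n x n) and maximizing the REML
## log-likelihood with analytic gradients
##   d logL / d theta = -1/2 [ tr(P dV) - y'P dV P y ].

denseSetup <- function(md) {
  Ko <- md$Kall[md$obsIdx, md$obsIdx, drop = FALSE]
  Ka <- Ko[md$iidx, md$iidx, drop = FALSE]
  sameLine <- outer(md$iidx, md$iidx, "==") * 1
  designM <- lapply(md$designTerms, function(tm) {
    M <- outer(tm$lev, tm$lev, function(a, b) !is.na(a) & !is.na(b) & a == b)
    M * 1
  })
  jf <- factor(md$jidx, levels = seq_len(md$p))
  logdetXtX <- as.numeric(determinant(crossprod(md$X),
                                      logarithm = TRUE)$modulus)
  list(Ko = Ko, Ka = Ka, sameLine = sameLine, designM = designM, jf = jf,
       logdetXtX = logdetXtX)
}

denseBuildV <- function(md, setup, pars) {
  p <- md$p
  Gaj <- pars$Ga[md$jidx, md$jidx, drop = FALSE]
  Gbj <- pars$Gab[md$jidx, md$jidx, drop = FALSE]
  V <- Gaj * setup$Ka + Gbj * setup$sameLine
  for (i in seq_along(setup$designM))
    V <- V + pars$design[i] * setup$designM[[i]]
  diag(V) <- diag(V) + pars$resid[md$rgroup]
  V
}

# Evaluate the REML log-likelihood and retain the pieces the gradient and
# the BLUP extraction need. Returns NULL on a non-PD V.
denseEval <- function(md, setup, theta, needP = FALSE) {
  pars <- unpackParams(md, theta)
  V <- denseBuildV(md, setup, pars)
  cholV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cholV)) return(NULL)
  n <- md$n; X <- md$X; y <- md$y
  rhs <- cbind(y, X)
  Vinv1 <- backsolve(cholV, forwardsolve(t(cholV), rhs))
  ## one step of iterative refinement guards against ill-conditioned V
  ## (variance components collapsing toward their bounds)
  Vinv1 <- Vinv1 +
    backsolve(cholV, forwardsolve(t(cholV), rhs - V %*% Vinv1))
  Vinvy <- Vinv1[, 1]
  VinvX <- Vinv1[, -1, drop = FALSE]
  A <- crossprod(X, VinvX)
  cholA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(cholA)) return(NULL)
  Xty <- crossprod(X, Vinvy)
  beta <- backsolve(cholA, forwardsolve(t(cholA), Xty))
  beta <- beta +
    backsolve(cholA, forwardsolve(t(cholA), Xty - A %*% beta))
  Py <- Vinvy - VinvX %*% beta
  quad <- sum(y * Py)
  ll <- -0.5 * (logDetChol(cholV) + logDetChol(cholA) + quad +
                (n - md$t) * log(2 * pi) - setup$logdetXtX)
  out <- list(value = as.numeric(ll), pars = pars, cholV = cholV,
              cholA = cholA, beta = drop(beta), Py = drop(Py),
              VinvX = VinvX)
  if (needP) {
    Vinv <- chol2inv(cholV)
    Ainv <- chol2inv(cholA)
    out$Pmat <- Vinv - VinvX %*% Ainv %*% t(VinvX)
  }
  out
}

denseGradient <- function(md, setup, theta, ev) {
  if (is.null(ev$Pmat)) stop("gradient requires P")
  Cmat <- ev$Pmat - tcrossprod(ev$Py)
  p <- md$p
  pi <- buildParIndex(md)
  grad <- numeric(pi$n)

  aggByExperiment <- function(M) {
    a <- rowsum(M, setup$jf, reorder = TRUE)
    t(rowsum(t(a), setup$jf, reorder = TRUE))
  }
  spec <- md$spec
  if (length(pi$addSeg)) {
    AggK <- aggByExperiment(Cmat * setup$Ka)
    dGs <- structureDerivs(spec@additive, p, theta[pi$addSeg])
    grad[pi$addSeg] <- vapply(dGs, function(D) -0.5 * sum(AggK * D),
                              numeric(1))
  }
  if (length(pi$resSeg)) {
    AggI <- aggByExperiment(Cmat * setup$sameLine)
    dGs <- structureDerivs(spec@residualGenetic, p, theta[pi$resSeg])
    grad[pi$resSeg] <- vapply(dGs, function(D) -0.5 * sum(AggI * D),
                              numeric(1))
  }
  if (length(pi$designSeg))
    for (i in seq_along(setup$designM))
      grad[pi$designSeg[i]] <-
        -0.5 * ev$pars$design[i] * sum(Cmat * setup$designM[[i]])
  dC <- diag(Cmat)
  for (g in seq_along(md$rgroupLevels))
    grad[pi$residSeg[g]] <-
      -0.5 * ev$pars$resid[g] * sum(dC[md$rgroup == g])
  grad
}

# BLUP solutions for all lines of K plus the aggregated Z'Py cell matrix W.
denseBlup <- function(md, setup, ev) {
  mo <- length(md$obsLines)
  W <- matrix(0, mo, md$p,
              dimnames = list(md$obsLines, md$expLevels))
  cell <- cbind(md$iidx, md$jidx)
  for (r in seq_len(md$n)) W[cell[r, 1], cell[r, 2]] <-
    W[cell[r, 1], cell[r, 2]] + ev$Py[r]
  KW <- md$Kall[, md$obsIdx, drop = FALSE] %*% W
  ua <- KW %*% ev$pars$Ga
  uabar <- matrix(0, length(md$linesAll), md$p)
  uabar[md$obsIdx, ] <- W %*% ev$pars$Gab
  dimnames(ua) <- dimnames(uabar) <- list(md$linesAll, md$expLevels)
  list(ua = ua, uabar = uabar, W = W)
}

# PEV machinery: T = Z'PZ over observed cells, then
#   PEV(j,j') = G[j,j']-kernel - B_j T B_j'   (per component mix).
denseCellT <- function(md, ev) {
  cellv <- (md$jidx - 1L) * length(md$obsLines) + md$iidx
  cellsPresent <- sort(unique(cellv))
  Tm <- rowsum(t(rowsum(ev$Pmat, cellv, reorder = TRUE)), cellv,
               reorder = TRUE)
  iC <- (cellsPresent - 1) %% length(md$obsLines) + 1
  aC <- (cellsPresent - 1) %/% length(md$obsLines) + 1
  list(T = Tm, iC = iC, aC = aC)
}

# Cross-experiment PEV block over observed lines for the dense engine.
# type: "gv" uses Ga + Gab in both prior and projection; "gebv" uses Ga.
densePevBlock <- function(md, setup, ev, cellT, j, jp, type) {
  Ga <- ev$pars$Ga; Gab <- ev$pars$Gab
  useB <- type == "gv"
  Ko <- setup$Ko
  mo <- nrow(Ko)
  bmat <- function(jj) {
    B <- Ko[, cellT$iC, drop = FALSE] *
      rep(Ga[jj, cellT$aC], each = mo)
    if (useB) {
      idx <- cbind(cellT$iC, seq_along(cellT$iC))
      add <- Gab[jj, cellT$aC]
      B[idx] <- B[idx] + add
    }
    B
  }
  S0 <- Ga[j, jp] * Ko
  if (useB) S0 <- S0 + diag(Gab[j, jp], mo)
  Bj <- bmat(j)
  Bjp <- if (jp == j) Bj else bmat(jp)
  S0 - Bj %*% cellT$T %*% t(Bjp)
}
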