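# Independent verification oracles, deliberately written with different
# algebra than the package engines.

# Dense mixed-model-equations oracle: fixed-effect and BLUP solutions plus
# PEV blocks at given variance parameters, via the scaled Henderson system
# (u = S v with S = G^{1/2} and identity prior on v, which keeps the
# system well conditioned even when G is nearly singular):
#   C = [X'R-X  X'R-ZS; S'Z'R-X  S'Z'R-ZS + I], u_hat = S v_hat,
#   PEV(u) = S C^{vv} S'.
mmeOracle <- function(data, K, spec, pars) {
  md <- faGBLUP:::assembleModelData(data, K, spec)
  mo <- length(md$obsLines); p <- md$p; n <- md$n
  Ko <- md$Kall[md$obsIdx, md$obsIdx, drop = FALSE]
  Zg <- matrix(0, n, mo * p)
  Zg[cbind(seq_len(n), (md$jidx - 1) * mo + md$iidx)] <- 1
  symSqrt <- function(M) {
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  }
  Zlist <- list(); Slist <- list()
  if (spec@additive != "none") {
    Zlist$ua <- Zg
    Slist$ua <- kronecker(symSqrt(pars$Ga), symSqrt(Ko))
  }
  if (spec@residualGenetic != "none") {
    Zlist$uabar <- Zg
    Slist$uabar <- kronecker(symSqrt(pars$Gabar), diag(mo))
  }
  for (i in seq_along(md$designTerms)) {
    tm <- md$designTerms[[i]]
    Zf <- matrix(0, n, tm$nlev)
    ok <- !is.na(tm$lev)
    Zf[cbind(which(ok), tm$lev[ok])] <- 1
    Zlist[[tm$id]] <- Zf
    Slist[[tm$id]] <- diag(sqrt(pars$design[[i]]), tm$nlev)
  }
  ZS <- do.call(cbind, Map(function(Z, S) Z %*% S, Zlist, Slist))
  Rinvd <- 1 / pars$residual[md$rgroup]
  X <- md$X
  XtR <- t(X * Rinvd)
  WtR <- t(ZS * Rinvd)
  q <- ncol(ZS)
  C <- rbind(cbind(XtR %*% X, XtR %*% ZS),
             cbind(WtR %*% X, WtR %*% ZS + diag(q)))
  rhs <- c(XtR %*% md$y, WtR %*% md$y)
  sol <- solve(C, rhs)
  sol <- sol + solve(C, rhs - C %*% sol)   # iterative refinement
  t <- md$t
  Cinv <- solve(C)
  blocks <- list()
  off <- t
  for (nm in names(Zlist)) {
    blocks[[nm]] <- off + seq_len(ncol(Zlist[[nm]]))
    off <- off + ncol(Zlist[[nm]])
  }
  uhat <- function(nm) {
    if (is.null(blocks[[nm]])) return(NULL)
    drop(Slist[[nm]] %*% sol[blocks[[nm]]])
  }
  uaMat <- function(nm) {
    u <- uhat(nm)
    if (is.null(u)) return(NULL)
    matrix(u, mo, p, dimnames = list(md$obsLines, md$expLevels))
  }
  list(beta = sol[seq_len(t)], ua = uaMat("ua"), uabar = uaMat("uabar"),
       Cinv = Cinv, blocks = blocks, Slist = Slist, mo = mo, p = p,
       obsLines = md$obsLines, expLevels = md$expLevels)
}

# PEV block over observed lines at experiment j from the MME inverse
# (back-transformed from the scaled system).
mmePevBlock <- function(orc, j, type) {
  sel <- (j - 1) * orc$mo + seq_len(orc$mo)
  ia <- orc$blocks$ua
  Sa <- orc$Slist$ua
  pevA <- Sa %*% orc$Cinv[ia, ia] %*% t(Sa)
  if (type == "gebv") return(pevA[sel, sel])
  ib <- orc$blocks$uabar
  Sb <- orc$Slist$uabar
  pevB <- Sb %*% orc$Cinv[ib, ib] %*% t(Sb)
  pevAB <- Sa %*% orc$Cinv[ia, ib] %*% t(Sb)
  (pevA + pevB + pevAB + t(pevAB))[sel, sel]
}

# Naive O(p^3) agglomerative clustering oracle over a dissimilarity
# matrix; returns merge heights and the partition at k clusters.
naiveAgglomerative <- function(D, k = NULL,
                               linkage = c("average", "complete",
                                           "single")) {
  linkage <- match.arg(linkage)
  p <- nrow(D)
  clusters <- as.list(seq_len(p))
  heights <- numeric(0)
  partitions <- list()
  linkfun <- switch(linkage, average = mean, complete = max, single = min)
  while (length(clusters) > 1) {
    nc <- length(clusters)
    best <- c(Inf, NA, NA)
    for (a in seq_len(nc - 1)) for (b in (a + 1):nc) {
      dval <- linkfun(D[clusters[[a]], clusters[[b]]])
      if (dval < best[1]) best <- c(dval, a, b)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    partitions[[length(partitions) + 1]] <- clusters
  }
  out <- list(heights = heights)
  if (!is.null(k)) {
    part <- partitions[[p - k]]
    lab <- integer(p)
    for (i in seq_along(part)) lab[part[[i]]] <- i
    out$labels <- lab
  }
  out
}

# Are two labelings the same partition (up to label permutation)?
samePartition <- function(a, b) {
  canon <- function(x) {
    groups <- lapply(split(seq_along(x), x), sort)
    unname(groups[order(vapply(groups, min, numeric(1)))])
  }
  identical(canon(a), canon(b))
}

# Central finite-difference gradient.
fdGradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}
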