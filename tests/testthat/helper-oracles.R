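# Independent oracles used across tests. These deliberately avoid the
# package's pruning path: brute-force enumeration over internal states, a
# separate two-state CTMC implementation, and null-space solves.

# brute-force pattern probability: sum over all internal-node state
# assignments of the covarion chain
enumLogProb <- function(pattern, phy, edgeRates, mu, params, m = 1) {
  q <- lexcal::qMatrix(lexcal::buildQMatrix(params))
  rf <- lexcal::rootFrequencies(params)
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  Plist <- vector("list", nn)
  parent <- integer(nn)
  for (i in seq_len(nrow(phy$edge))) {
    ch <- phy$edge[i, 2]
    parent[ch] <- phy$edge[i, 1]
    Plist[[ch]] <- lexcal::transitionProbabilities(
      lexcal::buildQMatrix(params), phy$edge.length[i] * mu * edgeRates[i] * m)
  }
  root <- ntip + 1
  internals <- (ntip + 1):nn
  tipStates <- lapply(pattern, function(x) if (x == 1) c(2, 4) else c(1, 3))
  gridInt <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
  tipGrids <- as.matrix(expand.grid(tipStates))
  tot <- 0
  for (gi in seq_len(nrow(gridInt))) {
    stInt <- gridInt[gi, ]
    names(stInt) <- internals
    pInt <- rf[stInt[as.character(root)]]
    for (v in internals) if (v != root)
      pInt <- pInt * Plist[[v]][stInt[as.character(parent[v])],
                                stInt[as.character(v)]]
    if (pInt == 0) next
    for (ti in seq_len(nrow(tipGrids))) {
      pt <- pInt
      for (tp in seq_len(ntip))
        pt <- pt * Plist[[tp]][stInt[as.character(parent[tp])],
                               tipGrids[ti, tp]]
      tot <- tot + pt
    }
  }
  log(unname(tot))
}

# independent two-state CTMC oracle (closed-form transition probabilities,
# flux-1 normalisation matching the covarion convention), small pruning in R
twoStateLogProb <- function(pattern, phy, edgeRates, mu, piObs, m = 1) {
  a <- piObs[2] / (2 * piObs[1] * piObs[2])  # 0 -> 1
  b <- piObs[1] / (2 * piObs[1] * piObs[2])  # 1 -> 0
  Pt <- function(t) {
    e <- exp(-(a + b) * t)
    matrix(c(b + a * e, a - a * e,
             b - b * e, a + b * e) / (a + b), 2, 2, byrow = TRUE)
  }
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  parent <- integer(nn)
  Plist <- vector("list", nn)
  for (i in seq_len(nrow(phy$edge))) {
    ch <- phy$edge[i, 2]
    parent[ch] <- phy$edge[i, 1]
    Plist[[ch]] <- Pt(phy$edge.length[i] * mu * edgeRates[i] * m)
  }
  partial <- matrix(NA_real_, nn, 2)
  for (tp in seq_len(ntip))
    partial[tp, ] <- if (pattern[tp] == 1) c(0, 1) else c(1, 0)
  for (v in nn:(ntip + 1)) {
    kids <- phy$edge[phy$edge[, 1] == v, 2]
    partial[v, ] <- 1
    for (k in kids)
      partial[v, ] <- partial[v, ] * as.vector(Plist[[k]] %*% partial[k, ])
  }
  log(sum(c(piObs[1], piObs[2]) * partial[ntip + 1, ]))
}

# stationary distribution of a rate matrix by a null-space solve:
# pi Q = 0  <=>  t(Q) pi' = 0, i.e. the right null vector of t(Q)
stationaryOf <- function(q) {
  ns <- svd(t(q))
  v <- ns$v[, which.min(ns$d)]
  v / sum(v)
}

randomCovarion <- function(mode = "beast") {
  piP <- runif(1, 0.15, 0.85)
  lexcal::covarionParams(alpha = runif(1), s = runif(1, 0.1, 3),
                         piObs = c(1 - piP, piP),
                         piHidden = if (mode == "reversible")
                           { h <- runif(1, 0.2, 0.8); c(h, 1 - h) }
                         else c(0.5, 0.5),
                         mode = mode,
                         sFast = runif(1, 0.2, 2), sSlow = runif(1, 0.2, 2))
}

tree3 <- function() ape::read.tree(text = "((A:1,B:1):0.5,C:1.5);")
tree4 <- function() ape::read.tree(text = "((A:1,B:1):0.5,(C:0.6,D:0.6):0.9);")

# random-walk Metropolis on a Beta-Binomial power posterior, used as the
# conjugate toy whose evidence has the closed form B(a+x, b+n-x) / B(a, b)
betaBinomDraw <- function(a, b, x, n) {
  function(beta, nIter, seed) {
    set.seed(seed)
    p <- 0.5
    ll <- function(p) x * log(p) + (n - x) * log(1 - p)
    out <- numeric(nIter)
    for (i in seq_len(nIter)) {
      prop <- p + runif(1, -0.15, 0.15)
      if (prop > 0 && prop < 1) {
        logr <- beta * (ll(prop) - ll(p)) +
          dbeta(prop, a, b, log = TRUE) - dbeta(p, a, b, log = TRUE)
        if (log(runif(1)) < logr) p <- prop
      }
      out[i] <- ll(p)
    }
    out[-seq_len(nIter %/% 4)]
  }
}

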