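test_that("pruning equals brute-force enumeration in all three modes", {
  set.seed(30)
  phy <- tree3()
  tt <- timeTree(phy)
  rates <- c(1.3, 0.8, 1, 1.1)[seq_len(nrow(phy$edge))]
  ck <- clockModel(0.7, 0.3, rates)
  for (mode in c("beast", "reversible", "tuffley_steel")) {
    for (i in 1:4) {
      p <- randomCovarion(mode)
      for (pat in list(c(0, 1, 1), c(1, 0, 0), c(0, 0, 0))) {
        expect_equal(patternLogProbability(pat, tt, ck, p, m = 0.8),
                     enumLogProb(pat, phy, rates, 0.7, p, m = 0.8),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("pattern probabilities sum to one over all patterns", {
  tt <- timeTree(tree4())
  ck <- clockModel(0.5, 0.3, c(1.1, 0.9, 1, 1.2, 0.8, 1))
  p <- covarionParams(0.35, 0.9, piObs = c(0.55, 0.45))
  pats <- t(as.matrix(expand.grid(rep(list(0:1), 4))))
  expect_equal(sum(exp(patternLogProbability(pats, tt, ck, p))), 1,
               tolerance = 1e-10)
})

test_that("corrected pattern probabilities renormalise to one over observables", {
  tt <- timeTree(tree3())
  ck <- clockModel(0.4, 0.3, c(1.2, 0.9, 1, 1.05)[1:4])
  p <- covarionParams(0.6, 1.3, piObs = c(0.7, 0.3))
  pats <- as.matrix(expand.grid(rep(list(0:1), 3)))
  obs <- pats[rowSums(pats) > 0, ]
  tot <- 0
  for (i in seq_len(nrow(obs))) {
    lp <- correctedPartitionLogLik(matrix(obs[i, ], ncol = 1), tt, ck, p,
                                   m = 0.7, correction = TRUE)
    tot <- tot + exp(lp)
  }
  expect_equal(tot, 1, tolerance = 1e-10)
})

test_that("the correction raises observable pattern probabilities as rates fall", {
  tt <- timeTree(tree3())
  ck <- clockModel(0.05, 0, rep(1, 4))
  p <- covarionParams(0.3, 1, piObs = c(0.9, 0.1))
  col <- matrix(c(1L, 0L, 0L), ncol = 1)
  for (m in c(1, 0.3, 0.05)) {
    un <- correctedPartitionLogLik(col, tt, ck, p, m = m, correction = FALSE)
    co <- correctedPartitionLogLik(col, tt, ck, p, m = m, correction = TRUE)
    expect_gt(co, un)
  }
  # lower rate -> larger Pr(all-absent) -> larger corrected/uncorrected gap
  gap <- vapply(c(1, 0.3, 0.05), function(m)
    correctedPartitionLogLik(col, tt, ck, p, m = m, correction = TRUE) -
    correctedPartitionLogLik(col, tt, ck, p, m = m, correction = FALSE), 0)
  expect_true(all(diff(gap) > 0))
  # correction vanishes as the all-absent probability vanishes
  pHi <- covarionParams(0.3, 1, piObs = c(1e-9, 1 - 1e-9))
  expect_equal(
    correctedPartitionLogLik(col, tt, ck, pHi, correction = TRUE),
    correctedPartitionLogLik(col, tt, ck, pHi, correction = FALSE),
    tolerance = 1e-6)
})

test_that("correction refuses data containing all-absent columns", {
  tt <- timeTree(tree3())
  ck <- clockModel(0.4, 0, rep(1, 4))
  p <- covarionParams(0.5, 1)
  cols <- cbind(c(1L, 0L, 1L), c(0L, 0L, 0L))
  expect_error(correctedPartitionLogLik(cols, tt, ck, p, correction = TRUE),
               "ascertained")
})

test_that("the sampler's batched likelihood kernel matches the reference path", {
  set.seed(31)
  tt <- simulateYuleTree(0.5, 6)
  ck <- clockModel(0.1, 0.3, rBranchRates(10, 0.3))
  p <- covarionParams(0.5, 1, c(0.4, 0.6))
  sim <- simulateMatrix(tt, ck, p, partitionRates(c(1.3, 0.7)), 120)
  filt <- applyAscertainmentFilter(sim)$matrix
  tr <- lexcal:::phyloToArrays(tt@phy)
  nodeRate <- numeric(tr$nnode)
  nodeRate[tt@phy$edge[, 2]] <- ck@branchRates
  po <- lexcal:::postorderInfo(tr)
  elenBase <- lexcal:::edgeDurations(tr) * ck@mu * nodeRate
  q <- qMatrix(buildQMatrix(p))
  rf <- rootFrequencies(p)
  mVec <- c(1.3, 0.7)
  pats <- cnts <- list(); nCols <- integer(2)
  for (i in 1:2) {
    cols <- filt@values[, filt@partition == paste0("P", i), drop = FALSE]
    cp <- lexcal:::compressPatterns(cols)
    pats[[i]] <- cbind(cp$patterns, 0L)
    cnts[[i]] <- cp$counts
    nCols[i] <- ncol(cols)
  }
  batched <- lexcal:::cppPartitionLogLik(pats, cnts, po$children,
                                         po$internalIdx, elenBase, mVec,
                                         q, rf, TRUE, nCols)
  for (i in 1:2) {
    cols <- filt@values[, filt@partition == paste0("P", i), drop = FALSE]
    expect_equal(batched[i],
                 correctedPartitionLogLik(cols, tt, ck, p, m = mVec[i], TRUE),
                 tolerance = 1e-9)
  }
})

test_that("log posterior composes likelihood and priors, -Inf out of support", {
  set.seed(32)
  cfg <- priorConfig()
  tt <- simulateYuleTree(0.4, 5)
  br <- rBranchRates(8, 0.3)
  ck <- clockModel(cfg@mu, 0.3, br)
  p <- covarionParams(0.5, 1, c(0.4, 0.6))
  m <- simulateMatrix(tt, ck, p, partitionRates(c(1.2, 0.8)), 60)
  filt <- applyAscertainmentFilter(m)$matrix
  state <- list(lambda = 0.4, params = p, sigma = 0.3,
                rates = partitionRates(c(1.2, 0.8)), tree = tt,
                branchRates = br)
  lp <- logPosterior(state, filt, cfg)
  expect_true(is.finite(lp))
  # likelihood factorises: adding an independent partition adds its loglik
  stateBad <- state; stateBad$lambda <- -1
  expect_identical(logPosterior(stateBad, filt, cfg), -Inf)
  # prior-only equals the sum of evaluable densities
  lpPrior <- logPosterior(state, NULL, cfg)
  ll <- lp - lpPrior
  llDirect <- sum(vapply(c("P1", "P2"), function(pn) {
    cols <- filt@values[, filt@partition == pn, drop = FALSE]
    correctedPartitionLogLik(cols, tt, ck, p,
                             m = c(P1 = 1.2, P2 = 0.8)[[pn]], TRUE)
  }, 0))
  expect_equal(ll, llDirect, tolerance = 1e-8)
})

test_that("Yule tree prior matches the closed form on three tips", {
  phy <- ape::read.tree(text = "((A:0.4,B:0.4):0.6,C:1);")
  tr <- lexcal:::phyloToArrays(phy)
  lambda <- 1.3
  # independent intervals: duration with 2 lineages = 0.6, with 3 = 0.4
  closed <- dexp(0.6, 2 * lambda, log = TRUE) + dexp(0.4, 3 * lambda, log = TRUE)
  ours <- lexcal:::yuleLogDensity(tr, lambda)
  # equal up to the lambda-free combinatorial constant: check lambda dependence
  lambda2 <- 0.5
  closed2 <- dexp(0.6, 2 * lambda2, log = TRUE) + dexp(0.4, 3 * lambda2, log = TRUE)
  ours2 <- lexcal:::yuleLogDensity(tr, lambda2)
  expect_equal(ours - ours2, closed - closed2, tolerance = 1e-12)
})
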