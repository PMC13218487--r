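test_that("rate matrix structure: zero row sums, no double transitions", {
  set.seed(1)
  for (mode in c("beast", "reversible", "tuffley_steel")) {
    for (i in 1:5) {
      q <- qMatrix(buildQMatrix(randomCovarion(mode), normalize = (i %% 2 == 0)))
      expect_lt(max(abs(rowSums(q))), 1e-10)
      # absent<->present only within a hidden class; switches keep the
      # observed state: the anti-diagonal double-transition entries are zero
      expect_identical(unname(q[1, 4]), 0)
      expect_identical(unname(q[2, 3]), 0)
      expect_identical(unname(q[3, 2]), 0)
      expect_identical(unname(q[4, 1]), 0)
    }
  }
})

test_that("alpha = 1 collapses the fast/slow distinction", {
  p <- covarionParams(alpha = 1, s = 0.7, piObs = c(0.5, 0.5))
  q <- qMatrix(buildQMatrix(p, normalize = FALSE))
  expect_equal(unname(q[1:2, 1:2] - diag(diag(q[1:2, 1:2]))),
               unname(q[3:4, 3:4] - diag(diag(q[3:4, 3:4]))))
  # and the observed marginal is a plain binary chain: pattern probabilities
  # on a tree match an independent two-state implementation
  phy <- tree3()
  tt <- timeTree(phy)
  rates <- c(1.3, 0.8, 1, 1.1)[seq_len(nrow(phy$edge))]
  ck <- clockModel(mu = 0.4, sigma = 0.3, branchRates = rates)
  p2 <- covarionParams(alpha = 1, s = 1.4, piObs = c(0.35, 0.65))
  for (pat in list(c(0, 0, 0), c(1, 0, 1), c(1, 1, 1), c(0, 1, 0))) {
    expect_equal(patternLogProbability(pat, tt, ck, p2),
                 twoStateLogProb(pat, phy, rates, 0.4, c(0.35, 0.65)),
                 tolerance = 1e-9)
  }
})

test_that("stationary distribution equals piObs x piHidden (null-space oracle)", {
  p <- covarionParams(alpha = 0.5, s = 1, piObs = c(0.3, 0.7),
                      piHidden = c(0.5, 0.5), mode = "reversible")
  q <- qMatrix(buildQMatrix(p))
  expect_equal(stationaryOf(q), unname(rootFrequencies(p)), tolerance = 1e-9)
  set.seed(2)
  for (mode in c("beast", "reversible", "tuffley_steel")) {
    pp <- randomCovarion(mode)
    expect_equal(stationaryOf(qMatrix(buildQMatrix(pp))),
                 unname(rootFrequencies(pp)), tolerance = 1e-8)
  }
})

test_that("reversible mode satisfies detailed balance", {
  set.seed(3)
  for (i in 1:5) {
    p <- randomCovarion("reversible")
    q <- qMatrix(buildQMatrix(p))
    pi4 <- rootFrequencies(p)
    flow <- pi4 * q          # pi_i q_ij
    expect_lt(max(abs(flow - t(flow))), 1e-12)
  }
})

test_that("tuffley_steel slow class produces no substitutions", {
  p <- covarionParams(mode = "tuffley_steel", sFast = 0.8, sSlow = 0.3,
                      piObs = c(0.4, 0.6))
  q <- qMatrix(buildQMatrix(p, normalize = FALSE))
  expect_identical(unname(q[3, 4]), 0)
  expect_identical(unname(q[4, 3]), 0)
  expect_identical(p@alpha, 0)
})

test_that("normalization sets the equilibrium observable flux to one", {
  p <- covarionParams(alpha = 0.3, s = 2, piObs = c(0.25, 0.75))
  q <- qMatrix(buildQMatrix(p, normalize = TRUE))
  pi4 <- rootFrequencies(p)
  flux <- pi4[1] * q[1, 2] + pi4[2] * q[2, 1] + pi4[3] * q[3, 4] +
    pi4[4] * q[4, 3]
  expect_equal(unname(flux), 1, tolerance = 1e-12)
})

test_that("transition probabilities: identity at t=0, series at small t, ergodic at large t", {
  p <- covarionParams(alpha = 0.5, s = 1, piObs = c(0.3, 0.7),
                      piHidden = c(0.4, 0.6), mode = "reversible")
  qr <- buildQMatrix(p)
  expect_equal(unname(transitionProbabilities(qr, 0)), diag(4))
  q <- qMatrix(qr)
  t <- 1e-4
  series <- diag(4) + q * t + q %*% q * t^2 / 2
  expect_equal(unname(transitionProbabilities(qr, t)), unname(series),
               tolerance = 1e-10)
  Pbig <- transitionProbabilities(qr, 1e3)
  st <- rootFrequencies(p)
  for (i in 1:4) expect_equal(unname(Pbig[i, ]), unname(st), tolerance = 1e-8)
  expect_error(transitionProbabilities(qr, -1), "non-negative")
})

test_that("root frequencies have the product form", {
  expect_equal(unname(rootFrequencies(covarionParams(0.5, 1))), rep(0.25, 4))
  p <- covarionParams(0.5, 1, piObs = c(0.2, 0.8))
  expect_equal(unname(rootFrequencies(p)), c(0.1, 0.4, 0.1, 0.4))
  expect_equal(sum(rootFrequencies(randomCovarion("reversible"))), 1)
})

test_that("parameter validation rejects bad inputs", {
  expect_error(covarionParams(alpha = 1.2, s = 1), "alpha")
  expect_error(covarionParams(alpha = 0.5, s = -1), "s must be")
  expect_error(covarionParams(alpha = 0.5, s = 1, piObs = c(0.2, 0.9)),
               "piObs")
  expect_error(covarionParams(alpha = 0.5, s = 1, mode = "nope"))
  expect_error(covarionParams(mode = "tuffley_steel", sFast = -1, sSlow = 1),
               "tuffley_steel")
})

test_that("the sampler's fast beast-mode path matches buildQMatrix", {
  set.seed(4)
  for (i in 1:5) {
    alpha <- runif(1); s <- runif(1, 0.1, 3); piP <- runif(1, 0.1, 0.9)
    fast <- lexcal:::covQRFBeast(alpha, s, piP)
    p <- covarionParams(alpha, s, piObs = c(1 - piP, piP))
    expect_equal(fast$q, unname(qMatrix(buildQMatrix(p))), tolerance = 1e-12)
    expect_equal(fast$rf, unname(rootFrequencies(p)), tolerance = 1e-12)
  }
})
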