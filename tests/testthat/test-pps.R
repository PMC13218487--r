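table1m <- function() {
  readCognateMatrix(system.file("extdata", "table1_slavic.csv",
                                package = "lexcal"))
}

test_that("adequacy metrics are correct on the Slavic worked example", {
  met <- computeMetrics(table1m())
  # hand counts from the printed matrix: three cognates occur in exactly one
  # language (*terh1-*, *gweh3-*, *kwehl-*); only *dwo-* clears the >80%
  # prevalence bar; Polish and Czech are identical (distance 0); every other
  # pair differs in 2 of 5 columns
  expect_equal(unname(met["nSingletons"]), 3)
  expect_equal(unname(met["nPrevalent"]), 1)
  expect_equal(unname(met["minPairwiseDistance"]), 0)
  expect_equal(unname(met["maxPairwiseDistance"]), 0.4)
  expect_equal(unname(met["meanPairwiseDistance"]), 0.36)
  expect_equal(unname(met["meanPropPresent"]), 0.4)
  expect_equal(unname(met["varNPresent"]), 0)
  expect_equal(unname(met["varPrevalence"]), var(c(1, 0.2, 0.4, 0.2, 0.2)))
})

test_that("metrics are invariant to language and column order", {
  m <- table1m()
  met <- computeMetrics(m)
  permL <- sample(nrow(m@values))
  permC <- sample(ncol(m@values))
  m2 <- cognateMatrix(m@values[permL, permC], m@partition[permC])
  expect_equal(computeMetrics(m2), met)
  # identical languages have pairwise distance zero
  v <- matrix(c(1L, 1L, 0L, 0L), 2, 2, dimnames = list(c("A", "B"), NULL))
  expect_equal(unname(computeMetrics(cognateMatrix(v, c("x", "x")))["maxPairwiseDistance"]), 0)
  mNA <- cognateMatrix(matrix(c(1L, NA), 1, 2,
                              dimnames = list("A", NULL)), c("x", "x"))
  expect_error(computeMetrics(mNA), "missing")
})

test_that("mid-point two-tailed p-value matches direct evaluation", {
  # discrete toy: P(T<2)=0.5, P(T=2)=0.25, P(T>2)=0.25 -> 2*min(.625,.375)
  expect_equal(midpointPValue(c(1, 1, 2, 3), 2), 0.75)
  # observed at the exact median of an odd sample without ties
  expect_equal(midpointPValue(c(1, 2, 3, 4, 5), 3), 1 * 2 * min(0.4 + 0.1, 0.4 + 0.1))
  expect_equal(midpointPValue(c(1, 2, 3, 4, 5), 3), 1)
  # observed beyond every simulated value
  expect_equal(midpointPValue(rnorm(1000), 99), 0)
  expect_error(midpointPValue(1, 1), "length")
})

test_that("p_B is approximately uniform in closed-loop adequate experiments", {
  set.seed(80)
  pb <- replicate(400, {
    sim <- rbinom(101, 12, 0.35)     # predictive draws with ties
    obs <- rbinom(1, 12, 0.35)       # observation from the same process
    midpointPValue(sim, obs)
  })
  expect_equal(mean(pb), 0.5, tolerance = 0.05)
  expect_lt(mean(pb < 0.05), 0.1)
})

test_that("posterior predictive simulation closes the loop on adequate data", {
  set.seed(81)
  cfg <- priorConfig(mu = 0.1)
  tt <- simulateYuleTree(0.4, 6)
  truth <- drawFromPriors(cfg, 2)
  ck <- clockModel(cfg@mu, truth$sigma, rBranchRates(10, truth$sigma))
  raw <- simulateMatrix(tt, ck, truth$params, truth$rates, 400, seed = 82)
  dat <- applyAscertainmentFilter(raw)$matrix
  pps <- runPps(dat, tt, priors = cfg, nSweeps = 1500, nReps = 150, seed = 83)
  expect_equal(nrow(pps$simulated), 150)
  expect_named(pps$pB)
  # the model generated the data: every observed metric sits inside the
  # central 99% of its predictive distribution
  for (s in names(pps$pB)) {
    qs <- quantile(pps$simulated[[s]], c(0.005, 0.995))
    expect_gte(pps$observed[[s]], qs[[1]])
    expect_lte(pps$observed[[s]], qs[[2]])
  }
  expect_true(all(pps$pB >= 0 & pps$pB <= 1))
})

test_that("predictive simulation is reproducible and respects nReps", {
  set.seed(84)
  cfg <- priorConfig(mu = 0.1)
  tt <- simulateYuleTree(0.4, 5)
  truth <- drawFromPriors(cfg, 2)
  ck <- clockModel(cfg@mu, truth$sigma, rBranchRates(8, truth$sigma))
  dat <- applyAscertainmentFilter(
    simulateMatrix(tt, ck, truth$params, truth$rates, 200, seed = 85))$matrix
  trace <- runMcmc(dat, priors = cfg, nSweeps = 600, thin = 1, seed = 86,
                   treeMode = "fixed", tree = tt, logBranchRates = TRUE)
  counts <- vapply(c("P1", "P2"), function(p) sum(dat@partition == p), 0L)
  one <- simulatePredictive(trace, tt, counts, nReps = 1, mu = cfg@mu,
                            seed = 87)
  expect_equal(nrow(one), 1)
  a <- simulatePredictive(trace, tt, counts, nReps = 5, mu = cfg@mu, seed = 88)
  b <- simulatePredictive(trace, tt, counts, nReps = 5, mu = cfg@mu, seed = 88)
  expect_identical(a, b)
  # filter_only mode leaves the column count random but non-degenerate
  fo <- simulatePredictive(trace, tt, counts, nReps = 3, mu = cfg@mu,
                           mode = "filter_only", seed = 89)
  expect_equal(nrow(fo), 3)
  expect_error(simulatePredictive(trace, tt, counts, nReps = 10000,
                                  mu = cfg@mu), "fewer")
})
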