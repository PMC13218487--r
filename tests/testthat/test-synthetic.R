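test_that("prior draws are deterministic given a seed and stay in support", {
  cfg <- priorConfig()
  d1 <- drawFromPriors(cfg, 3, seed = 11)
  d2 <- drawFromPriors(cfg, 3, seed = 11)
  expect_identical(d1$lambda, d2$lambda)
  expect_identical(d1$rates@m, d2$rates@m)
  expect_identical(d1$params@s, d2$params@s)
  expect_true(d1$lambda > 0 && d1$sigma > 0)
  expect_true(all(d1$params@piObs > 0 & d1$params@piObs < 1))
})

test_that("weighted Dirichlet rates have the stated moments and constraint", {
  set.seed(12)
  draws <- replicate(10000, rWeightedDirichlet(3, alpha = 1)@m)
  expect_equal(rowMeans(draws), rep(1, 3), tolerance = 0.03)
  w <- c(10, 3, 1)
  for (i in 1:50) {
    r <- rWeightedDirichlet(3, alpha = 2, w = w)
    expect_equal(sum(w * r@m) / sum(w), 1, tolerance = 1e-12)
    expect_true(all(r@m > 0))
  }
  expect_error(partitionRates(c(2, 1)), "weighted mean")
})

test_that("branch rates are mean-one lognormal", {
  set.seed(13)
  r <- rBranchRates(20000, 0.8)
  expect_equal(mean(r), 1, tolerance = 0.03)
  expect_equal(sd(log(r)), 0.8, tolerance = 0.03)
})

test_that("Yule simulator: branch count, two-tip waiting time, internode means", {
  tt <- simulateYuleTree(1, 30, seed = 14)
  expect_equal(nrow(tt@phy$edge), 58L)
  expect_s4_class(tt, "TimeTree")
  set.seed(15)
  h2 <- replicate(4000, treeHeight(simulateYuleTree(0.5, 2)))
  # single coalescence: waiting time ~ Exp(2 * lambda)
  expect_equal(mean(h2), 1, tolerance = 0.06)
  expect_gt(ks.test(h2, pexp, rate = 1)$p.value, 0.01)
  # internode interval with k lineages has mean 1/(k * lambda)
  set.seed(16)
  lambda <- 0.7
  gaps <- replicate(3000, {
    tr <- lexcal:::simulateYuleArrays(lambda, 5)
    sort(tr$age[tr$age > 0], decreasing = TRUE)
  })
  ages <- t(gaps)
  durs <- cbind(ages[, 1] - ages[, 2], ages[, 2] - ages[, 3],
                ages[, 3] - ages[, 4], ages[, 4])
  expect_equal(colMeans(durs), 1 / (2:5 * lambda), tolerance = 0.08)
})

test_that("degenerate zero-height tree yields constant columns at root frequencies", {
  phy <- ape::read.tree(text = "(A:0,B:0);")
  tt <- timeTree(phy)
  ck <- clockModel(0.05, 0.3, c(1, 1))
  p <- covarionParams(0.5, 1, piObs = c(0.3, 0.7))
  m <- simulateMatrix(tt, ck, p, partitionRates(1), 4000, seed = 17)
  expect_true(all(m@values[1, ] == m@values[2, ]))
  expect_equal(mean(m@values[1, ]), 0.7, tolerance = 3 * sqrt(0.21 / 4000))
})

test_that("simulated pattern frequencies match pruning probabilities", {
  # the central simulator/likelihood cross-check
  phy <- ape::read.tree(text = "(A:1,B:1);")
  tt <- timeTree(phy)
  ck <- clockModel(0.3, 0.3, c(0.9, 1.4))  # rate variation, tips at age 0
  p <- covarionParams(0.4, 0.8, piObs = c(0.6, 0.4))
  n <- 1e5
  m <- simulateMatrix(tt, ck, p, partitionRates(1), n, seed = 18)
  pats <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  theory <- exp(patternLogProbability(t(pats), tt, ck, p))
  key <- m@values[1, ] + 2 * m@values[2, ]
  emp <- tabulate(key + 1, 4) / n
  mcse <- sqrt(theory * (1 - theory) / n)
  expect_true(all(abs(emp - theory) < 3.5 * mcse))
})

test_that("all-absent fraction matches the analytic unobservable probability", {
  phy <- ape::read.tree(text = "((A:0.5,B:0.5):0.5,C:1);")
  tt <- timeTree(phy)
  ck <- clockModel(0.02, 0, rep(1, 4))  # slow clock
  p <- covarionParams(0.3, 1, piObs = c(0.92, 0.08))  # low present frequency
  n <- 2e4
  mLow <- simulateMatrix(tt, ck, p, partitionRates(1), n, seed = 19)
  p0 <- exp(patternLogProbability(c(0, 0, 0), tt, ck, p))
  frac <- mean(colSums(mLow@values) == 0)
  expect_gt(p0, 0.5)  # a large proportion is unobservable at low rates
  expect_equal(frac, unname(p0), tolerance = 4 * sqrt(p0 * (1 - p0) / n))
})

test_that("SBC suite encodes the three study configurations", {
  cfg <- priorConfig()
  s1 <- generateSbcSuite(cfg, 2, study = 1, nTips = 6, nCognates = 150,
                         nPartitions = 2, seed = 20)
  expect_false(s1[[1]]$inference$ascertainment)
  expect_true(any(colSums(s1[[1]]$data@values) == 0))  # all-absent retained
  s2 <- generateSbcSuite(cfg, 2, study = 2, nTips = 6, nCognates = 150,
                         nPartitions = 2, seed = 20)
  s3 <- generateSbcSuite(cfg, 2, study = 3, nTips = 6, nCognates = 150,
                         nPartitions = 2, seed = 20)
  expect_true(s2[[1]]$inference$ascertainment)
  # same data, different operator/prior weights only
  expect_identical(s2[[1]]$data@values, s3[[1]]$data@values)
  expect_identical(s2[[1]]$truth, s3[[1]]$truth)
  expect_equal(s2[[1]]$inference$weights, c(1, 1))
  expect_equal(s3[[1]]$inference$weights,
               unname(vapply(c("P1", "P2"), function(p)
                 sum(s3[[1]]$data@partition == p), 0L)))
  # replicates reproducible from (seed, index)
  s2b <- generateSbcSuite(cfg, 2, study = 2, nTips = 6, nCognates = 150,
                          nPartitions = 2, seed = 20)
  expect_identical(s2[[2]]$data@values, s2b[[2]]$data@values)
  expect_identical(s2[[2]]$truth$lambda, s2b[[2]]$truth$lambda)
})

test_that("observed partition length increases with its rate across draws", {
  cfg <- priorConfig()
  reps <- generateSbcSuite(cfg, 25, study = 2, nTips = 8, nCognates = 250,
                           nPartitions = 2, seed = 21)
  dm <- vapply(reps, function(r) r$truth$m[1] - r$truth$m[2], 0)
  dn <- vapply(reps, function(r)
    sum(r$data@partition == "P1") - sum(r$data@partition == "P2"), 0L)
  expect_gt(cor(dm, dn, method = "spearman"), 0)
})

test_that("suite files are written when an output directory is given", {
  cfg <- priorConfig()
  out <- file.path(tempdir(), "sbcout")
  generateSbcSuite(cfg, 1, study = 2, nTips = 5, nCognates = 100,
                   nPartitions = 2, seed = 22, outDir = out)
  expect_true(file.exists(file.path(out, "true_parameters.tsv")))
  expect_true(file.exists(file.path(out, "rep001_data.csv")))
  tr <- ape::read.tree(file.path(out, "rep001_tree.nwk"))
  expect_equal(ape::Ntip(tr), 5)
  cfgLines <- readLines(file.path(out, "rep001_config.yml"))
  expect_true(any(grepl("ascertainment_correction: true", cfgLines)))
})
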