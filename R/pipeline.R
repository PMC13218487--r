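#' Run a full simulation-based calibration study
#'
#' Orchestrates generate -> infer -> diagnose for one of the three study
#' configurations (see [generateSbcSuite()]): simulates replicates from the
#' priors, re-analyses each with [runMcmc()] under the study's inference
#' configuration, and collects true values, posterior ranks, HPD intervals,
#' effective sample sizes and pooled posterior clades.
#'
#' In study 3 the sampler is initialised at unit partition rates rather than
#' at the generating values: the weighted delta exchange preserves the
#' weighted rate sum of its starting state, and the analysis model
#' constrains the cognate-weighted mean to one -- a constraint the
#' generating rates (unweighted mean one) do not satisfy. This is precisely
#' the simulation/analysis mismatch the study probes.
#'
#' @param study 1, 2 or 3.
#' @param priors A [PriorConfig-class] object (shared by simulation and
#'   inference).
#' @param nReplicates Number of SBC replicates.
#' @param nTips,nCognates,nPartitions Simulation scale.
#' @param nSweeps,thin MCMC settings per replicate.
#' @param rankL Thinned posterior draws used for ranking.
#' @param seed Master seed.
#' @param outDir Optional output directory for per-replicate files.
#' @param verbose Print per-replicate progress.
#' @return An [SBCResult-class] object.
#' @export
runSbcStudy <- function(study = 2, priors = priorConfig(), nReplicates = 30,
                        nTips = 10, nCognates = 2000, nPartitions = 2,
                        nSweeps = 4000, thin = 2, rankL = 100, seed = 1,
                        outDir = NULL, verbose = FALSE) {
  reps <- generateSbcSuite(priors, nReplicates, study, nTips, nCognates,
                           nPartitions, seed, outDir)
  params <- c("lambda", "alpha", "s", "piPresent", "sigma",
              paste0("m", seq_len(nPartitions)), "treeHeight", "treeLength",
              "tipRate1")
  tv <- rk <- lo <- hi <- es <- matrix(NA_real_, nReplicates, length(params),
                                       dimnames = list(NULL, params))
  cladeList <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    rep <- reps[[r]]
    unweighted <- all(rep$inference$weights == rep$inference$weights[1])
    initM <- if (unweighted) rep$truth$m else rep(1, nPartitions)
    trace <- runMcmc(data = rep$data, priors = priors, nSweeps = nSweeps,
                     thin = thin, seed = seed * 10000L + 5000L + r,
                     treeMode = "sampled",
                     weights = rep$inference$weights,
                     correction = rep$inference$ascertainment,
                     init = list(lambda = rep$truth$lambda,
                                 alpha = rep$truth$alpha, s = rep$truth$s,
                                 piPresent = rep$truth$piPresent,
                                 sigma = rep$truth$sigma, m = initM,
                                 tree = rep$tree,
                                 nodeRate = rep$branchRates))
    truth <- unlist(rep$truth)
    names(truth) <- params[seq_along(truth)]
    sm <- trace@samples
    didx <- round(seq(1, nrow(sm), length.out = rankL))
    for (p in params) {
      draws <- sm[[p]]
      tv[r, p] <- truth[[p]]
      rk[r, p] <- pitRank(draws[didx], truth[[p]])
      h <- hpdInterval(draws, 0.95)
      lo[r, p] <- h[1]; hi[r, p] <- h[2]
      es[r, p] <- essChain(draws)
    }
    trueKeys <- cladeKeys(rep$tree)
    supp <- trace@cladeSupport
    if (length(supp))
      cladeList[[r]] <- data.frame(replicate = r, clade = names(supp),
                                   support = as.numeric(supp),
                                   inTrue = names(supp) %in% trueKeys,
                                   row.names = NULL)
    if (verbose)
      message(sprintf("replicate %d/%d done (min ESS %.0f)", r, nReplicates,
                      min(es[r, ])))
  }
  new("SBCResult", trueValues = as.data.frame(tv), ranks = as.data.frame(rk),
      rankL = rankL, hpdLow = as.data.frame(lo), hpdHigh = as.data.frame(hi),
      ess = as.data.frame(es),
      clades = do.call(rbind, cladeList) %||% data.frame(),
      study = study,
      config = list(nTips = nTips, nCognates = nCognates,
                    nPartitions = nPartitions, nSweeps = nSweeps,
                    seed = seed, hpdMass = 0.95))
}

#' Summarise an SBC study
#'
#' Per tracked parameter: HPD coverage with its exact binomial interval and
#' whether the nominal 95% lies inside it, the ECDF-difference uniformity
#' verdict, and the minimum effective sample size across replicates.
#'
#' @param sbc An [SBCResult-class] object.
#' @param level Simultaneous level for the ECDF bands.
#' @param bandSeed Seed for band calibration.
#' @return Data frame, one row per parameter.
#' @export
summarizeSbc <- function(sbc, level = 0.95, bandSeed = 1) {
  cov <- coverage(sbc)
  cov$coverageOk <- cov$ciLow <= 0.95 & 0.95 <= cov$ciHigh
  cov$ecdfPass <- vapply(cov$parameter, function(p)
    ecdfDifference(pitRanks(sbc, p), level = level,
                   bandSeed = bandSeed)$pass, TRUE)
  cov$minEss <- vapply(cov$parameter, function(p) min(sbc@ess[[p]]), 0)
  cov
}

#' Simulate a dataset whose partition rates follow a weighted Dirichlet
#'
#' Generates one partitioned cognate dataset in which each partition stands
#' for a bin of meaning classes and the partition rates are drawn from a
#' Dirichlet weighted by the number of meanings per partition -- the
#' meaning-weighted generative model. Used for self-consistency experiments
#' in weighting-scheme comparison.
#'
#' @param priors A [PriorConfig-class] object.
#' @param nTips Tips of the simulated Yule tree.
#' @param meaningsPerPartition Integer vector: meaning classes per partition.
#' @param rawCognatesPerMeaning Simulated (pre-filter) cognates per meaning.
#' @param seed Seed.
#' @return List with `data` (ascertained [CognateMatrix-class]), `tree`
#'   ([TimeTree-class]), `truth` (parameter list) and
#'   `meaningsPerPartition`.
#' @export
simulateWeightedDataset <- function(priors = priorConfig(), nTips = 8,
                                    meaningsPerPartition = c(5, 3, 1),
                                    rawCognatesPerMeaning = 60, seed = 1) {
  set.seed(seed)
  k <- length(meaningsPerPartition)
  lambda <- rlnorm(1, priors@lambdaMeanlog, priors@lambdaSdlog)
  piPresent <- rbeta(1, priors@piObsShape1, priors@piObsShape2)
  params <- covarionParams(alpha = runif(1), s = rexp(1, priors@sRate),
                           piObs = c(1 - piPresent, piPresent), mode = "beast")
  sigma <- rexp(1, priors@sigmaRate)
  rates <- rWeightedDirichlet(k, priors@dirichletAlpha,
                              w = meaningsPerPartition)
  tr <- simulateYuleArrays(lambda, nTips)
  nodeRate <- numeric(tr$nnode)
  nonroot <- which(tr$parent != 0L)
  nodeRate[nonroot] <- rBranchRates(length(nonroot), sigma)
  raw <- simulateMatrixArrays(tr, nodeRate, priors@mu, params, rates@m,
                              rawCognatesPerMeaning * meaningsPerPartition)
  filt <- applyAscertainmentFilter(raw, onEmpty = "error")
  list(data = filt$matrix, tree = timeTree(arraysToPhylo(tr)),
       truth = list(lambda = lambda, params = params, sigma = sigma,
                    rates = rates),
       meaningsPerPartition = meaningsPerPartition)
}

#' Posterior predictive adequacy analysis
#'
#' Fixed-tree MCMC on the observed matrix, posterior predictive simulation
#' matched to the observed per-partition column counts, and mid-point
#' two-tailed p-values for the eight adequacy metrics.
#'
#' @param data Ascertained [CognateMatrix-class] object without missing
#'   data.
#' @param tree Fixed [TimeTree-class] object.
#' @param priors A [PriorConfig-class] object.
#' @param nSweeps MCMC sweeps.
#' @param nReps Posterior predictive replicates.
#' @param seed Master seed.
#' @param mode Conditioning mode for [simulatePredictive()].
#' @return List with `observed` (metric vector), `simulated` (metric data
#'   frame), `pB` (named p-values), and `trace`.
#' @export
runPps <- function(data, tree, priors = priorConfig(), nSweeps = 3000,
                   nReps = 200, seed = 1, mode = "match_observed") {
  if (anyNA(data@values)) stop("missing data is not supported")
  trace <- runMcmc(data = data, priors = priors, nSweeps = nSweeps,
                   thin = 1, seed = seed, treeMode = "fixed", tree = tree,
                   correction = TRUE, logBranchRates = TRUE)
  meanings <- unique(data@partition)
  counts <- vapply(meanings, function(mm) sum(data@partition == mm), 0L)
  sim <- simulatePredictive(trace, tree, counts, nReps = nReps,
                            mu = priors@mu, mode = mode, seed = seed + 1)
  obs <- computeMetrics(data)
  pB <- vapply(PPS_METRICS, function(s) midpointPValue(sim[[s]], obs[[s]]), 0)
  list(observed = obs, simulated = sim, pB = pB, trace = trace)
}
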