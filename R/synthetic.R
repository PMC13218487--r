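#' Draw partition rates from a weighted Dirichlet
#'
#' Constructive definition: draw `x ~ Dirichlet(alpha * 1)` and set
#' `m_i = x_i * sum(w) / w_i`, which guarantees the weighted mean
#' `sum(w * m) / sum(w) = 1` exactly. With equal weights this is the plain
#' mean-one scaled Dirichlet.
#'
#' @param nPartitions Number of partitions.
#' @param alpha Dirichlet concentration.
#' @param w Positive weights (default equal).
#' @return A [PartitionRates-class] object.
#' @export
rWeightedDirichlet <- function(nPartitions, alpha = 1, w = rep(1, nPartitions)) {
  g <- rgamma(nPartitions, shape = alpha, rate = 1)
  x <- g / sum(g)
  partitionRates(x * sum(w) / w, w = w, dirichletAlpha = alpha)
}

# log density of the weighted-Dirichlet construction, up to a constant,
# evaluated at rates m satisfying the weighted mean-1 constraint
dWeightedDirichletLog <- function(m, w, alpha) {
  x <- m * w / sum(w)
  if (any(x <= 0)) return(-Inf)
  sum((alpha - 1) * log(x))
}

#' Draw all model parameters from their priors
#'
#' One joint draw of the generative model: Yule birth rate, covarion
#' parameters (beast mode), branch-rate standard deviation and partition
#' rates. The same [PriorConfig-class] drives inference, so simulation and
#' analysis share one model, as simulation-based calibration requires.
#'
#' @param cfg A [PriorConfig-class] object.
#' @param nPartitions Number of data partitions.
#' @param w Partition weights for the Dirichlet (default equal).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `lambda`, `params` ([CovarionParams-class]), `sigma`,
#'   and `rates` ([PartitionRates-class]).
#' @export
drawFromPriors <- function(cfg, nPartitions = 3, w = rep(1, nPartitions),
                           seed = NULL) {
  stopifnot(is(cfg, "PriorConfig"))
  if (!is.null(seed)) set.seed(seed)
  lambda <- rlnorm(1, cfg@lambdaMeanlog, cfg@lambdaSdlog)
  piPresent <- rbeta(1, cfg@piObsShape1, cfg@piObsShape2)
  params <- covarionParams(alpha = runif(1), s = rexp(1, cfg@sRate),
                           piObs = c(1 - piPresent, piPresent), mode = "beast")
  sigma <- rexp(1, cfg@sigmaRate)
  rates <- rWeightedDirichlet(nPartitions, cfg@dirichletAlpha, w)
  list(lambda = lambda, params = params, sigma = sigma, rates = rates)
}

#' Simulate a Yule time tree conditioned on the tip count
#'
#' Forward pure-birth simulation: while `k` lineages exist the waiting time
#' to the next split is exponential with rate `k * lambda`, for
#' `k = 2, ..., nTips` (the interval with `nTips` lineages ends the
#' simulation at the present). The splitting lineage is chosen uniformly.
#' The implied density over node ages is
#' `lambda^(n-1) * exp(-lambda * treeLength)` up to constants, which is the
#' tree prior used in inference.
#'
#' @param lambda Birth rate (> 0).
#' @param nTips Number of tips (>= 2).
#' @param seed Optional seed.
#' @return A [TimeTree-class] object with `2 * nTips - 2` branches.
#' @export
simulateYuleTree <- function(lambda, nTips, seed = NULL) {
  stopifnot(lambda > 0, nTips >= 2)
  if (!is.null(seed)) set.seed(seed)
  timeTree(arraysToPhylo(simulateYuleArrays(lambda, nTips)))
}

simulateYuleArrays <- function(lambda, nTips, tipLabels = paste0("L", seq_len(nTips))) {
  d <- rexp(nTips - 1, rate = (2:nTips) * lambda)   # interval with k lineages
  height <- sum(d)
  splitAges <- height - cumsum(c(0, d[-length(d)])) # age of split k -> k+1
  nnode <- 2L * nTips - 1L
  parent <- integer(nnode)
  kids <- matrix(NA_integer_, nnode, 2)
  age <- numeric(nnode)
  root <- nTips + 1L
  age[root] <- height
  nextInt <- nTips + 2L
  attach <- c(root, root)        # parent node of each currently open lineage
  if (nTips > 2) {
    for (k in 2:(nTips - 1)) {
      i <- sample.int(k, 1)      # open lineage that splits at splitAges[k]
      v <- nextInt; nextInt <- nextInt + 1L
      age[v] <- splitAges[k]
      parent[v] <- attach[i]
      kids[attach[i], if (is.na(kids[attach[i], 1])) 1 else 2] <- v
      attach[i] <- v
      attach <- c(attach, v)
    }
  }
  for (i in seq_along(attach)) { # remaining open lineages become the tips
    parent[i] <- attach[i]
    kids[attach[i], if (is.na(kids[attach[i], 1])) 1 else 2] <- i
  }
  list(ntip = nTips, nnode = nnode, parent = parent, kids = kids,
       age = age, root = root, tipLabels = tipLabels)
}

#' Draw lognormal branch rates with mean one
#'
#' Rates are `Lognormal(-sigma^2 / 2, sigma)` so the mean multiplier is 1.
#'
#' @param n Number of branches.
#' @param sigma Standard deviation on the log scale.
#' @export
rBranchRates <- function(n, sigma) rlnorm(n, -sigma^2 / 2, sigma)

#' Simulate a binary cognate matrix on a tree
#'
#' Evolves each cognate column independently under the covarion process:
#' a root state is drawn from [rootFrequencies()], states are propagated
#' down the tree with transition probabilities over the effective branch
#' length `duration * mu * branchRate * m_partition`, and the hidden class
#' is marginalised away in the output (only absent/present is recorded).
#' All-absent columns are retained (raw, unascertained output).
#'
#' @param tree A [TimeTree-class] object.
#' @param clock A [ClockModel-class] object (branch rates ordered like
#'   `phy$edge`).
#' @param params A [CovarionParams-class] object.
#' @param rates A [PartitionRates-class] object.
#' @param nCognates Cognates per partition (scalar or per-partition vector).
#' @param partitionNames Meaning ids (default P1, P2, ...).
#' @param seed Optional seed.
#' @return A raw [CognateMatrix-class] object.
#' @export
simulateMatrix <- function(tree, clock, params, rates, nCognates,
                           partitionNames = NULL, seed = NULL) {
  stopifnot(is(tree, "TimeTree"), is(clock, "ClockModel"),
            is(params, "CovarionParams"), is(rates, "PartitionRates"))
  if (!is.null(seed)) set.seed(seed)
  tr <- phyloToArrays(tree@phy)
  nodeRate <- numeric(tr$nnode)
  edge <- tree@phy$edge
  nodeRate[edge[, 2]] <- clock@branchRates
  simulateMatrixArrays(tr, nodeRate, clock@mu, params, rates@m, nCognates,
                       partitionNames)
}

# tr: internal arrays; nodeRate indexed by child node
simulateMatrixArrays <- function(tr, nodeRate, mu, params, m, nCognates,
                                 partitionNames = NULL) {
  k <- length(m)
  nCognates <- rep(nCognates, length.out = k)
  if (is.null(partitionNames)) partitionNames <- paste0("P", seq_len(k))
  q <- qMatrix(buildQMatrix(params, normalize = TRUE))
  rf <- rootFrequencies(params)
  dur <- edgeDurations(tr)
  preorder <- rev(postorderInfo(tr)$internalIdx + 1L)
  blocks <- vector("list", k)
  for (i in seq_len(k)) {
    nc <- nCognates[i]
    states <- matrix(0L, tr$nnode, nc)
    states[tr$root, ] <- sample.int(4, nc, replace = TRUE, prob = rf)
    for (v in preorder) {
      for (ch in tr$kids[v, ]) {
        p <- cppExpmat(q, dur[ch] * mu * nodeRate[ch] * m[i])
        ps <- states[v, ]
        for (sidx in 1:4) {
          sel <- which(ps == sidx)
          if (length(sel))
            states[ch, sel] <- sample.int(4, length(sel), replace = TRUE,
                                          prob = p[sidx, ])
        }
      }
    }
    obs <- matrix(as.integer(states[seq_len(tr$ntip), , drop = FALSE] %in% c(2L, 4L)),
                  tr$ntip, nc)
    blocks[[i]] <- obs
  }
  v <- do.call(cbind, blocks)
  rownames(v) <- tr$tipLabels
  meanings <- rep(partitionNames, times = nCognates)
  colnames(v) <- paste(meanings, unlist(lapply(nCognates, seq_len)), sep = "_")
  cognateMatrix(v, meanings, ascertained = FALSE)
}

#' Generate a suite of simulation-based calibration replicates
#'
#' Each replicate draws parameters from the priors, simulates a Yule tree,
#' branch rates and a partitioned cognate matrix, and packages the dataset
#' with the inference configuration of the requested study:
#' \describe{
#'   \item{study 1}{raw data (all-absent columns retained), no ascertainment
#'     correction, unweighted partition rates;}
#'   \item{study 2}{all-absent columns removed, correction on, rates
#'     unweighted;}
#'   \item{study 3}{as study 2, but the Dirichlet prior and the delta
#'     exchange operator are reweighted by the observed per-partition
#'     cognate counts (the default behaviour of mainstream Bayesian
#'     phylolinguistic pipelines).}
#' }
#' Simulation always uses the unweighted generative model; only the
#' analysis configuration differs between studies 2 and 3.
#'
#' @param cfg A [PriorConfig-class] object.
#' @param nReplicates Number of replicates.
#' @param study 1, 2 or 3.
#' @param nTips Tips per simulated tree.
#' @param nCognates Simulated cognates per partition (before filtering).
#' @param nPartitions Number of partitions.
#' @param seed Master seed; replicate r is reproducible from (seed, r).
#' @param outDir Optional directory: writes per-replicate CSV matrices,
#'   Newick trees, a true-parameter TSV and config files.
#' @return List of replicates, each with `truth` (named list), `data`
#'   (a [CognateMatrix-class]), `tree`, `branchRates` (node-indexed),
#'   and `inference` (list: ascertainment flag, weights).
#' @export
generateSbcSuite <- function(cfg, nReplicates, study = 2, nTips = 10,
                             nCognates = 2000, nPartitions = 2, seed = 1,
                             outDir = NULL) {
  stopifnot(study %in% 1:3, nReplicates >= 1)
  reps <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    set.seed(seed * 10000L + r)
    draw <- drawFromPriors(cfg, nPartitions)
    tr <- simulateYuleArrays(draw$lambda, nTips)
    nodeRate <- numeric(tr$nnode)
    nonroot <- which(tr$parent != 0L)
    nodeRate[nonroot] <- rBranchRates(length(nonroot), draw$sigma)
    raw <- simulateMatrixArrays(tr, nodeRate, cfg@mu, draw$params,
                                draw$rates@m, nCognates)
    if (study == 1) {
      dat <- raw
      weights <- rep(1, nPartitions)
      correction <- FALSE
    } else {
      filt <- applyAscertainmentFilter(raw, onEmpty = "error")
      dat <- filt$matrix
      correction <- TRUE
      obsCounts <- vapply(paste0("P", seq_len(nPartitions)),
                          function(p) sum(dat@partition == p), 0L)
      weights <- if (study == 3) as.numeric(obsCounts) else rep(1, nPartitions)
    }
    truth <- list(lambda = draw$lambda, alpha = draw$params@alpha,
                  s = draw$params@s, piPresent = draw$params@piObs[2],
                  sigma = draw$sigma, m = draw$rates@m,
                  treeHeight = tr$age[tr$root],
                  treeLength = sum(edgeDurations(tr)),
                  tipRate1 = nodeRate[1])
    reps[[r]] <- list(truth = truth, data = dat, tree = tr,
                      branchRates = nodeRate,
                      inference = list(ascertainment = correction,
                                       weights = weights))
  }
  if (!is.null(outDir)) writeSbcSuite(reps, cfg, study, outDir)
  reps
}

writeSbcSuite <- function(reps, cfg, study, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  truths <- do.call(rbind, lapply(seq_along(reps), function(r) {
    t <- reps[[r]]$truth
    data.frame(replicate = r, lambda = t$lambda, alpha = t$alpha, s = t$s,
               piPresent = t$piPresent, sigma = t$sigma,
               t(setNames(t$m, paste0("m", seq_along(t$m)))),
               treeHeight = t$treeHeight, treeLength = t$treeLength)
  }))
  utils::write.table(truths, file.path(outDir, "true_parameters.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (r in seq_along(reps)) {
    writeCognateMatrix(reps[[r]]$data,
                       file.path(outDir, sprintf("rep%03d_data.csv", r)))
    writeLines(ape::write.tree(arraysToPhylo(reps[[r]]$tree)),
               file.path(outDir, sprintf("rep%03d_tree.nwk", r)))
    inf <- reps[[r]]$inference
    writeLines(c(sprintf("study: %d", study),
                 sprintf("ascertainment_correction: %s",
                         tolower(inf$ascertainment)),
                 sprintf("weights: %s", paste(inf$weights, collapse = " ")),
                 sprintf("mu: %g", cfg@mu)),
               file.path(outDir, sprintf("rep%03d_config.yml", r)))
  }
  invisible(outDir)
}
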