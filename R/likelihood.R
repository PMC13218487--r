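#' @title Ascertainment-corrected covarion likelihood
#' @description Internal pattern machinery plus the exported likelihood
#'   operations. Columns are compressed to unique site patterns with counts
#'   before pruning (binary data on n tips has at most 2^n patterns, usually
#'   far fewer), and the all-absent pattern is appended so the correction
#'   term costs no extra pruning pass.
#' @name likelihood
NULL

# compress 0/1 columns to unique patterns; returns ntip x npat matrix + counts
compressPatterns <- function(values) {
  if (anyNA(values)) stop("missing data is not supported by the likelihood")
  ntip <- nrow(values)
  key <- as.character(as.vector(crossprod(values, 2^(seq_len(ntip) - 1))))
  ux <- !duplicated(key)
  pat <- values[, ux, drop = FALSE]
  cnt <- as.vector(table(factor(key, levels = key[ux])))
  list(patterns = matrix(as.integer(pat), ntip), counts = cnt)
}

# per-partition corrected log likelihood on internal arrays.
# pat already has the all-absent pattern appended as its LAST column;
# cnt covers only the observed patterns (length ncol(pat) - 1).
partitionLogLikArrays <- function(pat, cnt, po, elen, q, rf, correct, nCols) {
  lp <- cppPatternLogLik(pat, po$children, po$internalIdx, elen, q, rf)
  np <- length(lp)
  ll <- sum(cnt * lp[-np])
  if (correct) {
    p0 <- exp(lp[np])
    if (p0 >= 1 - 1e-12) stop("Pr(all-absent) numerically degenerate (>= 1)")
    ll <- ll - nCols * log1p(-p0)
  }
  ll
}

#' Log probability of site patterns under the covarion model
#'
#' Felsenstein pruning over the four covarion states with two-state tip
#' data: an observed 0 is compatible with (absent-fast, absent-slow), an
#' observed 1 with (present-fast, present-slow); the hidden class is
#' marginalised exactly.
#'
#' @param pattern 0/1 vector (one pattern) or languages-by-patterns matrix,
#'   rows ordered like the tree's tip labels.
#' @param tree A [TimeTree-class] object.
#' @param clock A [ClockModel-class] object.
#' @param params A [CovarionParams-class] object.
#' @param m Partition rate multiplier applied to all branch lengths.
#' @return Log probability (vector, one per pattern).
#' @export
patternLogProbability <- function(pattern, tree, clock, params, m = 1) {
  if (is.vector(pattern)) pattern <- matrix(pattern, ncol = 1)
  if (anyNA(pattern)) stop("missing data is not supported")
  tr <- phyloToArrays(tree@phy)
  nodeRate <- numeric(tr$nnode)
  nodeRate[tree@phy$edge[, 2]] <- clock@branchRates
  po <- postorderInfo(tr)
  elen <- edgeDurations(tr) * clock@mu * nodeRate * m
  q <- qMatrix(buildQMatrix(params, normalize = TRUE))
  rf <- rootFrequencies(params)
  as.vector(cppPatternLogLik(matrix(as.integer(pattern), nrow(pattern)),
                             po$children, po$internalIdx, elen, q, rf))
}

#' Corrected log likelihood of one data partition
#'
#' Sum of pattern log probabilities, optionally renormalised for
#' ascertainment bias: each observable pattern probability is divided by
#' `1 - Pr(all-absent)` computed under the same tree, clock and model
#' parameters, since all-absent cognate sets cannot be observed.
#'
#' @param columns 0/1 matrix (languages x cognate columns).
#' @param tree,clock,params,m As in [patternLogProbability()].
#' @param correction Apply the ascertainment correction (requires no
#'   all-absent columns in `columns`).
#' @return Log likelihood (scalar).
#' @export
correctedPartitionLogLik <- function(columns, tree, clock, params, m = 1,
                                     correction = TRUE) {
  if (correction && any(colSums(columns) == 0))
    stop("correction requires ascertained data (no all-absent columns)")
  cp <- compressPatterns(columns)
  tr <- phyloToArrays(tree@phy)
  nodeRate <- numeric(tr$nnode)
  nodeRate[tree@phy$edge[, 2]] <- clock@branchRates
  po <- postorderInfo(tr)
  elen <- edgeDurations(tr) * clock@mu * nodeRate * m
  q <- qMatrix(buildQMatrix(params, normalize = TRUE))
  rf <- rootFrequencies(params)
  pat <- cbind(cp$patterns, 0L)
  partitionLogLikArrays(pat, cp$counts, po, elen, q, rf, correction,
                        ncol(columns))
}

# joint log prior over all sampled quantities (internal arrays)
logPriorArrays <- function(lambda, alpha, s, piPresent, sigma, m, w, tr,
                           nodeRate, cfg) {
  if (lambda <= 0 || s <= 0 || sigma <= 0 || alpha < 0 || alpha > 1 ||
      piPresent <= 0 || piPresent >= 1 || any(m <= 0))
    return(-Inf)
  nonroot <- which(tr$parent != 0L)
  lp <- dlnorm(lambda, cfg@lambdaMeanlog, cfg@lambdaSdlog, log = TRUE) +
    dexp(s, cfg@sRate, log = TRUE) +
    dbeta(piPresent, cfg@piObsShape1, cfg@piObsShape2, log = TRUE) +
    dexp(sigma, cfg@sigmaRate, log = TRUE) +
    dWeightedDirichletLog(m, w, cfg@dirichletAlpha) +
    yuleLogDensity(tr, lambda) +
    sum(dlnorm(nodeRate[nonroot], -sigma^2 / 2, sigma, log = TRUE))
  lp
}

# Yule tree prior: lambda^(n-1) * exp(-lambda * treeLength), up to constants
yuleLogDensity <- function(tr, lambda) {
  (tr$ntip - 1) * log(lambda) - lambda * sum(edgeDurations(tr))
}

#' Joint log posterior density
#'
#' Sum of per-partition (optionally ascertainment-corrected) covarion log
#' likelihoods and the log priors: lognormal on the Yule birth rate, the
#' Yule tree density given the birth rate, mean-one lognormal branch rates,
#' a weighted Dirichlet on partition rates, and the covarion priors from the
#' supplied [PriorConfig-class]. Out-of-support states return `-Inf`.
#'
#' @param state Named list: `lambda`, `params` ([CovarionParams-class]),
#'   `sigma`, `rates` ([PartitionRates-class]), `tree`
#'   ([TimeTree-class]), `branchRates` (per-edge, ordered like `phy$edge`).
#' @param data A [CognateMatrix-class] object (or NULL for prior-only), with
#'   one partition per element of `partitions`.
#' @param partitions Partition list from [buildPartitions()] (default: one
#'   per meaning, in order).
#' @param priors A [PriorConfig-class] object.
#' @param correction Apply the ascertainment correction.
#' @return Log posterior density (unnormalised).
#' @export
logPosterior <- function(state, data, priors, partitions = NULL,
                         correction = TRUE) {
  tr <- phyloToArrays(state$tree@phy)
  nodeRate <- numeric(tr$nnode)
  nodeRate[state$tree@phy$edge[, 2]] <- state$branchRates
  lp <- logPriorArrays(state$lambda, state$params@alpha, state$params@s,
                       state$params@piObs[2], state$sigma, state$rates@m,
                       state$rates@w, tr, nodeRate, priors)
  if (!is.finite(lp) || is.null(data)) return(lp)
  if (is.null(partitions))
    partitions <- buildPartitions(data, partitionSpec("per_meaning"))
  clock <- clockModel(priors@mu, state$sigma, state$branchRates)
  for (i in seq_along(partitions)) {
    cols <- data@values[, partitions[[i]]$columns, drop = FALSE]
    lp <- lp + correctedPartitionLogLik(cols, state$tree, clock,
                                        state$params, state$rates@m[i],
                                        correction)
  }
  lp
}
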