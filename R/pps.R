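PPS_METRICS <- c("maxPairwiseDistance", "minPairwiseDistance",
                 "meanPairwiseDistance", "meanPropPresent", "varNPresent",
                 "nPrevalent", "nSingletons", "varPrevalence")

#' Posterior predictive adequacy metrics
#'
#' Eight summary statistics of a binary cognate matrix capturing language
#' divergence (maximum, minimum and mean pairwise Hamming-fraction distance
#' between languages), language composition (mean proportion of present
#' cognates, variance of the number of present cognates per language), and
#' the distribution of cognates across languages (number of prevalent
#' cognates, present in strictly more than 80% of languages; number of
#' singletons, present in exactly one language; variance of cognate
#' prevalence).
#'
#' @param m A [CognateMatrix-class] object without missing data.
#' @return Named numeric vector of the 8 metrics.
#' @export
computeMetrics <- function(m) {
  stopifnot(is(m, "CognateMatrix"))
  v <- m@values
  if (anyNA(v)) stop("metrics require a matrix without missing data")
  d <- as.matrix(stats::dist(v, method = "manhattan")) / ncol(v)
  pair <- d[upper.tri(d)]
  prev <- colMeans(v)
  c(maxPairwiseDistance = max(pair),
    minPairwiseDistance = min(pair),
    meanPairwiseDistance = mean(pair),
    meanPropPresent = mean(rowMeans(v)),
    varNPresent = var(rowSums(v)),
    nPrevalent = sum(prev > 0.8),
    nSingletons = sum(colSums(v) == 1),
    varPrevalence = var(prev))
}

#' Simulate posterior predictive datasets on a fixed tree
#'
#' For each of `nReps` (evenly subsampled) posterior draws from a
#' fixed-tree trace logged with branch rates, simulates a cognate matrix
#' under that draw on the fixed tree and computes the adequacy metrics.
#' With `mode = "match_observed"` cognates are simulated per partition
#' until the observed number of non-all-absent columns is reached
#' (rejection of all-absent columns), so replicates are directly comparable
#' to ascertained data; with `mode = "filter_only"` a fixed raw count is
#' simulated and filtered, leaving the column count random.
#'
#' @param trace A [PosteriorTrace-class] object from a fixed-tree
#'   [runMcmc()] run with `logBranchRates = TRUE`.
#' @param tree The fixed [TimeTree-class] object.
#' @param observedCounts Named (or ordered) integer vector: observed
#'   ascertained column count per partition.
#' @param nReps Number of predictive replicates (default 1001).
#' @param mu Clock rate used in the analysis.
#' @param mode Conditioning mode, see above.
#' @param nRaw Raw columns per partition for `filter_only` mode.
#' @param seed Optional seed.
#' @return Data frame (`nReps` rows) of the 8 metrics.
#' @export
simulatePredictive <- function(trace, tree, observedCounts, nReps = 1001,
                               mu = 0.05, mode = c("match_observed",
                                                   "filter_only"),
                               nRaw = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(trace, "PosteriorTrace"), is(tree, "TimeTree"))
  if (!is.null(seed)) set.seed(seed)
  sm <- trace@samples
  rateCols <- grep("^rate_", colnames(sm), value = TRUE)
  if (!length(rateCols))
    stop("trace was not logged with branch rates (logBranchRates = TRUE)")
  if (nrow(sm) < nReps)
    stop("trace has fewer post-burn-in samples than nReps")
  idx <- round(seq(1, nrow(sm), length.out = nReps))
  tr <- phyloToArrays(tree@phy)
  k <- length(observedCounts)
  mCols <- paste0("m", seq_len(k))
  out <- matrix(NA_real_, nReps, length(PPS_METRICS),
                dimnames = list(NULL, PPS_METRICS))
  for (r in seq_len(nReps)) {
    row <- sm[idx[r], ]
    params <- covarionParams(alpha = row$alpha, s = row$s,
                             piObs = c(1 - row$piPresent, row$piPresent),
                             mode = "beast")
    nodeRate <- numeric(tr$nnode)
    nodeRate[as.integer(sub("rate_", "", rateCols))] <-
      as.numeric(row[rateCols])
    m <- as.numeric(row[mCols])
    blocks <- vector("list", k)
    for (i in seq_len(k)) {
      if (mode == "match_observed") {
        need <- observedCounts[i]
        got <- NULL
        tries <- 0
        while (is.null(got) || ncol(got) < need) {
          tries <- tries + 1
          if (tries > 60) stop("rejection sampling failed to reach the observed column count")
          sim <- simulateMatrixArrays(tr, nodeRate, mu, params, m[i],
                                      max(2 * need, 50))
          keep <- sim@values[, colSums(sim@values) > 0, drop = FALSE]
          got <- if (is.null(got)) keep else cbind(got, keep)
        }
        blocks[[i]] <- got[, seq_len(need), drop = FALSE]
      } else {
        nr <- if (is.null(nRaw)) 2L * observedCounts[i] else rep(nRaw, length.out = k)[i]
        sim <- simulateMatrixArrays(tr, nodeRate, mu, params, m[i], nr)
        blocks[[i]] <- sim@values[, colSums(sim@values) > 0, drop = FALSE]
      }
    }
    v <- do.call(cbind, blocks)
    meanings <- rep(paste0("P", seq_len(k)),
                    times = vapply(blocks, ncol, 0L))
    colnames(v) <- make.unique(paste(meanings, "c", sep = "_"))
    mm <- cognateMatrix(v, meanings, ascertained = TRUE)
    out[r, ] <- computeMetrics(mm)
  }
  as.data.frame(out)
}

#' Mid-point two-tailed posterior predictive p-value
#'
#' `p_B = 2 * min(P(T < t) + P(T = t)/2, P(T > t) + P(T = t)/2)`, capped at
#' 1, where T runs over the simulated values and t is the observed value. A
#' value of 1 indicates the observation sits at the centre of the
#' predictive distribution (perfect fit); values below 0.05 indicate a
#' significant discrepancy.
#'
#' @param simulated Numeric vector of predictive statistic values (>= 2).
#' @param observed Observed statistic.
#' @return p-value in [0, 1].
#' @export
midpointPValue <- function(simulated, observed) {
  stopifnot(length(simulated) >= 2)
  pl <- mean(simulated < observed)
  pe <- mean(simulated == observed)
  pg <- mean(simulated > observed)
  min(1, 2 * min(pl + pe / 2, pg + pe / 2))
}
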