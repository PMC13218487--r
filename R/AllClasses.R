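#' @useDynLib lexcal, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats acf binom.test dbeta dexp dlnorm dunif dbinom
#'   optimize quantile setNames rbeta rbinom rexp rgamma rlnorm runif sd var
NULL

COVARION_STATES <- c("absent-fast", "present-fast", "absent-slow", "present-slow")
COVARION_MODES <- c("beast", "reversible", "tuffley_steel")

#' Binary covarion model parameters
#'
#' Parameter bundle for the binary covarion substitution process, in which
#' each cognate evolves between observed states (absent, present) while
#' switching between a hidden fast and a hidden slow rate class.
#'
#' @slot alpha Relative substitution rate of the slow class, in [0, 1].
#' @slot s Switch rate between hidden classes (per unit expected-substitution
#'   time). Ignored in `tuffley_steel` mode, which carries separate rates.
#' @slot piObs Equilibrium frequencies of the observed states
#'   (absent, present).
#' @slot piHidden Equilibrium frequencies of the hidden classes (fast, slow).
#' @slot mode One of `"beast"` (hidden frequencies fixed at 0.5/0.5 and left
#'   out of the rate matrix; the standard phylolinguistic set-up),
#'   `"reversible"` (hidden frequencies enter the switch rates), or
#'   `"tuffley_steel"` (alpha = 0 with separate fast/slow switch rates).
#' @slot sFast,sSlow Switch rates out of the fast / slow class
#'   (`tuffley_steel` mode only; `NA` otherwise).
#' @export
setClass("CovarionParams",
  representation(alpha = "numeric", s = "numeric", piObs = "numeric",
                 piHidden = "numeric", mode = "character",
                 sFast = "numeric", sSlow = "numeric"))

setValidity("CovarionParams", function(object) {
  msg <- character()
  ok1 <- function(p) length(p) == 2 && all(is.finite(p)) && all(p > 0) &&
    all(p < 1) && abs(sum(p) - 1) < 1e-9
  if (!ok1(object@piObs)) msg <- c(msg, "piObs must be a 2-vector in (0,1) summing to 1")
  if (!ok1(object@piHidden)) msg <- c(msg, "piHidden must be a 2-vector in (0,1) summing to 1")
  if (!(length(object@alpha) == 1 && is.finite(object@alpha) &&
        object@alpha >= 0 && object@alpha <= 1))
    msg <- c(msg, "alpha must lie in [0, 1]")
  if (!object@mode %in% COVARION_MODES)
    msg <- c(msg, paste("mode must be one of:", paste(COVARION_MODES, collapse = ", ")))
  if (object@mode == "tuffley_steel") {
    if (object@alpha != 0) msg <- c(msg, "tuffley_steel mode requires alpha = 0")
    if (!(is.finite(object@sFast) && object@sFast > 0 &&
          is.finite(object@sSlow) && object@sSlow > 0))
      msg <- c(msg, "tuffley_steel mode requires positive sFast and sSlow")
  } else {
    if (!(length(object@s) == 1 && is.finite(object@s) && object@s > 0))
      msg <- c(msg, "s must be a positive finite switch rate")
    if (object@mode == "beast" && any(abs(object@piHidden - 0.5) > 1e-9))
      msg <- c(msg, "beast mode fixes piHidden at (0.5, 0.5)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct covarion model parameters
#'
#' @param alpha Relative rate of the slow class, in [0, 1].
#' @param s Switch rate between hidden classes.
#' @param piObs Observed-state (absent, present) equilibrium frequencies.
#' @param piHidden Hidden-class (fast, slow) equilibrium frequencies. Forced
#'   to (0.5, 0.5) in `beast` mode; in `tuffley_steel` mode derived from the
#'   switch rates so that the root distribution is stationary.
#' @param mode Parameterisation, see [CovarionParams-class].
#' @param sFast,sSlow Switch rates out of the fast and slow classes
#'   (`tuffley_steel` mode only).
#' @return A [CovarionParams-class] object.
#' @examples
#' covarionParams(alpha = 0.3, s = 0.5, piObs = c(0.7, 0.3))
#' @export
covarionParams <- function(alpha, s = NA_real_, piObs = c(0.5, 0.5),
                           piHidden = c(0.5, 0.5),
                           mode = c("beast", "reversible", "tuffley_steel"),
                           sFast = NA_real_, sSlow = NA_real_) {
  mode <- match.arg(mode)
  if (mode == "beast") piHidden <- c(0.5, 0.5)
  if (mode == "tuffley_steel") {
    alpha <- 0
    piHidden <- c(sSlow, sFast) / (sFast + sSlow)
    s <- NA_real_
  }
  new("CovarionParams", alpha = as.numeric(alpha), s = as.numeric(s),
      piObs = as.numeric(piObs), piHidden = as.numeric(piHidden),
      mode = mode, sFast = as.numeric(sFast), sSlow = as.numeric(sSlow))
}

setMethod("show", "CovarionParams", function(object) {
  cat("CovarionParams [", object@mode, "]\n", sep = "")
  cat("  alpha =", format(object@alpha, digits = 4),
      if (object@mode == "tuffley_steel")
        paste0(" sFast = ", format(object@sFast, digits = 4),
               " sSlow = ", format(object@sSlow, digits = 4))
      else paste0(" s = ", format(object@s, digits = 4)), "\n")
  cat("  piObs (absent, present) =", paste(format(object@piObs, digits = 4), collapse = ", "), "\n")
  cat("  piHidden (fast, slow)   =", paste(format(object@piHidden, digits = 4), collapse = ", "), "\n")
})

#' Covarion instantaneous rate matrix
#'
#' @slot q 4x4 rate matrix over states ordered
#'   (absent-fast, present-fast, absent-slow, present-slow); rows sum to zero.
#' @slot stateOrder State labels.
#' @slot normalized Whether the matrix was rescaled so the equilibrium flux of
#'   observable (absent/present) substitutions is one per unit time.
#' @export
setClass("RateMatrix",
  representation(q = "matrix", stateOrder = "character", normalized = "logical"))

setValidity("RateMatrix", function(object) {
  q <- object@q
  if (!all(dim(q) == c(4, 4))) return("q must be 4x4")
  off <- q; diag(off) <- 0
  sc <- max(abs(q), 1)
  if (any(off < -1e-12 * sc)) return("off-diagonal rates must be non-negative")
  if (any(abs(rowSums(q)) > 1e-8 * sc)) return("rows must sum to zero")
  TRUE
})

setMethod("show", "RateMatrix", function(object) {
  cat("Covarion rate matrix (",
      if (object@normalized) "normalized" else "unnormalized", ")\n", sep = "")
  print(round(object@q, 5))
})

#' Partitioned binary cognate matrix
#'
#' Languages-by-cognate-sets presence/absence matrix, with each column
#' assigned to a meaning class (the data partition) and a flag recording
#' whether all-absent columns have been filtered out (the ascertainment
#' status of real cognate data, where a cognate set absent from every
#' language is unobservable).
#'
#' @slot values Integer matrix (languages x cognate sets) with entries 0, 1 or
#'   NA (missing, written "?" on disk). Row names are language names, column
#'   names cognate-set ids.
#' @slot partition Character vector, one meaning id per column.
#' @slot ascertained TRUE if no all-absent columns are present (filtered
#'   data / real data), FALSE for raw simulated data.
#' @export
setClass("CognateMatrix",
  representation(values = "matrix", partition = "character", ascertained = "logical"))

setValidity("CognateMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!all(v %in% c(0L, 1L, NA))) msg <- c(msg, "values must be 0, 1 or NA")
  if (is.null(rownames(v))) msg <- c(msg, "values must have language row names")
  if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate language names")
  if (length(object@partition) != ncol(v))
    msg <- c(msg, "partition must assign one meaning per column")
  if (any(is.na(object@partition)) || any(object@partition == ""))
    msg <- c(msg, "every column needs a meaning assignment")
  if (isTRUE(object@ascertained) && ncol(v) > 0) {
    present <- colSums(v == 1L, na.rm = TRUE)
    if (any(present == 0)) msg <- c(msg, "ascertained matrix contains an all-absent column")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a cognate matrix
#'
#' @param values Numeric/integer matrix of 0/1/NA with language row names.
#' @param meanings Character vector of meaning ids, one per column.
#' @param ascertained Whether all-absent columns are known to be removed.
#' @return A [CognateMatrix-class] object.
#' @export
cognateMatrix <- function(values, meanings, ascertained = FALSE) {
  storage.mode(values) <- "integer"
  if (is.null(colnames(values)))
    colnames(values) <- make.unique(paste(meanings, seq_len(ncol(values)), sep = "_"))
  new("CognateMatrix", values = values, partition = as.character(meanings),
      ascertained = ascertained)
}

setMethod("show", "CognateMatrix", function(object) {
  cat("CognateMatrix:", nrow(object@values), "languages x",
      ncol(object@values), "cognate sets in",
      length(unique(object@partition)), "meanings;",
      if (object@ascertained) "ascertained (no all-absent columns)" else "raw", "\n")
})

#' Rooted time tree
#'
#' A rooted, binary, ultrametric tree with branch lengths in time units
#' (tips at age zero).
#'
#' @slot phy An [ape::phylo] object with edge lengths in time.
#' @export
setClass("TimeTree", representation(phy = "ANY"))

setValidity("TimeTree", function(object) {
  phy <- object@phy
  if (!inherits(phy, "phylo")) return("phy must be an ape phylo object")
  if (is.null(phy$edge.length)) return("tree must have edge lengths")
  if (!ape::is.binary(phy)) return("tree must be binary")
  if (!ape::is.rooted(phy)) return("tree must be rooted")
  depth <- ape::node.depth.edgelength(phy)
  tipd <- depth[seq_len(ape::Ntip(phy))]
  if (diff(range(tipd)) > 1e-6 * max(tipd, 1))
    return("tree must be ultrametric (tips at age 0)")
  TRUE
})

#' Construct a time tree
#' @param phy A rooted binary ultrametric [ape::phylo] tree.
#' @export
timeTree <- function(phy) new("TimeTree", phy = phy)

setMethod("show", "TimeTree", function(object) {
  cat("TimeTree:", ape::Ntip(object@phy), "tips, height",
      format(treeHeight(object), digits = 5), "time units\n")
})

#' Relaxed clock model
#'
#' Global clock rate plus independent lognormal branch-rate multipliers
#' (mean 1 on the natural scale), one per edge of the associated tree.
#'
#' @slot mu Clock rate: expected substitutions per cognate per time unit.
#' @slot sigma Standard deviation of log branch rates.
#' @slot branchRates Multipliers, ordered like the rows of `phy$edge` of the
#'   tree the clock belongs to.
#' @export
setClass("ClockModel",
  representation(mu = "numeric", sigma = "numeric", branchRates = "numeric"))

setValidity("ClockModel", function(object) {
  if (!(object@mu > 0)) return("mu must be positive")
  if (!(object@sigma >= 0)) return("sigma must be non-negative")
  if (any(object@branchRates <= 0)) return("branch rates must be positive")
  TRUE
})

#' Construct a clock model
#' @param mu Clock rate (expected substitutions per cognate per time unit).
#' @param sigma Lognormal standard deviation of branch rates (log scale).
#' @param branchRates Per-edge rate multipliers.
#' @export
clockModel <- function(mu, sigma, branchRates)
  new("ClockModel", mu = mu, sigma = sigma, branchRates = branchRates)

#' Partition rate multipliers under a weighted mean-one constraint
#'
#' @slot m Per-partition rate multipliers.
#' @slot w Positive weights; `sum(w * m) / sum(w) == 1`.
#' @slot dirichletAlpha Concentration of the generating Dirichlet.
#' @export
setClass("PartitionRates",
  representation(m = "numeric", w = "numeric", dirichletAlpha = "numeric"))

setValidity("PartitionRates", function(object) {
  if (length(object@m) != length(object@w)) return("m and w must have equal length")
  if (any(object@m <= 0)) return("rates must be positive")
  if (any(object@w <= 0)) return("weights must be positive")
  if (abs(sum(object@w * object@m) / sum(object@w) - 1) > 1e-8)
    return("weighted mean of rates must equal 1")
  TRUE
})

#' Construct partition rates
#' @param m Rate multipliers with weighted mean one.
#' @param w Weights (default equal).
#' @param dirichletAlpha Dirichlet concentration used to draw them.
#' @export
partitionRates <- function(m, w = rep(1, length(m)), dirichletAlpha = 1)
  new("PartitionRates", m = as.numeric(m), w = as.numeric(w),
      dirichletAlpha = dirichletAlpha)

#' Prior configuration for simulation and inference
#'
#' The same object parameterises the generative model (prior draws for
#' simulation) and the inference priors; simulation-based calibration is only
#' meaningful when the two coincide.
#'
#' @slot lambdaMeanlog,lambdaSdlog Lognormal prior on the Yule birth rate.
#' @slot sRate Exponential rate for the covarion switch-rate prior.
#' @slot piObsShape1,piObsShape2 Beta prior on the present-state frequency.
#' @slot sigmaRate Exponential rate for the branch-rate lognormal sd prior.
#' @slot dirichletAlpha Concentration of the partition-rate Dirichlet.
#' @slot mu Fixed clock rate.
#' @export
setClass("PriorConfig",
  representation(lambdaMeanlog = "numeric", lambdaSdlog = "numeric",
                 sRate = "numeric", piObsShape1 = "numeric",
                 piObsShape2 = "numeric", sigmaRate = "numeric",
                 dirichletAlpha = "numeric", mu = "numeric"))

setValidity("PriorConfig", function(object) {
  pos <- c(lambdaSdlog = object@lambdaSdlog, sRate = object@sRate,
           piObsShape1 = object@piObsShape1, piObsShape2 = object@piObsShape2,
           sigmaRate = object@sigmaRate, dirichletAlpha = object@dirichletAlpha,
           mu = object@mu)
  if (any(!is.finite(pos)) || any(pos <= 0))
    return("all prior hyperparameters must be positive and finite")
  TRUE
})

#' Construct a prior configuration
#'
#' Defaults give a desk-scale study: trees a few time units deep under the
#' fixed clock rate 0.05, uniform slow-class rate, mean-1 exponential switch
#' rate, Beta(2, 2) present frequency, Exp(mean 0.3) branch-rate sd and a
#' flat Dirichlet on partition rates.
#'
#' @param lambdaMeanlog,lambdaSdlog Lognormal prior on the Yule birth rate.
#' @param sRate Exponential rate of the switch-rate prior (mean `1/sRate`).
#' @param piObsShape1,piObsShape2 Beta prior on the present-state frequency.
#' @param sigmaRate Exponential rate of the prior on the branch-rate sd.
#' @param dirichletAlpha Dirichlet concentration for partition rates.
#' @param mu Fixed clock rate (expected substitutions per cognate per time
#'   unit).
#' @export
priorConfig <- function(lambdaMeanlog = log(0.3), lambdaSdlog = 0.5,
                        sRate = 1, piObsShape1 = 2, piObsShape2 = 2,
                        sigmaRate = 1 / 0.3, dirichletAlpha = 1, mu = 0.05)
  new("PriorConfig", lambdaMeanlog = lambdaMeanlog, lambdaSdlog = lambdaSdlog,
      sRate = sRate, piObsShape1 = piObsShape1, piObsShape2 = piObsShape2,
      sigmaRate = sigmaRate, dirichletAlpha = dirichletAlpha, mu = mu)

#' Posterior trace from an MCMC run
#'
#' @slot samples Data frame of logged scalar parameters (one row per
#'   retained sweep), including derived tree height and length columns.
#' @slot cladeSupport Named numeric vector of posterior clade probabilities
#'   (names are semicolon-joined sorted tip labels); empty for fixed-tree
#'   runs where only the scalars are sampled.
#' @slot acceptance Named acceptance rates per operator.
#' @slot burninFrac Fraction of sweeps discarded as burn-in before logging.
#' @slot nSweeps Total post-burn-in sweeps retained.
#' @export
setClass("PosteriorTrace",
  representation(samples = "data.frame", cladeSupport = "numeric",
                 acceptance = "numeric", burninFrac = "numeric",
                 nSweeps = "numeric"))

setMethod("show", "PosteriorTrace", function(object) {
  cat("PosteriorTrace:", nrow(object@samples), "samples x",
      ncol(object@samples), "columns;",
      length(object@cladeSupport), "distinct posterior clades\n")
})

#' Simulation-based calibration result
#'
#' @slot trueValues Data frame (replicate x parameter) of generating values.
#' @slot ranks Data frame of ranks of the true values among `rankL` thinned
#'   posterior draws (0..rankL).
#' @slot rankL Number of thinned draws used for ranking.
#' @slot hpdLow,hpdHigh Data frames of 95% HPD bounds per replicate/parameter.
#' @slot ess Data frame of effective sample sizes.
#' @slot clades Data frame of pooled posterior clades: replicate, clade key,
#'   posterior support, and whether the clade is in the true tree.
#' @slot study Which study configuration was run (1, 2 or 3).
#' @slot config List of run settings.
#' @export
setClass("SBCResult",
  representation(trueValues = "data.frame", ranks = "data.frame",
                 rankL = "numeric", hpdLow = "data.frame",
                 hpdHigh = "data.frame", ess = "data.frame",
                 clades = "data.frame", study = "numeric", config = "list"))

setMethod("show", "SBCResult", function(object) {
  cat("SBCResult: study", object@study, "with", nrow(object@trueValues),
      "replicates,", ncol(object@ranks), "tracked parameters\n")
})
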