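#' Power posterior schedule
#'
#' Tempering powers `beta_k = (k / (K - 1))^(1 / shape)` for
#' `k = 0, ..., K - 1`: the quantiles of a Beta(shape, 1) distribution, the
#' de facto standard schedule for path sampling, concentrating steps near
#' the prior where the integrand changes fastest.
#'
#' @param nSteps Number of power posteriors (>= 2).
#' @param shape Schedule shape (default 0.3); 1 gives uniform spacing.
#' @return Increasing vector from 0 to 1 of length `nSteps`.
#' @export
powerPosteriorSchedule <- function(nSteps = 30, shape = 0.3) {
  stopifnot(nSteps >= 2)
  if (shape <= 0) stop("shape must be positive")
  (seq_len(nSteps) - 1)^(1 / shape) / (nSteps - 1)^(1 / shape)
}

#' Path-sampling estimate of the log marginal likelihood
#'
#' Generic engine: for each power `beta` in the schedule an MCMC run
#' targeting `prior * likelihood^beta` supplies samples of the
#' (untempered) log likelihood; the log marginal likelihood is the
#' trapezoidal integral of the mean log likelihood over `beta`, with a
#' standard error assembled from the per-step variances and effective
#' sample sizes. Steps are independent and mergeable, so they can be run in
#' any order (or in parallel) and combined.
#'
#' @param drawLogLik Function `(beta, nIter, seed)` returning a numeric
#'   vector of post-burn-in log-likelihood samples under the power
#'   posterior at `beta`.
#' @param schedule Vector of powers from [powerPosteriorSchedule()]; must
#'   contain both endpoints 0 and 1.
#' @param nIter Iterations passed to `drawLogLik`.
#' @param seed Master seed; step k uses `seed + k`.
#' @param essFloor Minimum ESS of the log-likelihood chain per step; a
#'   failure is a warning naming the step.
#' @return List with `logML`, `se`, and a per-step data frame
#'   (`beta`, `meanLogLik`, `varLogLik`, `ess`).
#' @export
pathSamplingLogML <- function(drawLogLik, schedule = powerPosteriorSchedule(),
                              nIter = 1000, seed = 1, essFloor = 50) {
  schedule <- sort(schedule)
  if (length(schedule) < 2 || abs(schedule[1]) > 1e-12 ||
      abs(schedule[length(schedule)] - 1) > 1e-12)
    stop("schedule must run from 0 to 1 with at least two steps")
  steps <- lapply(seq_along(schedule), function(k) {
    llk <- drawLogLik(schedule[k], nIter, seed + k)
    ess <- tryCatch(essChain(llk), warning = function(w) length(llk))
    data.frame(beta = schedule[k], meanLogLik = mean(llk),
               varLogLik = var(llk), ess = ess)
  })
  tab <- do.call(rbind, steps)
  low <- tab$ess < essFloor
  if (any(low))
    warning("log-likelihood ESS below ", essFloor, " at beta = ",
            paste(signif(tab$beta[low], 3), collapse = ", "))
  db <- diff(tab$beta)
  logML <- sum(db * (tab$meanLogLik[-1] + tab$meanLogLik[-nrow(tab)]) / 2)
  # each step's mean enters two trapezoids; collect its total weight
  wts <- c(db / 2, 0) + c(0, db / 2)
  se <- sqrt(sum(wts^2 * tab$varLogLik / pmax(tab$ess, 1)))
  list(logML = logML, se = se, steps = tab)
}

#' Path sampling for a partitioned cognate dataset
#'
#' Runs the package's MCMC at each power of the schedule (fixed tree) and
#' integrates the mean log likelihood. The `weights` argument selects the
#' partition-rate weighting scheme under comparison: it sets both the
#' weighted Dirichlet prior and the delta exchange operator.
#'
#' @param data A [CognateMatrix-class] object (ascertained).
#' @param tree Fixed [TimeTree-class] object.
#' @param priors A [PriorConfig-class] object.
#' @param weights Partition weights (length = number of meanings in `data`).
#' @param schedule Power schedule.
#' @param nSweeps MCMC sweeps per power posterior.
#' @param seed Master seed.
#' @param correction Ascertainment correction flag.
#' @return As [pathSamplingLogML()].
#' @export
pathSamplingCognate <- function(data, tree, priors = priorConfig(),
                                weights = NULL,
                                schedule = powerPosteriorSchedule(),
                                nSweeps = 800, seed = 1, correction = TRUE) {
  drawLogLik <- function(beta, nIter, sd) {
    tr <- runMcmc(data = data, priors = priors, nSweeps = nIter,
                  burninFrac = 0.25, thin = 1, seed = sd,
                  treeMode = "fixed", tree = tree, weights = weights,
                  correction = correction, beta = beta)
    tr@samples$logLik
  }
  pathSamplingLogML(drawLogLik, schedule, nIter = nSweeps, seed = seed)
}

#' Bayes factors against the best model
#'
#' @param logMLs Named numeric vector of log marginal likelihoods.
#' @return Data frame with model, logML, and `BF = exp(logML - max(logML))`
#'   (best model has BF 1).
#' @export
bayesFactors <- function(logMLs) {
  stopifnot(length(logMLs) >= 2)
  if (is.null(names(logMLs)))
    names(logMLs) <- paste0("model", seq_along(logMLs))
  data.frame(model = names(logMLs), logML = as.numeric(logMLs),
             BF = exp(logMLs - max(logMLs)), row.names = NULL)
}

#' Compare partition-rate weighting schemes by marginal likelihood
#'
#' Estimates the log marginal likelihood of the cognate-weighted,
#' meaning-weighted and equal-weighted partition-rate models by path
#' sampling and reports a Bayes factor table against the best model.
#'
#' @param data A [CognateMatrix-class] object (ascertained), partitioned by
#'   meaning.
#' @param tree Fixed [TimeTree-class] object.
#' @param meaningsPerPartition Number of meaning classes each partition
#'   aggregates (the meaning-weighting weights); default 1 per partition.
#' @param priors,schedule,nSweeps,seed As in [pathSamplingCognate()].
#' @return List with `table` (model, logML, SE, BF) and the per-model step
#'   logs.
#' @export
compareWeightings <- function(data, tree, meaningsPerPartition = NULL,
                              priors = priorConfig(),
                              schedule = powerPosteriorSchedule(),
                              nSweeps = 800, seed = 1) {
  meanings <- unique(data@partition)
  k <- length(meanings)
  counts <- vapply(meanings, function(mm) sum(data@partition == mm), 0L)
  mw <- meaningsPerPartition %||% rep(1, k)
  schemes <- list(cognates = as.numeric(counts), meanings = as.numeric(mw),
                  equal = rep(1, k))
  fits <- lapply(seq_along(schemes), function(i)
    pathSamplingCognate(data, tree, priors, weights = schemes[[i]],
                        schedule = schedule, nSweeps = nSweeps,
                        seed = seed + 1000 * i))
  names(fits) <- names(schemes)
  logMLs <- vapply(fits, function(f) f$logML, 0)
  tab <- bayesFactors(logMLs)
  tab$se <- vapply(fits, function(f) f$se, 0)
  list(table = tab, fits = fits)
}
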