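#' Weighted delta exchange proposal on partition rates
#'
#' Picks two distinct partitions i, j, draws `delta ~ U(0, deltaMax)`, and
#' proposes `m_i + delta / w_i`, `m_j - delta / w_j`, which preserves
#' `sum(w * m)` exactly; the proposal is symmetric (log Hastings ratio 0).
#' Moves that would drive a rate non-positive are flagged invalid.
#'
#' @param m A [PartitionRates-class] object (>= 2 partitions).
#' @param deltaMax Maximum transfer.
#' @return List with `m` (proposed [PartitionRates-class] or NULL if
#'   invalid), `valid`, and `logHastings` (always 0).
#' @export
weightedDeltaExchange <- function(m, deltaMax = 0.3) {
  stopifnot(is(m, "PartitionRates"))
  if (length(m@m) < 2) stop("delta exchange needs at least two partitions")
  pr <- deltaExchangeRaw(m@m, m@w, deltaMax)
  list(m = if (pr$valid) partitionRates(pr$m, m@w, m@dirichletAlpha) else NULL,
       valid = pr$valid, logHastings = 0)
}

deltaExchangeRaw <- function(m, w, deltaMax) {
  ij <- sample.int(length(m), 2)
  delta <- runif(1, 0, deltaMax)
  m2 <- m
  m2[ij[1]] <- m[ij[1]] + delta / w[ij[1]]
  m2[ij[2]] <- m[ij[2]] - delta / w[ij[2]]
  list(m = m2, valid = all(m2 > 0))
}

# reflecting random walk on (lo, hi)
reflect <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' Run MCMC over tree, clock, covarion and partition-rate parameters
#'
#' Metropolis-within-Gibbs sampler targeting the posterior of the standard
#' phylolinguistic model: per-partition ascertainment-corrected covarion
#' likelihoods, a Yule tree prior with birth rate `lambda`, mean-one
#' lognormal branch rates with sd `sigma`, and a weighted Dirichlet prior on
#' partition rates. Operators: scale moves on `lambda`, `s`, `sigma`;
#' reflecting random walks on `alpha` and the present frequency; weighted
#' delta exchange on partition rates; log-scale random walks on single
#' branch rates; and (in sampled-tree mode) uniform node-age moves, a root
#' age scaler, a whole-tree scaler, and narrow and wide topology exchanges.
#' Step sizes are adapted toward a 0.2--0.4 acceptance rate during burn-in
#' only. With `data = NULL` the likelihood is identically zero and the
#' sampler targets the prior (used for prior-recovery checks); `beta`
#' tempers the likelihood for power-posterior runs.
#'
#' @param data A [CognateMatrix-class] object, or NULL for prior-only
#'   sampling. Partitions are its meanings in order of first appearance.
#' @param priors A [PriorConfig-class] object.
#' @param nSweeps Total sweeps including burn-in.
#' @param burninFrac Fraction of sweeps discarded (and used for adaptation).
#' @param thin Record every `thin`-th post-burn-in sweep.
#' @param seed Optional seed.
#' @param treeMode `"sampled"` or `"fixed"` (fixed requires `tree`).
#' @param tree A [TimeTree-class] object: the fixed tree, or the initial
#'   tree in sampled mode.
#' @param weights Partition weights for the Dirichlet prior and the delta
#'   exchange operator (default equal).
#' @param correction Apply the ascertainment correction.
#' @param beta Likelihood tempering power in [0, 1].
#' @param init Optional initial state: list with any of `lambda`, `alpha`,
#'   `s`, `piPresent`, `sigma`, `m`, `tree` (internal arrays or
#'   [TimeTree-class]), `nodeRate` (per-node branch rates).
#' @param logBranchRates Also record every branch rate in the trace
#'   (fixed-tree mode; needed for posterior predictive simulation).
#' @param nTipsPrior,nPartitionsPrior Tip/partition counts for prior-only
#'   runs without data.
#' @return A [PosteriorTrace-class] object.
#' @export
runMcmc <- function(data = NULL, priors = priorConfig(), nSweeps = 4000,
                    burninFrac = 0.1, thin = 2, seed = NULL,
                    treeMode = c("sampled", "fixed"), tree = NULL,
                    weights = NULL, correction = TRUE, beta = 1,
                    init = NULL, logBranchRates = FALSE,
                    nTipsPrior = 10, nPartitionsPrior = 2) {
  treeMode <- match.arg(treeMode)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is(priors, "PriorConfig"))

  # ---- initial tree ----
  tr <- NULL
  if (!is.null(init$tree))
    tr <- if (is(init$tree, "TimeTree")) phyloToArrays(init$tree@phy) else init$tree
  else if (!is.null(tree)) tr <- phyloToArrays(tree@phy)
  ntip <- if (!is.null(tr)) tr$ntip else if (!is.null(data)) nrow(data@values) else nTipsPrior

  # ---- data preparation ----
  if (!is.null(data)) {
    stopifnot(is(data, "CognateMatrix"))
    if (anyNA(data@values)) stop("missing data is not supported")
    v <- data@values
    if (!is.null(tr)) {
      if (!setequal(rownames(v), tr$tipLabels)) stop("tree/data tip mismatch")
      v <- v[tr$tipLabels, , drop = FALSE]
    }
    meanings <- unique(data@partition)
    k <- length(meanings)
    pats <- vector("list", k); cnts <- vector("list", k); nCols <- integer(k)
    for (i in seq_len(k)) {
      cols <- v[, data@partition == meanings[i], drop = FALSE]
      if (correction && any(colSums(cols) == 0))
        stop("correction requires ascertained data")
      cp <- compressPatterns(cols)
      pats[[i]] <- cbind(cp$patterns, 0L)
      cnts[[i]] <- cp$counts
      nCols[i] <- ncol(cols)
    }
  } else {
    k <- nPartitionsPrior
    pats <- NULL
  }
  if (is.null(weights)) weights <- rep(1, k)
  stopifnot(length(weights) == k, all(weights > 0))

  # ---- initial state ----
  st <- drawFromPriors(priors, k, weights)
  lambda <- init$lambda %||% st$lambda
  alpha <- init$alpha %||% st$params@alpha
  s <- init$s %||% st$params@s
  piP <- init$piPresent %||% st$params@piObs[2]
  sigma <- init$sigma %||% st$sigma
  m <- init$m %||% st$rates@m
  if (is.null(tr)) tr <- simulateYuleArrays(lambda, ntip)
  nodeRate <- init$nodeRate %||% {
    nr <- numeric(tr$nnode)
    nr[tr$parent != 0L] <- rBranchRates(sum(tr$parent != 0L), sigma)
    nr
  }
  nonroot <- tr$parent != 0L

  # ---- cached quantities ----
  po <- postorderInfo(tr)
  dur <- edgeDurations(tr)
  durMu <- dur * priors@mu
  cu0 <- covQRFBeast(alpha, s, piP)
  q <- cu0$q; rf <- cu0$rf
  covUpdate <- covQRFBeast
  allLL <- function(q, rf) {
    if (is.null(pats)) return(numeric(k))
    as.numeric(cppPartitionLogLik(pats, cnts, po$children, po$internalIdx,
                                  durMu * nodeRate, m, q, rf, correction,
                                  nCols))
  }
  partLL <- function(i, q, rf) {
    if (is.null(pats)) return(0)
    cppPartitionLogLik(pats[i], cnts[i], po$children, po$internalIdx,
                       durMu * nodeRate, m[i], q, rf, correction,
                       nCols[i])[1]
  }
  ll <- allLL(q, rf)

  # operator step sizes, adapted during burn-in
  tune <- c(alpha = 0.15, s = 0.8, pi = 0.08, sigma = 0.8, sigJ = 0.5,
            lambda = 0.8, m = 0.3 * mean(weights), br = 0.7, root = 0.4,
            scale = 0.25, upd = 0.4)
  nAcc <- nTry <- setNames(numeric(14),
    c(names(tune), "age", "narrow", "wide"))
  nBurn <- ceiling(burninFrac * nSweeps)
  nBr <- min(2L * ntip - 2L, max(3L, ceiling((2 * ntip - 2) / 2.5)))

  # the delta exchange transfers delta / w_i, so with cognate-count weights
  # its useful step sizes are on the scale of the weights themselves
  tuneMax <- c(alpha = 1, s = 5, pi = 0.5, sigma = 5, sigJ = 5, lambda = 5,
               m = 10 * sum(weights), br = 5, root = 5, scale = 5, upd = 5)
  adapt <- function(op, acc) {
    if (sweep <= nBurn && op %in% names(tune)) {
      tune[op] <<- tune[op] * exp(0.05 * ((if (acc) 1 else 0) - 0.3))
      tune[op] <<- min(max(tune[op], 1e-3), tuneMax[op])
    } else {
      nTry[op] <<- nTry[op] + 1
      if (acc) nAcc[op] <<- nAcc[op] + 1
    }
  }

  # records
  recIdx <- seq.int(nBurn + 1, nSweeps)
  recIdx <- recIdx[(recIdx - nBurn - 1) %% thin == 0]
  nRec <- length(recIdx)
  cn <- c("lambda", "alpha", "s", "piPresent", "sigma",
          paste0("m", seq_len(k)), "treeHeight", "treeLength", "tipRate1",
          "logLik", "logPrior")
  if (logBranchRates)
    cn <- c(cn, paste0("rate_", which(nonroot)))
  out <- matrix(NA_real_, nRec, length(cn), dimnames = list(NULL, cn))
  cladeEnv <- new.env(hash = TRUE)
  nCladeSamples <- 0L
  recRow <- 0L

  logPriorCur <- function() logPriorArrays(lambda, alpha, s, piP, sigma, m,
                                           weights, tr, nodeRate, priors)

  for (sweep in seq_len(nSweeps)) {
    ## covarion parameters (full likelihood)
    for (op in c("alpha", "s", "pi")) {
      if (op == "alpha") {
        prop <- reflect(alpha + runif(1, -tune["alpha"], tune["alpha"]), 0, 1)
        cu <- covUpdate(prop, s, piP)
        llp <- allLL(cu$q, cu$rf)
        logr <- beta * (sum(llp) - sum(ll))
        if (mhAccept(logr)) { alpha <- prop; q <- cu$q; rf <- cu$rf; ll <- llp; adapt("alpha", TRUE) } else adapt("alpha", FALSE)
      } else if (op == "s") {
        cc <- exp(runif(1, -tune["s"], tune["s"]))
        prop <- s * cc
        cu <- covUpdate(alpha, prop, piP)
        llp <- allLL(cu$q, cu$rf)
        logr <- beta * (sum(llp) - sum(ll)) +
          dexp(prop, priors@sRate, log = TRUE) - dexp(s, priors@sRate, log = TRUE) +
          log(cc)
        if (mhAccept(logr)) { s <- prop; q <- cu$q; rf <- cu$rf; ll <- llp; adapt("s", TRUE) } else adapt("s", FALSE)
      } else {
        prop <- reflect(piP + runif(1, -tune["pi"], tune["pi"]), 1e-6, 1 - 1e-6)
        cu <- covUpdate(alpha, s, prop)
        llp <- allLL(cu$q, cu$rf)
        logr <- beta * (sum(llp) - sum(ll)) +
          dbeta(prop, priors@piObsShape1, priors@piObsShape2, log = TRUE) -
          dbeta(piP, priors@piObsShape1, priors@piObsShape2, log = TRUE)
        if (mhAccept(logr)) { piP <- prop; q <- cu$q; rf <- cu$rf; ll <- llp; adapt("pi", TRUE) } else adapt("pi", FALSE)
      }
    }

    ## sigma (prior-only: exponential prior + branch-rate lognormal)
    {
      cc <- exp(runif(1, -tune["sigma"], tune["sigma"]))
      prop <- sigma * cc
      logr <- dexp(prop, priors@sigmaRate, log = TRUE) -
        dexp(sigma, priors@sigmaRate, log = TRUE) +
        sum(dlnorm(nodeRate[nonroot], -prop^2 / 2, prop, log = TRUE)) -
        sum(dlnorm(nodeRate[nonroot], -sigma^2 / 2, sigma, log = TRUE)) +
        log(cc)
      if (mhAccept(logr)) { sigma <- prop; adapt("sigma", TRUE) } else adapt("sigma", FALSE)
    }

    ## joint non-centred (sigma, branch rates) scale: sigma is rescaled while
    ## the standardised log-rates are held fixed; the lognormal prior terms
    ## cancel against the Jacobian, leaving the sigma prior, log c, and the
    ## likelihood change
    for (rep4 in 1:3) {
      cc <- exp(runif(1, -tune["sigJ"], tune["sigJ"]))
      propS <- sigma * cc
      oldR <- nodeRate
      u <- (log(nodeRate[nonroot]) + sigma^2 / 2) / sigma
      nodeRate[nonroot] <- exp(propS * u - propS^2 / 2)
      llp <- allLL(q, rf)
      logr <- beta * (sum(llp) - sum(ll)) +
        dexp(propS, priors@sigmaRate, log = TRUE) -
        dexp(sigma, priors@sigmaRate, log = TRUE) + log(cc)
      if (mhAccept(logr)) { sigma <- propS; ll <- llp; adapt("sigJ", TRUE) }
      else { nodeRate <- oldR; adapt("sigJ", FALSE) }
    }

    ## lambda (prior-only: lognormal prior + Yule density)
    {
      cc <- exp(runif(1, -tune["lambda"], tune["lambda"]))
      prop <- lambda * cc
      L <- sum(dur)
      logr <- dlnorm(prop, priors@lambdaMeanlog, priors@lambdaSdlog, log = TRUE) -
        dlnorm(lambda, priors@lambdaMeanlog, priors@lambdaSdlog, log = TRUE) +
        (ntip - 1) * (log(prop) - log(lambda)) - (prop - lambda) * L +
        log(cc)
      if (mhAccept(logr)) { lambda <- prop; adapt("lambda", TRUE) } else adapt("lambda", FALSE)
    }

    ## partition rates: weighted delta exchange
    if (k >= 2) {
      pr <- deltaExchangeRaw(m, weights, tune["m"])
      if (pr$valid) {
        ij <- which(pr$m != m)
        mOld <- m
        m <- pr$m
        llp <- ll
        for (i in ij) llp[i] <- partLL(i, q, rf)
        logr <- beta * (sum(llp[ij]) - sum(ll[ij])) +
          dWeightedDirichletLog(pr$m, weights, priors@dirichletAlpha) -
          dWeightedDirichletLog(mOld, weights, priors@dirichletAlpha)
        if (mhAccept(logr)) { ll <- llp; adapt("m", TRUE) }
        else { m <- mOld; adapt("m", FALSE) }
      } else adapt("m", FALSE)
    }

    ## branch rates: single-branch log-scale moves
    brIds <- sample(which(nonroot), nBr)
    for (v in brIds) {
      cc <- exp(runif(1, -tune["br"], tune["br"]))
      old <- nodeRate[v]
      nodeRate[v] <- old * cc
      llp <- allLL(q, rf)
      logr <- beta * (sum(llp) - sum(ll)) +
        dlnorm(nodeRate[v], -sigma^2 / 2, sigma, log = TRUE) -
        dlnorm(old, -sigma^2 / 2, sigma, log = TRUE) + log(cc)
      if (mhAccept(logr)) { ll <- llp; adapt("br", TRUE) }
      else { nodeRate[v] <- old; adapt("br", FALSE) }
    }

    ## tree moves
    if (treeMode == "sampled") {
      internalNR <- which(tr$parent != 0L & seq_len(tr$nnode) > ntip)
      ## two uniform node-age moves
      for (rep2 in 1:2) {
        if (!length(internalNR)) break
        v <- internalNR[sample.int(length(internalNR), 1)]
        lo <- max(tr$age[tr$kids[v, ]])
        hi <- tr$age[tr$parent[v]]
        old <- tr$age[v]
        tr$age[v] <- runif(1, lo, hi)
        durP <- edgeDurations(tr)
        durMuOld <- durMu; durMu <- durP * priors@mu
        llp <- allLL(q, rf)
        logr <- beta * (sum(llp) - sum(ll)) - lambda * (sum(durP) - sum(dur))
        if (mhAccept(logr)) { dur <- durP; ll <- llp; adapt("age", TRUE) }
        else { tr$age[v] <- old; durMu <- durMuOld; adapt("age", FALSE) }
      }
      ## root age scaler
      {
        rt <- tr$root
        lo <- max(tr$age[tr$kids[rt, ]])
        cc <- exp(runif(1, -tune["root"], tune["root"]))
        old <- tr$age[rt]
        tr$age[rt] <- lo + (old - lo) * cc
        durP <- edgeDurations(tr); durMuOld <- durMu; durMu <- durP * priors@mu
        llp <- allLL(q, rf)
        logr <- beta * (sum(llp) - sum(ll)) - lambda * (sum(durP) - sum(dur)) +
          log(cc)
        if (mhAccept(logr)) { dur <- durP; ll <- llp; adapt("root", TRUE) }
        else { tr$age[rt] <- old; durMu <- durMuOld; adapt("root", FALSE) }
      }
      ## whole-tree scaler
      {
        cc <- exp(runif(1, -tune["scale"], tune["scale"]))
        oldAges <- tr$age
        ints <- seq_len(tr$nnode) > ntip
        tr$age[ints] <- tr$age[ints] * cc
        durP <- edgeDurations(tr); durMuOld <- durMu; durMu <- durP * priors@mu
        llp <- allLL(q, rf)
        logr <- beta * (sum(llp) - sum(ll)) - lambda * (sum(durP) - sum(dur)) +
          (ntip - 1) * log(cc)
        if (mhAccept(logr)) { dur <- durP; ll <- llp; adapt("scale", TRUE) }
        else { tr$age <- oldAges; durMu <- durMuOld; adapt("scale", FALSE) }
      }
      ## upDown: scale ages up and branch rates down; the effective branch
      ## lengths (duration x rate) are exactly invariant, so the likelihood
      ## does not change and only the priors and the Jacobian enter
      for (rep3 in 1:2) {
        cc <- exp(runif(1, -tune["upd"], tune["upd"]))
        ints <- seq_len(tr$nnode) > ntip
        oldAges <- tr$age; oldR <- nodeRate
        tr$age[ints] <- tr$age[ints] * cc
        nodeRate[nonroot] <- nodeRate[nonroot] / cc
        durP <- edgeDurations(tr)
        logr <- -lambda * (cc - 1) * sum(dur) +
          sum(dlnorm(nodeRate[nonroot], -sigma^2 / 2, sigma, log = TRUE)) -
          sum(dlnorm(oldR[nonroot], -sigma^2 / 2, sigma, log = TRUE)) -
          (ntip - 1) * log(cc)
        if (mhAccept(logr)) {
          dur <- durP; durMu <- durP * priors@mu
          adapt("upd", TRUE)
        } else {
          tr$age <- oldAges; nodeRate <- oldR
          adapt("upd", FALSE)
        }
      }
      ## narrow exchange
      if (ntip >= 3) {
        cand <- which(tr$parent != 0L & seq_len(tr$nnode) > ntip)
        if (length(cand)) {
          p <- cand[sample.int(length(cand), 1)]
          gp <- tr$parent[p]
          u <- setdiff(tr$kids[gp, ], p)
          cidx <- sample.int(2, 1)
          ch <- tr$kids[p, cidx]
          if (tr$age[u] < tr$age[p]) {
            oldTr <- tr
            tr$kids[gp, tr$kids[gp, ] == u] <- ch
            tr$kids[p, cidx] <- u
            tr$parent[ch] <- gp
            tr$parent[u] <- p
            poP <- postorderInfo(tr)
            durP <- edgeDurations(tr)
            poOld <- po; durMuOld <- durMu
            po <- poP; durMu <- durP * priors@mu
            llp <- allLL(q, rf)
            logr <- beta * (sum(llp) - sum(ll)) - lambda * (sum(durP) - sum(dur))
            if (mhAccept(logr)) { dur <- durP; ll <- llp; adapt("narrow", TRUE) }
            else { tr <- oldTr; po <- poOld; durMu <- durMuOld; adapt("narrow", FALSE) }
          } else adapt("narrow", FALSE)
        }
      }
      ## wide exchange
      if (ntip >= 4) {
        nr <- which(tr$parent != 0L)
        ab <- sample(nr, 2)
        a <- ab[1]; b <- ab[2]
        pa <- tr$parent[a]; pb <- tr$parent[b]
        ok <- pa != pb && !isAncestor(tr, a, b) && !isAncestor(tr, b, a) &&
          tr$age[a] < tr$age[pb] && tr$age[b] < tr$age[pa]
        if (ok) {
          oldTr <- tr
          tr$kids[pa, tr$kids[pa, ] == a] <- b
          tr$kids[pb, tr$kids[pb, ] == b] <- a
          tr$parent[a] <- pb; tr$parent[b] <- pa
          poP <- postorderInfo(tr)
          durP <- edgeDurations(tr)
          poOld <- po; durMuOld <- durMu
          po <- poP; durMu <- durP * priors@mu
          llp <- allLL(q, rf)
          logr <- beta * (sum(llp) - sum(ll)) - lambda * (sum(durP) - sum(dur))
          if (mhAccept(logr)) { dur <- durP; ll <- llp; adapt("wide", TRUE) }
          else { tr <- oldTr; po <- poOld; durMu <- durMuOld; adapt("wide", FALSE) }
        } else adapt("wide", FALSE)
      }
    }

    ## record
    if (sweep > nBurn && (sweep - nBurn - 1) %% thin == 0) {
      recRow <- recRow + 1L
      row <- c(lambda, alpha, s, piP, sigma, m, tr$age[tr$root], sum(dur),
               nodeRate[1], sum(ll), logPriorCur())
      if (logBranchRates) row <- c(row, nodeRate[nonroot])
      out[recRow, ] <- row
      if (treeMode == "sampled" && ntip >= 3) {
        nCladeSamples <- nCladeSamples + 1L
        for (key in cladeKeys(tr)) {
          cur <- get0(key, envir = cladeEnv, ifnotfound = 0L)
          assign(key, cur + 1L, envir = cladeEnv)
        }
      }
    }
  }

  support <- numeric(0)
  if (nCladeSamples > 0) {
    keys <- ls(cladeEnv)
    support <- vapply(keys, function(kk) get(kk, envir = cladeEnv), 0) /
      nCladeSamples
    names(support) <- keys
  }
  accRates <- ifelse(nTry > 0, nAcc / nTry, NA_real_)
  new("PosteriorTrace", samples = as.data.frame(out), cladeSupport = support,
      acceptance = accRates, burninFrac = burninFrac, nSweeps = nRec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# NaN-safe Metropolis accept: a NaN ratio (e.g. -Inf minus -Inf from a
# numerically degenerate proposal) counts as a rejection
mhAccept <- function(logr) !is.nan(logr) && log(runif(1)) < logr

isAncestor <- function(tr, a, b) {
  # is a an ancestor of b?
  v <- b
  while (tr$parent[v] != 0L) {
    v <- tr$parent[v]
    if (v == a) return(TRUE)
  }
  FALSE
}
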