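#' Highest posterior density interval
#'
#' Shortest contiguous interval containing `ceiling(mass * N)` of the sorted
#' samples.
#'
#' @param samples Numeric vector (>= 2 values).
#' @param mass Probability mass (default 0.95).
#' @return Numeric `c(low, high)`.
#' @export
hpdInterval <- function(samples, mass = 0.95) {
  n <- length(samples)
  if (n < 2) stop("need at least two samples")
  x <- sort(samples)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  i <- which.min(x[(k):n] - x[seq_len(n - k + 1)])
  c(x[i], x[i + k - 1])
}

#' HPD coverage across SBC replicates
#'
#' Fraction of replicates whose 95% HPD interval contains the generating
#' value, with an exact binomial confidence interval. For a well-calibrated
#' analysis this should be consistent with the nominal mass.
#'
#' @param sbc An [SBCResult-class] object.
#' @param parameter Parameter name (column of the rank/truth tables);
#'   default all.
#' @param ciLevel Level of the exact binomial interval.
#' @return Data frame with parameter, n, covered, fraction, ciLow, ciHigh.
#' @export
coverage <- function(sbc, parameter = NULL, ciLevel = 0.95) {
  stopifnot(is(sbc, "SBCResult"))
  pars <- parameter %||% colnames(sbc@ranks)
  if (!all(pars %in% colnames(sbc@trueValues))) stop("unknown parameter")
  do.call(rbind, lapply(pars, function(p) {
    inside <- sbc@trueValues[[p]] >= sbc@hpdLow[[p]] &
      sbc@trueValues[[p]] <= sbc@hpdHigh[[p]]
    n <- length(inside)
    bt <- binom.test(sum(inside), n, conf.level = ciLevel)
    data.frame(parameter = p, n = n, covered = sum(inside),
               fraction = sum(inside) / n,
               ciLow = bt$conf.int[1], ciHigh = bt$conf.int[2])
  }))
}

# rank of the true value among L posterior draws; ties broken uniformly
pitRank <- function(draws, true) {
  below <- sum(draws < true)
  ties <- sum(draws == true)
  if (ties > 0) below <- below + sample.int(ties + 1, 1) - 1L
  below
}

#' Normalised PIT ranks of the true values
#'
#' Rank of each generating value among its replicate's thinned posterior
#' draws, normalised to [0, 1] (the probability integral transform). Under a
#' correctly implemented analysis these are uniform.
#'
#' @param sbc An [SBCResult-class] object.
#' @param parameter Parameter name.
#' @return Numeric vector of ranks in [0, 1].
#' @export
pitRanks <- function(sbc, parameter) {
  stopifnot(is(sbc, "SBCResult"))
  if (sbc@rankL < 10) warning("fewer than 10 posterior draws per rank; ranks are coarse")
  sbc@ranks[[parameter]] / sbc@rankL
}

withFixedSeed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' ECDF difference curve with simultaneous confidence bands
#'
#' Empirical CDF of the PIT ranks minus the uniform diagonal, with
#' simultaneous bands calibrated by Monte Carlo under uniformity: the
#' pointwise binomial envelope level is adjusted until the probability that
#' a uniform sample escapes the envelope anywhere on the grid equals
#' `1 - level`. The curve passes when it stays inside the bands everywhere.
#'
#' @param ranks Normalised ranks in [0, 1].
#' @param level Simultaneous confidence level (default 0.95).
#' @param gridN Number of evaluation points (default `min(n, 50)`).
#' @param nMc Monte Carlo replicates for band calibration.
#' @param bandSeed Internal seed for the calibration draws (the global RNG
#'   state is preserved).
#' @return List with `x`, `diff` (ECDF minus diagonal), `lower`, `upper`
#'   (band limits on the difference scale), and `pass`.
#' @export
ecdfDifference <- function(ranks, level = 0.95, gridN = NULL, nMc = 1000,
                           bandSeed = 1) {
  stopifnot(all(ranks >= 0 & ranks <= 1))
  n <- length(ranks)
  J <- gridN %||% min(n, 50)
  grid <- seq_len(J) / J
  countP <- function(r) vapply(grid, function(t) sum(r <= t), 0)
  pOf <- function(cnt) {
    pmin(1, 2 * pmin(stats::pbinom(cnt, n, grid),
                     1 - stats::pbinom(cnt - 1, n, grid)))
  }
  minP <- withFixedSeed(bandSeed, {
    u <- matrix(runif(nMc * n), n, nMc)
    apply(u, 2, function(col) min(pOf(countP(col))))
  })
  thr <- as.numeric(quantile(minP, 1 - level, type = 1))
  lower <- upper <- numeric(J)
  for (j in seq_len(J)) {
    cand <- 0:n
    p <- pmin(1, 2 * pmin(stats::pbinom(cand, n, grid[j]),
                          1 - stats::pbinom(cand - 1, n, grid[j])))
    ok <- which(p > thr)
    lower[j] <- (min(ok) - 1) / n - grid[j]
    upper[j] <- (max(ok) - 1) / n - grid[j]
  }
  cnt <- countP(ranks)
  diffs <- cnt / n - grid
  pass <- min(pOf(cnt)) > thr
  list(x = grid, diff = diffs, lower = lower, upper = upper, pass = pass,
       level = level, threshold = thr, n = n)
}

#' Effective sample size by initial positive sequence truncation
#'
#' `N / (1 + 2 * sum(rho_k))`, with the autocorrelation sum truncated at the
#' first non-positive pair of consecutive autocorrelations.
#'
#' @param chain Numeric vector (length >= 10).
#' @return Effective sample size (capped at N; a constant chain returns N
#'   with a warning).
#' @export
essChain <- function(chain) {
  n <- length(chain)
  if (n < 10) stop("chain too short for an ESS estimate")
  if (stats::sd(chain) == 0) {
    warning("constant chain; ESS undefined, returning N")
    return(n)
  }
  rho <- as.vector(acf(chain, lag.max = min(n - 1, 2000), plot = FALSE,
                       demean = TRUE)$acf)[-1]
  tau <- 1
  i <- 1
  while (i + 1 <= length(rho)) {
    g <- rho[i] + rho[i + 1]
    if (g <= 0) break
    tau <- tau + 2 * g
    i <- i + 2
  }
  min(n, n / tau)
}

# weighted pool-adjacent-violators: isotonic fit of y on x with weights
pavFit <- function(x, y, w = rep(1, length(x))) {
  o <- order(x)
  x <- x[o]; y <- y[o]; w <- w[o]
  ux <- unique(x)
  if (length(ux) < length(x)) {
    agg <- function(v) vapply(ux, function(u) sum(v[x == u]), 0)
    wy <- agg(w * y); ww <- agg(w)
    y <- wy / ww; w <- ww; x <- ux
  }
  # stack of blocks: value, weight, count
  val <- numeric(0); wt <- numeric(0); cnt <- integer(0)
  for (i in seq_along(y)) {
    val <- c(val, y[i]); wt <- c(wt, w[i]); cnt <- c(cnt, 1L)
    while (length(val) > 1 && val[length(val) - 1] > val[length(val)]) {
      l <- length(val)
      nv <- (val[l - 1] * wt[l - 1] + val[l] * wt[l]) / (wt[l - 1] + wt[l])
      val <- c(val[seq_len(l - 2)], nv)
      wt <- c(wt[seq_len(l - 2)], wt[l - 1] + wt[l])
      cnt <- c(cnt[seq_len(l - 2)], cnt[l - 1] + cnt[l])
    }
  }
  fit <- rep(val, cnt)
  list(x = x, fit = fit)
}

#' Clade-support reliability (conditional event probability)
#'
#' Pools posterior clades across SBC replicates and estimates the
#' conditional event probability (CEP) -- the probability that a clade is in
#' the true tree given its posterior support -- by isotonic (pool adjacent
#' violators) regression of the true-tree indicator on the support value,
#' with bootstrap consistency bands. Under calibrated clade probabilities
#' the curve lies on the diagonal: clades with support X are true X of the
#' time.
#'
#' @param clades Data frame with columns `support` (posterior probability)
#'   and `inTrue` (0/1), e.g. the `clades` slot of an [SBCResult-class].
#' @param nBoot Bootstrap replicates for the bands.
#' @param bandLevel Band level (default 0.90).
#' @param bootSeed Internal seed for resampling.
#' @return List with the PAV curve (`support`, `cep`), a function
#'   `cepAt(p)`, bootstrap bands at a probability grid, and a histogram of
#'   support values.
#' @export
cladeReliability <- function(clades, nBoot = 200, bandLevel = 0.90,
                             bootSeed = 1) {
  if (!nrow(clades)) stop("no clades to pool (fixed-tree traces?)")
  fit <- pavFit(clades$support, as.numeric(clades$inTrue))
  cepAt <- stats::approxfun(fit$x, fit$fit, method = "constant", rule = 2,
                            ties = "ordered")
  grid <- seq(0.05, 0.95, by = 0.05)
  boot <- withFixedSeed(bootSeed, {
    vapply(seq_len(nBoot), function(b) {
      idx <- sample.int(nrow(clades), replace = TRUE)
      f <- pavFit(clades$support[idx], as.numeric(clades$inTrue[idx]))
      stats::approxfun(f$x, f$fit, method = "constant", rule = 2,
                       ties = "ordered")(grid)
    }, numeric(length(grid)))
  })
  a <- (1 - bandLevel) / 2
  list(support = fit$x, cep = fit$fit, cepAt = cepAt,
       bandGrid = grid,
       bandLow = apply(boot, 1, quantile, probs = a),
       bandHigh = apply(boot, 1, quantile, probs = 1 - a),
       histogram = graphics::hist(clades$support, breaks = seq(0, 1, 0.1),
                                  plot = FALSE))
}
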