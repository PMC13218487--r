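#' Build the covarion instantaneous rate matrix
#'
#' Constructs the 4x4 rate matrix of the binary covarion process over states
#' (absent-fast, present-fast, absent-slow, present-slow). Substitutions
#' (absent <-> present) happen only within a hidden class, at rate
#' `piObs[dest]` in the fast class and `alpha * piObs[dest]` in the slow
#' class; switches change only the hidden class, at rate `s` in `beast` mode,
#' `s * piHidden[dest]` in `reversible` mode, and `sFast` / `sSlow` in
#' `tuffley_steel` mode. Simultaneous changes of both the observed state and
#' the hidden class have rate zero.
#'
#' @param params A [CovarionParams-class] object.
#' @param normalize If TRUE (default), rescale so the equilibrium rate of
#'   observable (absent <-> present) events is one per unit time, hidden
#'   switches excluded; branch lengths are then expected substitutions per
#'   cognate.
#' @return A [RateMatrix-class] object.
#' @examples
#' q <- buildQMatrix(covarionParams(alpha = 0.5, s = 1, piObs = c(0.3, 0.7)))
#' rowSums(qMatrix(q))   # zeros
#' @export
buildQMatrix <- function(params, normalize = TRUE) {
  stopifnot(is(params, "CovarionParams"))
  validObject(params)
  po <- params@piObs
  ph <- params@piHidden
  a <- params@alpha
  sw <- switch(params@mode,
    beast = c(fs = params@s, sf = params@s),
    reversible = c(fs = params@s * ph[2], sf = params@s * ph[1]),
    tuffley_steel = c(fs = params@sFast, sf = params@sSlow))
  if (any(!is.finite(sw))) stop("non-finite switch rates")
  q <- matrix(0, 4, 4, dimnames = list(COVARION_STATES, COVARION_STATES))
  # within-class substitutions
  q[1, 2] <- po[2]; q[2, 1] <- po[1]          # fast class
  q[3, 4] <- a * po[2]; q[4, 3] <- a * po[1]  # slow class
  # hidden-class switches (observed state unchanged)
  q[1, 3] <- sw["fs"]; q[2, 4] <- sw["fs"]
  q[3, 1] <- sw["sf"]; q[4, 2] <- sw["sf"]
  diag(q) <- -rowSums(q)
  if (normalize) {
    pi4 <- rootFrequencies(params)
    # equilibrium flux of observable events only
    flux <- pi4[1] * q[1, 2] + pi4[2] * q[2, 1] + pi4[3] * q[3, 4] + pi4[4] * q[4, 3]
    if (flux <= 0) stop("degenerate parameters: zero observable flux")
    q <- q / flux
  }
  new("RateMatrix", q = q, stateOrder = COVARION_STATES, normalized = normalize)
}

#' Extract the numeric rate matrix
#' @param q A [RateMatrix-class] object.
#' @export
qMatrix <- function(q) q@q

#' Transition probability matrix
#'
#' Matrix exponential `expm(Q t)` of the covarion rate matrix, computed by a
#' dense general-purpose routine (the beast parameterisation is not
#' reversible in general, so no eigendecomposition is assumed).
#'
#' @param q A [RateMatrix-class] object or a square rate matrix.
#' @param t Branch length in expected-substitution units; must be >= 0.
#' @return Stochastic matrix of the same dimension.
#' @export
transitionProbabilities <- function(q, t) {
  if (is(q, "RateMatrix")) q <- q@q
  if (!is.finite(t) || t < 0) stop("t must be a non-negative branch length")
  p <- cppExpmat(q, t)
  dimnames(p) <- dimnames(q)
  p
}

# fast path for the sampler: beast-mode normalized Q and root frequencies
# without S4 construction; must agree with buildQMatrix (tested)
covQRFBeast <- function(alpha, s, piP) {
  p0 <- 1 - piP
  q <- matrix(0, 4, 4)
  q[1, 2] <- piP; q[2, 1] <- p0
  q[3, 4] <- alpha * piP; q[4, 3] <- alpha * p0
  q[1, 3] <- q[2, 4] <- q[3, 1] <- q[4, 2] <- s
  diag(q) <- -rowSums(q)
  flux <- p0 * piP * (1 + alpha)
  list(q = q / flux, rf = c(p0, piP, p0, piP) / 2)
}

#' Root state frequencies
#'
#' The root (and equilibrium) distribution over the four covarion states:
#' the outer product of the observed-state and hidden-class frequencies, in
#' state order (absent-fast, present-fast, absent-slow, present-slow).
#'
#' @param params A [CovarionParams-class] object.
#' @return Numeric 4-vector summing to one.
#' @export
rootFrequencies <- function(params) {
  stopifnot(is(params, "CovarionParams"))
  po <- params@piObs
  ph <- params@piHidden
  out <- c(po[1] * ph[1], po[2] * ph[1], po[1] * ph[2], po[2] * ph[2])
  names(out) <- COVARION_STATES
  out
}
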