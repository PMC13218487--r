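// Pruning likelihood for the binary covarion process.
//
// States are ordered (absent-fast, present-fast, absent-slow, present-slow).
// Tips carry observed 0/1 data only; the hidden rate class is marginalised by
// giving observed 0 the partial (1,0,1,0) and observed 1 the partial (0,1,0,1).
// Per-pattern scaling keeps partials in range at very low rates.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::export]]
arma::mat cppExpmat(const arma::mat& Q, double t) {
  return arma::expmat(Q * t);
}

// Corrected log likelihood of several partitions in one call (the sampler's
// inner loop). elenBase holds duration * mu * branchRate per node; partition
// i uses elenBase * m[i]. Each pattern matrix must carry the all-absent
// pattern as its LAST column (used for the ascertainment correction); counts
// cover only the observed patterns. When Q is reversible with respect to
// rootFreq the per-edge exponentials use one symmetric eigendecomposition;
// otherwise a dense expmat per edge. Partials are rescaled only when they
// leave the comfortable double range.
// [[Rcpp::export]]
NumericVector cppPartitionLogLik(const List& patList, const List& cntList,
                                 const IntegerMatrix& children,
                                 const IntegerVector& internalIdx,
                                 const NumericVector& elenBase,
                                 const NumericVector& m,
                                 const arma::mat& Q,
                                 const arma::vec& rootFreq,
                                 const bool correct,
                                 const IntegerVector& nCols) {
  const int k = patList.size();
  const int nnode = elenBase.size();
  const int nint = internalIdx.size();
  const int root = internalIdx[nint - 1];

  const arma::vec d = arma::sqrt(rootFreq);
  const arma::mat S = arma::diagmat(d) * Q * arma::diagmat(1.0 / d);
  const bool sym = arma::approx_equal(S, S.t(), "absdiff", 1e-9);
  arma::vec ev; arma::mat V, Amat, Bmat;
  if (sym) {
    arma::eig_sym(ev, V, (S + S.t()) / 2);
    ev.transform([](double x) { return x > 0 ? 0.0 : x; }); // Q spectrum <= 0
    Amat = arma::diagmat(1.0 / d) * V;
    Bmat = V.t() * arma::diagmat(d);
  }

  NumericVector out(k);
  std::vector<arma::mat> P(nnode);
  for (int i = 0; i < k; ++i) {
    const IntegerMatrix patterns = patList[i];
    const NumericVector cnt = cntList[i];
    const int ntip = patterns.nrow();
    const int npat = patterns.ncol();
    for (int v = 0; v < nnode; ++v) {
      if (v == root) continue;
      const double t = elenBase[v] * m[i];
      P[v] = sym ? arma::mat(Amat * arma::diagmat(arma::exp(ev * t)) * Bmat)
                 : arma::mat(arma::expmat(Q * t));
    }
    std::vector<arma::mat> part(nnode);
    arma::vec scale(npat, arma::fill::zeros);
    for (int kk = 0; kk < nint; ++kk) {
      const int v = internalIdx[kk];
      arma::mat L(4, npat, arma::fill::ones);
      for (int cidx = 0; cidx < 2; ++cidx) {
        const int c = children(kk, cidx);
        if (c < ntip) {
          const arma::vec M0 = P[c].col(0) + P[c].col(2);
          const arma::vec M1 = P[c].col(1) + P[c].col(3);
          for (int p = 0; p < npat; ++p)
            L.col(p) %= (patterns(c, p) == 1) ? M1 : M0;
        } else {
          L %= (P[c] * part[c]);
          part[c].reset();
        }
      }
      if (L.min() < 1e-120) {
        const arma::rowvec mx = arma::max(L, 0);
        for (int p = 0; p < npat; ++p)
          if (mx[p] > 0) {
            L.col(p) /= mx[p];
            scale[p] += std::log(mx[p]);
          }
      }
      part[v] = L;
    }
    double ll = 0;
    const arma::mat& LR = part[root];
    for (int p = 0; p < npat - 1; ++p)
      ll += cnt[p] * (std::log(arma::dot(rootFreq, LR.col(p))) + scale[p]);
    if (correct) {
      const double lp0 = std::log(arma::dot(rootFreq, LR.col(npat - 1))) +
        scale[npat - 1];
      const double p0 = std::exp(lp0);
      if (p0 >= 1 - 1e-12) Rcpp::stop("Pr(all-absent) numerically degenerate");
      ll -= nCols[i] * std::log1p(-p0);
    }
    out[i] = ll;
  }
  return out;
}

// patterns   : ntip x npat integer matrix with entries 0/1
// children   : nint x 2 matrix of 0-based node ids; row k = children of internalIdx[k]
// internalIdx: 0-based internal node ids in postorder; last entry is the root
// elen       : per-node expected-substitution length of the edge above the node
//              (entry for the root is ignored)
// [[Rcpp::export]]
NumericVector cppPatternLogLik(const IntegerMatrix& patterns,
                               const IntegerMatrix& children,
                               const IntegerVector& internalIdx,
                               const NumericVector& elen,
                               const arma::mat& Q,
                               const arma::vec& rootFreq) {
  const int ntip = patterns.nrow();
  const int npat = patterns.ncol();
  const int nnode = elen.size();
  const int nint = internalIdx.size();
  const int root = internalIdx[nint - 1];

  std::vector<arma::mat> P(nnode);
  for (int v = 0; v < nnode; ++v)
    if (v != root) P[v] = arma::expmat(Q * elen[v]);

  std::vector<arma::mat> part(nnode);
  arma::vec scale(npat, arma::fill::zeros);

  for (int k = 0; k < nint; ++k) {
    const int v = internalIdx[k];
    arma::mat L(4, npat, arma::fill::ones);
    for (int cidx = 0; cidx < 2; ++cidx) {
      const int c = children(k, cidx);
      if (c < ntip) {
        const arma::vec M0 = P[c].col(0) + P[c].col(2);
        const arma::vec M1 = P[c].col(1) + P[c].col(3);
        for (int p = 0; p < npat; ++p)
          L.col(p) %= (patterns(c, p) == 1) ? M1 : M0;
      } else {
        L %= (P[c] * part[c]);
        part[c].reset();
      }
    }
    for (int p = 0; p < npat; ++p) {
      const double mx = L.col(p).max();
      if (mx > 0 && std::isfinite(mx)) {
        L.col(p) /= mx;
        scale[p] += std::log(mx);
      }
    }
    part[v] = L;
  }

  NumericVector out(npat);
  for (int p = 0; p < npat; ++p)
    out[p] = std::log(arma::dot(rootFreq, part[root].col(p))) + scale[p];
  return out;
}
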