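// Felsenstein pruning for a four-taxon tree, vectorized over site patterns.
//
// The unrooted quartet ((1,2),(3,4)) is rooted at the ancestor u of tips 1
// and 2; v is the ancestor of tips 3 and 4 and the fifth branch joins u and
// v. By reversibility (pulley principle) the root placement does not affect
// the likelihood. Tip partials are 20 x npat matrices: a unit column for an
// observed residue, all-ones for gap/'X'/ambiguity.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat pmat(const mat& U, const mat& Ui, const vec& lambda, double t) {
  vec e = exp(lambda * t);
  mat B = Ui;
  B.each_col() %= e;
  mat P = U * B;
  P.for_each([](mat::elem_type& x) { if (x < 0) x = 0; });
  return P;
}

// Site likelihood vector averaged over GAMMA categories (equal weights).
// br: pendant branches for the four tips in pairing order, then the internal
// branch.
// [[Rcpp::export]]
arma::vec quartet_site_lik(const arma::mat& X1, const arma::mat& X2,
                           const arma::mat& X3, const arma::mat& X4,
                           const arma::vec& br,
                           const arma::mat& U, const arma::mat& Ui,
                           const arma::vec& lambda, const arma::vec& pi,
                           const arma::vec& rates) {
  const uword npat = X1.n_cols;
  vec site(npat, fill::zeros);
  for (uword k = 0; k < rates.n_elem; ++k) {
    const double r = rates[k];
    mat Lu = (pmat(U, Ui, lambda, br[0] * r) * X1) %
             (pmat(U, Ui, lambda, br[1] * r) * X2);
    mat Lv = (pmat(U, Ui, lambda, br[2] * r) * X3) %
             (pmat(U, Ui, lambda, br[3] * r) * X4);
    Lu %= pmat(U, Ui, lambda, br[4] * r) * Lv;
    site += Lu.t() * pi;
  }
  return site / static_cast<double>(rates.n_elem);
}

// Weighted total log-likelihood over compressed patterns.
// [[Rcpp::export]]
double quartet_loglik_cpp(const arma::mat& X1, const arma::mat& X2,
                          const arma::mat& X3, const arma::mat& X4,
                          const arma::vec& w, const arma::vec& br,
                          const arma::mat& U, const arma::mat& Ui,
                          const arma::vec& lambda, const arma::vec& pi,
                          const arma::vec& rates) {
  vec site = quartet_site_lik(X1, X2, X3, X4, br, U, Ui, lambda, pi, rates);
  // sites missing in all four taxa have likelihood 1; guard log(0) anyway
  site.for_each([](vec::elem_type& x) { if (x < 1e-300) x = 1e-300; });
  return dot(w, log(site));
}
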