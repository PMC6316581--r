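// Multiplicative-update NMF under the generalized Kullback-Leibler
// divergence D(V || WH). The update rules guarantee a non-increasing
// objective; an epsilon guard keeps logs and divisions finite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double EPS = 1e-12;

static double kl_div(const mat& V, const mat& WH) {
  // sum over entries of V log(V/WH) - V + WH, with 0 log 0 = 0
  double d = 0.0;
  for (uword j = 0; j < V.n_cols; ++j) {
    for (uword i = 0; i < V.n_rows; ++i) {
      const double v = V(i, j), wh = WH(i, j);
      if (v > 0.0) d += v * std::log(v / (wh + EPS)) - v + wh;
      else d += wh;
    }
  }
  return d;
}

// [[Rcpp::export]]
Rcpp::List nmf_kl_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                      int max_iter, double tol, int check_every) {
  mat WH = W * H;
  std::vector<double> trace;
  double d_prev = kl_div(V, WH);
  trace.push_back(d_prev);
  bool converged = false;
  int it = 0;
  const rowvec ones_keep; (void)ones_keep;
  for (it = 1; it <= max_iter; ++it) {
    // H update: H_aj *= sum_i W_ia V_ij/(WH)_ij / sum_i W_ia
    mat P = V / (WH + EPS);
    H %= (W.t() * P);
    colvec wsum = sum(W, 0).t();
    H.each_col() /= (wsum + EPS);
    // W update with refreshed WH
    WH = W * H;
    P = V / (WH + EPS);
    W %= (P * H.t());
    rowvec hsum = sum(H, 1).t();
    W.each_row() /= (hsum + EPS);
    WH = W * H;
    if (it % check_every == 0 || it == max_iter) {
      double d = kl_div(V, WH);
      if (!std::isfinite(d))
        Rcpp::stop("non-finite divergence at iteration %d", it);
      trace.push_back(d);
      double rel = (d_prev - d) / std::max(std::abs(d_prev), EPS);
      d_prev = d;
      if (d < 1e-14 || (rel >= 0.0 && rel < tol)) { converged = true; break; }
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("W") = W, Rcpp::Named("H") = H,
    Rcpp::Named("divergence") = trace,
    Rcpp::Named("iterations") = std::min(it, max_iter),
    Rcpp::Named("converged") = converged);
}
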