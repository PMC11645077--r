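#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gradient ascent on the pairwise-MEM log-likelihood with exact model
// moments by enumeration. S: 2^N x N spin matrix (+/-1), P: 2^N x K
// pairwise-product matrix (K = N(N-1)/2, upper triangle i < j).
// Data moments m_data (<s_i>) and c_data (<s_i s_j>) are precomputed in R.
// [[Rcpp::export]]
List fit_mem_cpp(const arma::mat& S, const arma::mat& P,
                 const arma::vec& m_data, const arma::vec& c_data,
                 double lr, double tol, int max_iter, double l2,
                 bool track) {
  const arma::uword N = S.n_cols, K = P.n_cols;
  arma::vec h(N, arma::fill::zeros), j(K, arma::fill::zeros);
  std::vector<double> ll_trace;
  if (track) ll_trace.reserve(max_iter);

  bool converged = false;
  int it = 0;
  double resid = NA_REAL;
  for (it = 0; it < max_iter; ++it) {
    arma::vec logw = S * h + P * j;            // -E(V_k)
    double m = logw.max();
    arma::vec w = arma::exp(logw - m);
    double Z = arma::accu(w);
    arma::vec p = w / Z;
    if (track) {
      double logZ = m + std::log(Z);
      ll_trace.push_back(arma::dot(m_data, h) + arma::dot(c_data, j) - logZ);
    }
    arma::vec gm = m_data - S.t() * p;
    arma::vec gc = c_data - P.t() * p;
    resid = std::max(arma::abs(gm).max(), arma::abs(gc).max());
    if (resid <= tol) { converged = true; break; }
    h += lr * gm;
    j += lr * (gc - l2 * j);
  }

  return List::create(_["h"] = h, _["j"] = j,
                      _["n_iterations"] = it,
                      _["converged"] = converged,
                      _["max_moment_residual"] = resid,
                      _["ll_trace"] = ll_trace);
}

// Single-site Gibbs sampler for the pairwise MEM. One sweep updates every
// spin once in index order; conditional log-odds of +1 at site i is
// 2 * (h_i + sum_j J_ij s_j). Uses R's RNG so set.seed() controls draws.
// [[Rcpp::export]]
IntegerMatrix gibbs_sample_cpp(const arma::vec& h, const arma::mat& J,
                               int n_samples, int burn_in, int thin) {
  const int N = h.n_elem;
  arma::vec s(N);
  for (int i = 0; i < N; ++i) s[i] = unif_rand() < 0.5 ? -1.0 : 1.0;

  IntegerMatrix out(n_samples, N);
  int kept = 0, sweep = 0;
  while (kept < n_samples) {
    for (int i = 0; i < N; ++i) {
      double field = h[i] + arma::dot(J.row(i).t(), s);
      double p1 = 1.0 / (1.0 + std::exp(-2.0 * field));
      s[i] = (unif_rand() < p1) ? 1.0 : -1.0;
    }
    ++sweep;
    if (sweep > burn_in && ((sweep - burn_in) % thin == 0)) {
      for (int i = 0; i < N; ++i) out(kept, i) = (int)s[i];
      ++kept;
    }
  }
  return out;
}
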