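// Nightly consolidation loop of the hierarchical neocortical cascade.
//
// Fresh rectified-Gaussian input is sampled at the outermost layer every
// step, propagated through one-step delay buffers, and every shortcut
// matrix W_i is updated with the trace-based STDP rule with learning
// amplitudes shrinking geometrically with the level index.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_cascade_night(const arma::mat& V_hpc, List W_list,
                       const arma::vec& a_plus, const arma::vec& a_minus,
                       double tau_stdp, double dT, int n_steps,
                       double r, double w_max) {
  const int L = W_list.size();
  const int N = V_hpc.n_rows;
  const double trace_k = dT / tau_stdp;

  std::vector<arma::mat> W(L);
  for (int i = 0; i < L; ++i) W[i] = as<arma::mat>(W_list[i]);

  // x_prev.col(i) = x_{i+1 in math} at previous step; y_prev likewise
  arma::mat x_prev(N, L, arma::fill::zeros), x_new(N, L);
  arma::mat y_prev(N, L, arma::fill::zeros), y_new(N, L);
  arma::mat xhat(N, L, arma::fill::zeros), yhat(N, L, arma::fill::zeros);
  arma::vec yhpc_prev(N, arma::fill::zeros);

  RNGScope scope;
  for (int s = 0; s < n_steps; ++s) {
    // inward chain: x_L sampled fresh, x_i = x_{i+1}(t - D)
    for (int j = 0; j < N; ++j) {
      double v = r + norm_rand() * (r / 2.0);
      x_new(j, L - 1) = v > 0 ? v : 0.0;
    }
    for (int i = 0; i < L - 1; ++i) x_new.col(i) = x_prev.col(i + 1);

    arma::vec yhpc = V_hpc.t() * x_prev.col(0);
    y_new.col(0) = 0.5 * (W[0].t() * x_prev.col(0)) + 0.5 * yhpc_prev;
    for (int i = 1; i < L; ++i)
      y_new.col(i) = 0.5 * (W[i].t() * x_prev.col(i)) + 0.5 * y_prev.col(i - 1);

    // plasticity: dW_i/dt = A+ xhat_i(t-D) y_i(t)^T + A- x_i(t-D) yhat_i(t)^T
    for (int i = 0; i < L; ++i) {
      W[i] += dT * (a_plus[i] * (xhat.col(i) * y_new.col(i).t()) +
                    a_minus[i] * (x_prev.col(i) * yhat.col(i).t()));
      W[i].clamp(0.0, w_max);
    }

    // traces track the (delayed) pre activity and current post activity
    xhat += trace_k * (x_prev - xhat);
    yhat += trace_k * (y_new - yhat);

    x_prev = x_new;
    y_prev = y_new;
    yhpc_prev = yhpc;
  }

  List out(L);
  for (int i = 0; i < L; ++i) out[i] = W[i];
  return List::create(_["W"] = out);
}
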