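// Consolidation-phase inner loop of the multi-stage hippocampal rate model.
//
// Each step draws an independent random position and object, computes the
// layered activities with a one-step transmission delay, updates the
// exponential pre/post traces and applies the trace-based STDP rule to the
// plastic shortcut matrices, clipped to [0, w_max].  Uses R's RNG so runs
// are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::vec grid_rates(const arma::vec& m, const arma::vec& theta,
                            const arma::vec& px, const arma::vec& py,
                            double rmax, double p1, double p2) {
  const int N = m.n_elem;
  arma::vec r(N);
  for (int i = 0; i < N; ++i) {
    double s = 0.0;
    for (int l = 1; l <= 3; ++l) {
      const double ang = l * M_PI / 3.0 + theta[i];
      const double kx = std::cos(ang), ky = std::sin(ang);
      s += 0.5 + std::cos(m[i] * (kx * (p1 - px[i]) + ky * (p2 - py[i])));
    }
    r[i] = rmax * (2.0 / 9.0) * s;
  }
  return r;
}

static arma::vec place_rates(const arma::vec& cx, const arma::vec& cy,
                             double rmax, double sigma,
                             double p1, double p2) {
  arma::vec d2 = arma::square(cx - p1) + arma::square(cy - p2);
  return rmax * arma::exp(-d2 / (2.0 * sigma * sigma));
}

// [[Rcpp::export]]
List cpp_hpc_consolidation(arma::mat W_ca1, arma::mat W_sub,
                           const arma::mat& V_sc, const arma::mat& V_cs,
                           const arma::vec& grid_m, const arma::vec& grid_theta,
                           const arma::vec& grid_px, const arma::vec& grid_py,
                           const arma::vec& place_cx, const arma::vec& place_cy,
                           const arma::mat& ec_obj, const arma::mat& ca3_obj,
                           double r_max, double sigma,
                           double ap_ca1, double am_ca1,
                           double ap_sub, double am_sub,
                           double tau_stdp, double dT, int n_steps,
                           double w_max,
                           bool ca1_plastic, bool sub_plastic) {
  const int N = grid_m.n_elem;
  const int twoN = 2 * N;
  const int n_obj = ec_obj.n_cols;
  const double trace_k = dT / tau_stdp;

  arma::vec x_ec(twoN), x_ca3(twoN);
  arma::vec x_ca3_prev(twoN, arma::fill::zeros);
  arma::vec y_ca1_prev(twoN, arma::fill::zeros);
  arma::vec xhat_ec(twoN, arma::fill::zeros);
  arma::vec yhat_ca1(twoN, arma::fill::zeros);
  arma::vec yhat_sub(twoN, arma::fill::zeros);

  RNGScope scope;
  for (int s = 0; s < n_steps; ++s) {
    const double p1 = unif_rand(), p2 = unif_rand();
    int o = (int)std::floor(unif_rand() * n_obj);
    if (o >= n_obj) o = n_obj - 1;

    x_ec.head(N) = grid_rates(grid_m, grid_theta, grid_px, grid_py,
                              r_max, p1, p2);
    x_ec.tail(N) = ec_obj.col(o);
    x_ca3.head(N) = place_rates(place_cx, place_cy, r_max, sigma, p1, p2);
    x_ca3.tail(N) = ca3_obj.col(o);

    arma::vec y_ca1 = W_ca1.t() * x_ec + V_sc.t() * x_ca3_prev;
    arma::vec y_sub = W_sub.t() * x_ec + V_cs.t() * y_ca1_prev;

    xhat_ec += trace_k * (x_ec - xhat_ec);
    yhat_ca1 += trace_k * (y_ca1 - yhat_ca1);
    yhat_sub += trace_k * (y_sub - yhat_sub);

    if (ca1_plastic) {
      W_ca1 += dT * (ap_ca1 * (xhat_ec * y_ca1.t()) +
                     am_ca1 * (x_ec * yhat_ca1.t()));
      W_ca1.clamp(0.0, w_max);
    }
    if (sub_plastic) {
      W_sub += dT * (ap_sub * (xhat_ec * y_sub.t()) +
                     am_sub * (x_ec * yhat_sub.t()));
      W_sub.clamp(0.0, w_max);
    }

    x_ca3_prev = x_ca3;
    y_ca1_prev = y_ca1;
  }
  return List::create(_["W_ca1"] = W_ca1, _["W_sub"] = W_sub);
}

// [[Rcpp::export]]
arma::vec cpp_grid_rates(const arma::vec& m, const arma::vec& theta,
                         const arma::vec& px, const arma::vec& py,
                         double rmax, double p1, double p2) {
  return grid_rates(m, theta, px, py, rmax, p1, p2);
}

// [[Rcpp::export]]
arma::vec cpp_place_rates(const arma::vec& cx, const arma::vec& cy,
                          double rmax, double sigma, double p1, double p2) {
  return place_rates(cx, cy, rmax, sigma, p1, p2);
}
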