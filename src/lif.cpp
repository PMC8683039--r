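// Conductance-based leaky integrate-and-fire neuron with additive STDP.
//
// Forward Euler at a fixed step dt.  Input spikes carry exact (continuous)
// times; their conductance jump is applied in the step containing them and
// their STDP pairing uses the exact times via exponentially decaying
// pre/post traces with lazy evaluation, which is equivalent to the
// all-to-all pair sum of the exponential learning window.  Postsynaptic
// spikes are detected at grid points.  A pre spike coinciding exactly with
// a post spike (dt_pair = t_pre - t_post = 0) is assigned to the
// depression branch.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_lif_stdp(IntegerVector spike_id,      // 0-based afferent index, sorted by time
                  NumericVector spike_t,       // ms, ascending
                  NumericVector w0,            // initial weights, length n_aff
                  LogicalVector plastic,       // per afferent
                  NumericVector g_max,         // per afferent bound
                  NumericVector a_plus,        // per afferent LTP jump (weight units)
                  NumericVector a_minus,       // per afferent LTD jump (positive)
                  double tau_stdp,             // ms
                  double tau_m, double v_rest, double e_syn,
                  double v_thresh, double v_reset, double t_ref,
                  double tau_syn, double dt,
                  double duration,             // ms
                  NumericVector snapshot_times,
                  bool record_v = false) {
  const int n = w0.size();
  const int n_spk = spike_id.size();
  std::vector<double> w(w0.begin(), w0.end());

  // lazy pre traces: value at time `pre_t[i]`, plus count of spikes exactly
  // at pre_t[i] (for the tie-to-depression rule)
  std::vector<double> pre_x(n, 0.0), pre_t(n, -1e18);
  std::vector<int> pre_tied(n, 0);
  double post_y = 0.0, post_t = -1e18;

  const int n_steps = (int)std::lround(duration / dt);
  const double g_decay = 1.0 - dt / tau_syn;   // forward Euler decay

  double v = v_rest, g = 0.0;
  double ref_until = -1e18;

  std::vector<double> post_times;
  NumericVector vtrace(record_v ? n_steps + 1 : 0);
  if (record_v) vtrace[0] = v;

  const int n_snap = snapshot_times.size();
  NumericMatrix snaps(n_snap, n);
  int next_snap = 0;

  int spk = 0;
  for (int step = 0; step < n_steps; ++step) {
    const double t0 = step * dt, t1 = (step + 1) * dt;

    // snapshots due at or before the start of this step
    while (next_snap < n_snap && snapshot_times[next_snap] <= t0 + 1e-9) {
      for (int i = 0; i < n; ++i) snaps(next_snap, i) = w[i];
      ++next_snap;
    }

    // input spikes with time in (t0, t1]
    while (spk < n_spk && spike_t[spk] <= t1 + 1e-12) {
      const int i = spike_id[spk];
      const double ts = spike_t[spk];
      g += w[i];
      if (plastic[i]) {
        // depression from all previous post spikes (dt_pair >= 0)
        const double y = post_y * std::exp(-(ts - post_t) / tau_stdp);
        w[i] -= a_minus[i] * y;
        if (w[i] < 0) w[i] = 0;
        if (w[i] > g_max[i]) w[i] = g_max[i];
      }
      // update the pre trace regardless (the afferent may pair later)
      const double decayed = pre_x[i] * std::exp(-(ts - pre_t[i]) / tau_stdp);
      if (ts == pre_t[i]) ++pre_tied[i]; else pre_tied[i] = 1;
      pre_x[i] = decayed + 1.0;
      pre_t[i] = ts;
      ++spk;
    }

    // membrane + conductance update
    if (t1 >= ref_until) {
      v += dt / tau_m * (v_rest - v + g * (e_syn - v));
    } else {
      v = v_reset;
    }
    g *= g_decay;
    if (g < 0) g = 0;

    if (v >= v_thresh && t1 >= ref_until) {
      // postsynaptic spike at grid time t1
      const double tp = t1;
      post_times.push_back(tp);
      for (int i = 0; i < n; ++i) {
        if (!plastic[i] || pre_t[i] < -1e17) continue;
        double x = pre_x[i] * std::exp(-(tp - pre_t[i]) / tau_stdp);
        if (pre_t[i] == tp) {
          // exact ties: those pairs belong to the depression branch
          x -= pre_tied[i];
          w[i] -= a_minus[i] * pre_tied[i];
        }
        if (x > 0) w[i] += a_plus[i] * x;
        if (w[i] < 0) w[i] = 0;
        if (w[i] > g_max[i]) w[i] = g_max[i];
      }
      post_y = post_y * std::exp(-(tp - post_t) / tau_stdp) + 1.0;
      post_t = tp;
      v = v_reset;
      ref_until = tp + t_ref;
    }

    if (record_v) vtrace[step + 1] = v;
  }

  // trailing snapshots (at or after the end)
  while (next_snap < n_snap) {
    for (int i = 0; i < n; ++i) snaps(next_snap, i) = w[i];
    ++next_snap;
  }

  List out = List::create(
    _["weights"] = NumericVector(w.begin(), w.end()),
    _["snapshots"] = snaps,
    _["snapshot_times"] = snapshot_times,
    _["post_times"] = NumericVector(post_times.begin(), post_times.end()));
  if (record_v) out["v"] = vtrace;
  return out;
}
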