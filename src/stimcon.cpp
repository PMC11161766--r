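#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Post-threshold activation dynamics. Ta is the time (ms) since the node
// last reached its activation threshold; a node that never activated sits at
// the rest branch (base inhibition). base_inhib < 0, so -3*base_inhib is a
// brief excitatory burst and +3*base_inhib a strong self-inhibition.
static inline double post_thres(double ta, double B,
                                double exc_hi, double inh_hi) {
  if (ta < exc_hi) return -3.0 * B;   // 0 <= Ta < 20: excitatory burst
  if (ta <= inh_hi) return 3.0 * B;   // 20 <= Ta <= 100: self-inhibition
  return B;                           // rest inhibition (incl. never active)
}

// Integrate the two-level node model over a fixed 1-kHz (dt_ms) grid.
//
// input_act: n_input x n_steps matrix of input-node activations (stimulus
//   pulses, already shaped by the caller).
// c_ip: n_input x n_phon connectivity; c_iw: n_input x n_word (identity for
//   the parallel topology). If hierarchical is true, the word level is driven
//   by the phoneme-level activations through c_pw (n_phon x n_word) instead
//   of directly by the input.
//
// Returns per-level activation traces (optional) and all threshold-crossing
// events (level, node, time, activation at crossing). A crossing is the step
// at which activation reaches threshold from below.
// [[Rcpp::export]]
List cpp_simulate(NumericMatrix input_act,
                  NumericMatrix c_ip,
                  NumericMatrix c_iw,
                  NumericMatrix c_pw,
                  bool hierarchical,
                  NumericVector thr_p,
                  NumericVector thr_w,
                  double osc_amp, double osc_freq, double osc_phase,
                  double base_inhib,
                  double exc_hi, double inh_hi,
                  double dt_ms,
                  bool keep_trace) {
  const int n_steps = input_act.ncol();
  const int n_input = input_act.nrow();
  const int n_phon  = thr_p.size();
  const int n_word  = thr_w.size();
  const double huge_ta = 1e12;  // sentinel: never activated

  std::vector<double> ta_p(n_phon, huge_ta), ta_w(n_word, huge_ta);
  std::vector<double> prev_p(n_phon, -1e12), prev_w(n_word, -1e12);
  std::vector<double> a_p(n_phon), a_w(n_word);

  NumericMatrix trace_p, trace_w;
  if (keep_trace) {
    trace_p = NumericMatrix(n_phon, n_steps);
    trace_w = NumericMatrix(n_word, n_steps);
  }

  std::vector<int> ev_level, ev_node;
  std::vector<double> ev_time, ev_act;

  const double w = 2.0 * M_PI * osc_freq / 1000.0;

  for (int s = 0; s < n_steps; s++) {
    const double t = s * dt_ms;
    const double osc = osc_amp * std::cos(w * t + osc_phase);

    // phoneme level
    for (int j = 0; j < n_phon; j++) {
      double drive = 0.0;
      for (int i = 0; i < n_input; i++) drive += input_act(i, s) * c_ip(i, j);
      a_p[j] = drive + post_thres(ta_p[j], base_inhib, exc_hi, inh_hi) + osc;
    }
    // word level
    for (int j = 0; j < n_word; j++) {
      double drive = 0.0;
      if (hierarchical) {
        for (int i = 0; i < n_phon; i++) drive += a_p[i] * c_pw(i, j);
      } else {
        for (int i = 0; i < n_input; i++) drive += input_act(i, s) * c_iw(i, j);
      }
      a_w[j] = drive + post_thres(ta_w[j], base_inhib, exc_hi, inh_hi) + osc;
    }

    for (int j = 0; j < n_phon; j++) {
      if (a_p[j] >= thr_p[j] && prev_p[j] < thr_p[j]) {
        ev_level.push_back(1); ev_node.push_back(j + 1);
        ev_time.push_back(t); ev_act.push_back(a_p[j]);
      }
    }
    for (int j = 0; j < n_word; j++) {
      if (a_w[j] >= thr_w[j] && prev_w[j] < thr_w[j]) {
        ev_level.push_back(2); ev_node.push_back(j + 1);
        ev_time.push_back(t); ev_act.push_back(a_w[j]);
      }
    }

    // Ta resets to 0 exactly when activation >= threshold at that step.
    for (int j = 0; j < n_phon; j++) {
      if (a_p[j] >= thr_p[j]) ta_p[j] = 0.0; else if (ta_p[j] < huge_ta) ta_p[j] += dt_ms;
      prev_p[j] = a_p[j];
      if (keep_trace) trace_p(j, s) = a_p[j];
    }
    for (int j = 0; j < n_word; j++) {
      if (a_w[j] >= thr_w[j]) ta_w[j] = 0.0; else if (ta_w[j] < huge_ta) ta_w[j] += dt_ms;
      prev_w[j] = a_w[j];
      if (keep_trace) trace_w(j, s) = a_w[j];
    }
  }

  const int n_ev = ev_level.size();
  IntegerVector lev(n_ev), node(n_ev);
  NumericVector tim(n_ev), act(n_ev);
  for (int k = 0; k < n_ev; k++) {
    lev[k] = ev_level[k]; node[k] = ev_node[k];
    tim[k] = ev_time[k]; act[k] = ev_act[k];
  }

  List out = List::create(
    _["level"] = lev, _["node"] = node, _["time_ms"] = tim,
    _["activation"] = act);
  if (keep_trace) {
    out["trace_phoneme"] = trace_p;
    out["trace_word"] = trace_w;
  }
  return out;
}
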