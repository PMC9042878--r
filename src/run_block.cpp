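#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fast inner loop for the neuromodulated network: runs `reps` synchronous
// steps of one presentation block (constant external input). Mirrors the
// reference R implementation in step_network() exactly, including the order
// in which noise values are drawn from R's RNG (7 input draws, then one draw
// per active neuron, each step).
//
// Index vectors are 1-based (R convention): act_idx are active neuron slots,
// std_rows / mod_rows are row indices of standard / modulatory presynaptic
// units in the 23-row weight matrix, mod_cols are the plastic postsynaptic
// neuron slots.
// [[Rcpp::export]]
List mm_run_block(NumericMatrix W_, NumericVector o_, NumericVector ext,
                  int reps,
                  IntegerVector act_idx, IntegerVector std_rows,
                  IntegerVector mod_rows, IntegerVector mod_cols,
                  double eta, double A, double B, double C, double D,
                  bool noise, double sigma_input, double sigma_neuron,
                  bool plastic, bool record) {
  NumericMatrix W = clone(W_);
  NumericVector o = clone(o_);
  const int n_in = 7;
  const int n_units = W.nrow();
  const int n_slots = W.ncol();
  const int n_act = act_idx.size();
  const int n_std = std_rows.size();
  const int n_mod = mod_rows.size();
  const int n_pl = mod_cols.size();

  std::vector<double> a(n_act, 0.0), m(n_act, 0.0), o_new(n_units, 0.0);
  std::vector<int> pos(n_slots, -1);  // neuron slot -> index in act_idx
  for (int k = 0; k < n_act; ++k) pos[act_idx[k] - 1] = k;

  NumericMatrix rec;
  if (record) rec = NumericMatrix(n_units, reps);

  for (int t = 0; t < reps; ++t) {
    for (int k = 0; k < n_act; ++k) {
      const int c = act_idx[k] - 1;
      double sa = 0.0, sm = 0.0;
      for (int r = 0; r < n_std; ++r) {
        const int j = std_rows[r] - 1;
        sa += W(j, c) * o[j];
      }
      for (int r = 0; r < n_mod; ++r) {
        const int j = mod_rows[r] - 1;
        sm += W(j, c) * o[j];
      }
      a[k] = sa;
      m[k] = sm;
    }
    for (int j = 0; j < n_in; ++j) {
      o_new[j] = ext[j] + (noise ? R::rnorm(0.0, sigma_input) : 0.0);
    }
    for (int j = n_in; j < n_units; ++j) o_new[j] = 0.0;
    for (int k = 0; k < n_act; ++k) {
      const double nn = noise ? R::rnorm(0.0, sigma_neuron) : 0.0;
      o_new[n_in + act_idx[k] - 1] = std::tanh(a[k] + nn);
    }
    for (int j = 0; j < n_units; ++j) o[j] = o_new[j];

    if (plastic && n_pl > 0) {
      for (int q = 0; q < n_pl; ++q) {
        const int c = mod_cols[q] - 1;
        const double g = std::tanh(m[pos[c]]) * eta;
        const double opost = o[n_in + c];
        // all incoming connections of a modulated neuron are plastic:
        // input units first, then active neurons (matches the R reference)
        for (int j = 0; j < n_in; ++j) {
          double w = W(j, c) + g * (A * o[j] * opost + B * o[j] + C * opost + D);
          W(j, c) = w > 10.0 ? 10.0 : (w < -10.0 ? -10.0 : w);
        }
        for (int k = 0; k < n_act; ++k) {
          const int j = n_in + act_idx[k] - 1;
          double w = W(j, c) + g * (A * o[j] * opost + B * o[j] + C * opost + D);
          W(j, c) = w > 10.0 ? 10.0 : (w < -10.0 ? -10.0 : w);
        }
      }
    }
    if (record) {
      for (int j = 0; j < n_units; ++j) rec(j, t) = o[j];
    }
  }

  NumericVector a_full(n_slots, 0.0), m_full(n_slots, 0.0);
  for (int k = 0; k < n_act; ++k) {
    a_full[act_idx[k] - 1] = a[k];
    m_full[act_idx[k] - 1] = m[k];
  }

  List out = List::create(_["weights"] = W, _["outputs"] = o,
                          _["activation_sums"] = a_full,
                          _["modulation_sums"] = m_full);
  if (record) out["record"] = rec;
  return out;
}
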