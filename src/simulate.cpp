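#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Synchronous Boolean update over a gate list.
// Gates are flattened: gate g has output node gate_out[g] (0-based) and
// literals gate_in[k], gate_sign[k] for k in [gate_ptr[g], gate_ptr[g+1]).
// A gate fires iff every +1 literal is 1 and every -1 literal is 0; a node
// with at least one selected gate becomes the OR over its firing gates,
// a node with no selected gate keeps its value. Clamps (-1 free, 0/1
// fixed) are reapplied after every step.

static void apply_clamp(std::vector<int> &s, const IntegerVector &clamp) {
  for (int i = 0; i < (int)s.size(); ++i)
    if (clamp[i] >= 0) s[i] = clamp[i];
}

static void sync_step(const std::vector<int> &s, std::vector<int> &ns,
                      const IntegerVector &gate_out,
                      const IntegerVector &gate_ptr,
                      const IntegerVector &gate_in,
                      const IntegerVector &gate_sign,
                      const IntegerVector &selection,
                      const std::vector<char> &has_sel) {
  const int n = s.size();
  for (int i = 0; i < n; ++i) ns[i] = has_sel[i] ? 0 : s[i];
  const int G = gate_out.size();
  for (int g = 0; g < G; ++g) {
    if (!selection[g]) continue;
    const int out = gate_out[g];
    if (ns[out] == 1) continue;
    bool fire = true;
    for (int k = gate_ptr[g]; k < gate_ptr[g + 1]; ++k) {
      const int v = s[gate_in[k]];
      if (gate_sign[k] > 0 ? (v != 1) : (v != 0)) { fire = false; break; }
    }
    if (fire) ns[out] = 1;
  }
}

// Core steady-state routine shared by the exported entry points.
// Returns 0/1 per node, NA for nodes oscillating in a limit cycle (or all
// unclamped nodes when max_iter is exhausted without fixpoint or cycle).
static IntegerVector steady_core(int n_nodes,
                                 const IntegerVector &gate_out,
                                 const IntegerVector &gate_ptr,
                                 const IntegerVector &gate_in,
                                 const IntegerVector &gate_sign,
                                 const IntegerVector &selection,
                                 const IntegerVector &clamp,
                                 const IntegerVector &init, int max_iter,
                                 int &iterations, bool &converged,
                                 std::string &attractor) {
  std::vector<char> has_sel(n_nodes, 0);
  for (int g = 0; g < gate_out.size(); ++g)
    if (selection[g]) has_sel[gate_out[g]] = 1;

  std::vector<int> s(init.begin(), init.end());
  apply_clamp(s, clamp);
  // bit-packed state keys make history lookups O(1) per word
  const int n_words = (n_nodes + 63) / 64;
  std::vector<uint64_t> key(n_words, 0), nkey(n_words, 0);
  auto pack = [&](const std::vector<int> &st, std::vector<uint64_t> &k) {
    std::fill(k.begin(), k.end(), 0ULL);
    for (int i = 0; i < n_nodes; ++i)
      if (st[i]) k[i >> 6] |= (1ULL << (i & 63));
  };
  pack(s, key);
  std::vector< std::vector<uint64_t> > hist_keys;
  std::vector< std::vector<int> > hist;
  hist_keys.push_back(key);
  hist.push_back(s);
  std::vector<int> ns(n_nodes);

  iterations = 0;
  converged = false;
  attractor = "none";
  int cyc_start = -1;

  for (int it = 1; it <= max_iter; ++it) {
    sync_step(s, ns, gate_out, gate_ptr, gate_in, gate_sign, selection, has_sel);
    apply_clamp(ns, clamp);
    pack(ns, nkey);
    iterations = it;
    if (nkey == key) { converged = true; attractor = "fixpoint"; s = ns; break; }
    for (int h = (int)hist_keys.size() - 1; h >= 0; --h) {
      if (hist_keys[h] == nkey) { cyc_start = h; break; }
    }
    s = ns;
    key = nkey;
    hist_keys.push_back(key);
    hist.push_back(s);
    if (cyc_start >= 0) { attractor = "cycle"; break; }
  }

  IntegerVector out(n_nodes);
  if (converged) {
    for (int i = 0; i < n_nodes; ++i) out[i] = s[i];
  } else if (cyc_start >= 0) {
    // nodes constant over the cycle keep their value, others are unresolved
    for (int i = 0; i < n_nodes; ++i) {
      int v = hist[cyc_start][i];
      bool constant = true;
      for (int h = cyc_start + 1; h < (int)hist.size(); ++h)
        if (hist[h][i] != v) { constant = false; break; }
      out[i] = constant ? v : NA_INTEGER;
    }
  } else {
    for (int i = 0; i < n_nodes; ++i)
      out[i] = (clamp[i] >= 0) ? clamp[i] : NA_INTEGER;
  }
  return out;
}

// [[Rcpp::export]]
List sim_logic_cpp(int n_nodes, IntegerVector gate_out, IntegerVector gate_ptr,
                   IntegerVector gate_in, IntegerVector gate_sign,
                   IntegerVector selection, IntegerVector clamp,
                   IntegerVector init, int max_iter) {
  int iterations; bool converged; std::string attractor;
  IntegerVector st = steady_core(n_nodes, gate_out, gate_ptr, gate_in,
                                 gate_sign, selection, clamp, init, max_iter,
                                 iterations, converged, attractor);
  return List::create(_["state"] = st, _["iterations"] = iterations,
                      _["converged"] = converged, _["attractor"] = attractor);
}

// Fitness of a batch of gate selections against a conditions x sentinels
// data matrix. clamps is conditions x nodes (-1 free, 0/1 fixed).
// Per unmasked data cell: resolved prediction contributes its squared
// deviation, an unresolved prediction contributes theta_na. Both sums are
// divided by the number of unmasked cells; the size penalty is
// theta_size * (selected gate inputs / total gate inputs).
// Returns a matrix with columns total, mse, na_penalty, size_penalty,
// n_points.
// [[Rcpp::export]]
NumericMatrix fitness_batch_cpp(IntegerMatrix selections, int n_nodes,
                                IntegerVector gate_out, IntegerVector gate_ptr,
                                IntegerVector gate_in, IntegerVector gate_sign,
                                IntegerMatrix clamps, NumericMatrix data,
                                IntegerVector sent_idx, IntegerVector sent_act,
                                IntegerVector init, int max_iter,
                                double theta_size, double theta_na) {
  const int n_ind = selections.nrow();
  const int n_cond = clamps.nrow();
  const int n_sent = sent_idx.size();
  const int G = gate_out.size();
  double total_inputs = 0;
  for (int g = 0; g < G; ++g) total_inputs += gate_ptr[g + 1] - gate_ptr[g];

  NumericMatrix res(n_ind, 5);
  colnames(res) = CharacterVector::create("total", "mse", "na_penalty",
                                          "size_penalty", "n_points");
  for (int ind = 0; ind < n_ind; ++ind) {
    IntegerVector sel = selections(ind, _);
    double sel_inputs = 0;
    for (int g = 0; g < G; ++g)
      if (sel[g]) sel_inputs += gate_ptr[g + 1] - gate_ptr[g];
    double sse = 0, na_sum = 0;
    int n_points = 0;
    for (int c = 0; c < n_cond; ++c) {
      IntegerVector clamp = clamps(c, _);
      int iterations; bool converged; std::string attractor;
      IntegerVector st = steady_core(n_nodes, gate_out, gate_ptr, gate_in,
                                     gate_sign, sel, clamp, init, max_iter,
                                     iterations, converged, attractor);
      for (int j = 0; j < n_sent; ++j) {
        double y = data(c, j);
        if (NumericVector::is_na(y)) continue;
        ++n_points;
        int p = st[sent_idx[j]];
        if (p == NA_INTEGER) {
          na_sum += theta_na;
        } else {
          double pred = (sent_act[j] < 0) ? 1.0 - p : (double)p;
          sse += (pred - y) * (pred - y);
        }
      }
    }
    double mse = n_points ? sse / n_points : 0.0;
    double nap = n_points ? na_sum / n_points : 0.0;
    double sz = total_inputs > 0 ? theta_size * sel_inputs / total_inputs : 0.0;
    res(ind, 0) = mse + nap + sz;
    res(ind, 1) = mse;
    res(ind, 2) = nap;
    res(ind, 3) = sz;
    res(ind, 4) = n_points;
  }
  return res;
}
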