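#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Time-stepped forward-Euler engine for current-based LIF populations with
// exponential synapses, per-connection conduction delays and per-neuron
// Poisson background. All randomness goes through R's RNG so that a
// set.seed() in the caller fixes the run bit-exactly.
//
// Units: time ms, potentials mV, external drive mV/ms. A synaptic event of
// weight w (mV) increments the target's input-current trace by w / tau_syn
// (mV/ms), which then decays with tau_syn, so the total injected "charge"
// integrates to w millivolts of depolarisation before leak.
//
// conns: list of lists with fields
//   src, tgt        0-based population indices
//   delay_steps     integer >= 1
//   decay           exp(-dt / tau_syn)
//   A               dense effect matrix (n_tgt x n_src), signed, in mV/ms
//                   per presynaptic spike (weight/tau_syn, Dale sign, mask)
//
// Returns spike events plus (optionally) per-population mean-voltage traces.

// [[Rcpp::export]]
List sim_core(IntegerVector pop_sizes,
              NumericVector tau_m,
              NumericVector v_rest,
              NumericVector v_thresh,
              NumericVector v_reset,
              NumericVector t_ref,
              NumericVector bg_rate,
              NumericVector bg_weight,
              List conns,
              NumericMatrix drive,
              double dt,
              int n_steps,
              bool record_voltage) {
  const int n_pops = pop_sizes.size();
  const int n_conns = conns.size();

  // per-population state
  std::vector< std::vector<double> > V(n_pops);
  std::vector< std::vector<int> > refrac(n_pops);
  std::vector<int> ref_steps(n_pops);
  for (int p = 0; p < n_pops; ++p) {
    V[p].assign(pop_sizes[p], v_rest[p]);
    refrac[p].assign(pop_sizes[p], 0);
    ref_steps[p] = (int) std::lround(t_ref[p] / dt);
  }

  // per-connection state: current trace on targets + delay ring buffer
  std::vector<int> c_src(n_conns), c_tgt(n_conns), c_delay(n_conns);
  std::vector<double> c_decay(n_conns);
  std::vector<NumericMatrix> c_A;
  std::vector< std::vector<double> > g(n_conns);
  std::vector< std::vector< std::vector<int> > > ring(n_conns);
  // connections grouped by target for the integration pass
  std::vector< std::vector<int> > conns_by_tgt(n_pops);
  // and by source for spike delivery
  std::vector< std::vector<int> > conns_by_src(n_pops);
  for (int c = 0; c < n_conns; ++c) {
    List cc = conns[c];
    c_src[c] = as<int>(cc["src"]);
    c_tgt[c] = as<int>(cc["tgt"]);
    c_delay[c] = as<int>(cc["delay_steps"]);
    c_decay[c] = as<double>(cc["decay"]);
    c_A.push_back(as<NumericMatrix>(cc["A"]));
    if (c_A[c].nrow() != pop_sizes[c_tgt[c]] || c_A[c].ncol() != pop_sizes[c_src[c]])
      stop("connection %d: effect matrix dimensions do not match populations", c + 1);
    if (c_delay[c] < 1) stop("connection %d: delay shorter than one step", c + 1);
    g[c].assign(pop_sizes[c_tgt[c]], 0.0);
    ring[c].assign(c_delay[c], std::vector<int>());
    conns_by_tgt[c_tgt[c]].push_back(c);
    conns_by_src[c_src[c]].push_back(c);
  }

  std::vector<int> out_pop, out_neuron;
  std::vector<double> out_time;
  NumericMatrix vtrace;
  if (record_voltage) vtrace = NumericMatrix(n_steps, n_pops);

  std::vector<double> lambda(n_pops);
  for (int p = 0; p < n_pops; ++p) lambda[p] = bg_rate[p] * dt / 1000.0;

  std::vector<int> spiked; // scratch, local indices of one population

  for (int step = 0; step < n_steps; ++step) {
    // 1. decay synaptic traces, then deliver spikes arriving this step
    for (int c = 0; c < n_conns; ++c) {
      std::vector<double> &gc = g[c];
      const double d = c_decay[c];
      for (size_t i = 0; i < gc.size(); ++i) gc[i] *= d;
      std::vector<int> &slot = ring[c][step % c_delay[c]];
      if (!slot.empty()) {
        const NumericMatrix &A = c_A[c];
        const int nt = A.nrow();
        for (size_t s = 0; s < slot.size(); ++s) {
          const double *col = &A(0, slot[s]);
          for (int i = 0; i < nt; ++i) gc[i] += col[i];
        }
        slot.clear();
      }
    }

    // 2. per population: background jumps, Euler integration, thresholding
    for (int p = 0; p < n_pops; ++p) {
      const int n = pop_sizes[p];
      std::vector<double> &Vp = V[p];
      std::vector<int> &rp = refrac[p];
      const double ext = drive(step, p);
      const double leak_rest = v_rest[p], tm = tau_m[p];
      const double vth = v_thresh[p], vre = v_reset[p];

      if (lambda[p] > 0.0) {
        // population-level draw + uniform assignment: same process as
        // independent per-neuron trains (Poisson thinning), fewer RNG calls
        const double bw = bg_weight[p];
        int N = (int) R::rpois(lambda[p] * n);
        for (int e = 0; e < N; ++e) {
          int i = (int) (unif_rand() * n);
          if (i >= n) i = n - 1;
          if (rp[i] == 0) Vp[i] += bw;
        }
      }

      spiked.clear();
      for (int i = 0; i < n; ++i) {
        if (rp[i] > 0) {
          --rp[i];
          Vp[i] = vre; // clamped through the refractory period
          continue;
        }
        double I = ext;
        for (size_t k = 0; k < conns_by_tgt[p].size(); ++k)
          I += g[conns_by_tgt[p][k]][i];
        Vp[i] += dt * ((leak_rest - Vp[i]) / tm + I);
        if (!std::isfinite(Vp[i]))
          stop("non-finite membrane potential in population %d, neuron %d, t = %.2f ms (pathological weights?)",
               p + 1, i + 1, (step + 1) * dt);
        if (Vp[i] >= vth) {
          spiked.push_back(i);
          Vp[i] = vre;
          rp[i] = ref_steps[p];
        }
      }

      if (!spiked.empty()) {
        const double t_now = (step + 1) * dt;
        for (size_t s = 0; s < spiked.size(); ++s) {
          out_pop.push_back(p + 1);
          out_neuron.push_back(spiked[s]);
          out_time.push_back(t_now);
        }
        for (size_t k = 0; k < conns_by_src[p].size(); ++k) {
          const int c = conns_by_src[p][k];
          std::vector<int> &slot = ring[c][(step + c_delay[c]) % c_delay[c]];
          slot.insert(slot.end(), spiked.begin(), spiked.end());
        }
      }

      if (record_voltage) {
        double m = 0.0;
        for (int i = 0; i < n; ++i) m += Vp[i];
        vtrace(step, p) = m / n;
      }
    }
  }

  List out = List::create(
    _["pop"] = wrap(out_pop),
    _["neuron"] = wrap(out_neuron),
    _["time"] = wrap(out_time));
  if (record_voltage) out["voltage"] = vtrace;
  return out;
}
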