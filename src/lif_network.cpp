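// Forward-Euler engine for the excitatory LIF network with conductance-based
// synapses, delayed spike delivery, Poisson background input and event-driven
// nearest-neighbour STDP.
//
// Time convention: one call advances the state from t0 over n_steps steps of
// width h. A threshold crossing detected while integrating step n (t0 + n*h ->
// t0 + (n+1)*h) emits a spike stamped t0 + (n+1)*h. A spike emitted at step e
// produces, at the start of step e + d (d = delay/h), the corresponding
// arrival events stamped t0 + (e + d)*h: postsynaptic (backpropagating)
// arrivals are processed before presynaptic arrivals, so that a pre arrival
// simultaneous with a post arrival pairs with it at lag zero (a null update).
// Conductance jumps use the weight as it is at arrival, before the STDP update
// triggered by the same arrival.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static inline double stdp_W(double dt, double eta, double amp_neg,
                            double tau_p, double tau_m) {
  if (dt > 0) return eta * std::exp(-dt / tau_p);
  if (dt < 0) return -amp_neg * std::exp(dt / tau_m);
  return 0.0;
}

static inline int delay_steps(double d, double h, const char *what) {
  double s = d / h;
  int si = (int) std::llround(s);
  if (std::fabs(si - s) > 1e-6) stop("delay '%s' must be an integer multiple of the step h", what);
  return si;
}

// [[Rcpp::export]]
List lif_run_cpp(NumericVector V_, NumericVector Vth_, NumericVector gsyn_,
                 NumericVector gnoise_, NumericVector C_, NumericVector plateau_ms_,
                 IntegerVector edge_pre, IntegerVector edge_post,
                 NumericVector w_, NumericVector last_pre_, NumericVector last_post_,
                 List neuron, List net, List stdp, List stim,
                 double h, double n_steps_d, double t0,
                 bool record_spikes, double record_spikes_from,
                 int block_every_steps, List partition0,
                 NumericVector snapshot_steps,
                 NumericVector pending_es, IntegerVector pending_neuron) {
  const int N = V_.size();
  const long long n_steps = (long long) n_steps_d;
  NumericVector V = clone(V_), Vth = clone(Vth_), gsyn = clone(gsyn_),
                gnoise = clone(gnoise_), w = clone(w_),
                last_pre = clone(last_pre_), last_post = clone(last_post_);
  const NumericVector C = C_;
  const int n_edge = edge_pre.size();

  // neuron parameters
  const double g_leak = neuron["g_leak"], V_rest = neuron["V_rest"],
               V_reset = neuron["V_reset"], V_syn = neuron["V_syn"],
               V_th_spike = neuron["V_th_spike"], V_th_rest = neuron["V_th_rest"],
               V_spike = neuron["V_spike"], tau_th = neuron["tau_th"],
               tau_syn = neuron["tau_syn"], tau_spike = neuron["tau_spike"];
  const double kappa = net["kappa"], kappa_noise = net["kappa_noise"],
               f_noise = net["f_noise"], t_a = net["t_a"], t_d = net["t_d"];
  const double eta = stdp["eta"], beta = stdp["beta"], tau_R = stdp["tau_R"],
               tau_p = stdp["tau_plus"];
  const double tau_m = tau_p * tau_R;
  const double amp_neg = eta * beta / tau_R;
  const bool plastic = eta > 0.0;

  const int ta_steps = delay_steps(t_a, h, "t_a");
  const int td_steps = delay_steps(t_d, h, "t_d");
  const int tau_spike_steps = delay_steps(tau_spike, h, "tau_spike");
  if (tau_spike_steps < 1) stop("tau_spike must be at least one step");

  // plateau timers arrive in ms; convert to remaining steps
  std::vector<int> plateau(N);
  for (int i = 0; i < N; ++i) {
    plateau[i] = (int) std::llround(plateau_ms_[i] / h);
    if (plateau[i] < 0) plateau[i] = 0;
  }

  // adjacency in CSR (by presynaptic neuron) and CSC (by postsynaptic neuron)
  // edge_pre/post are 0-based; edges kept in input order within each neuron
  std::vector<int> out_ptr(N + 1, 0), in_ptr(N + 1, 0);
  std::vector<int> out_edges(n_edge), in_edges(n_edge);
  for (int e = 0; e < n_edge; ++e) { out_ptr[edge_pre[e] + 1]++; in_ptr[edge_post[e] + 1]++; }
  for (int i = 0; i < N; ++i) { out_ptr[i + 1] += out_ptr[i]; in_ptr[i + 1] += in_ptr[i]; }
  {
    std::vector<int> oc(N, 0), ic(N, 0);
    for (int e = 0; e < n_edge; ++e) {
      int p = edge_pre[e], q = edge_post[e];
      out_edges[out_ptr[p] + oc[p]++] = e;
      in_edges[in_ptr[q] + ic[q]++] = e;
    }
  }

  // stimulation
  IntegerVector membership = stim["membership"];   // 0-based subpop, -1 = none
  List onset_list = stim["onsets"];                 // per subpop, sorted ms
  const int n_subpop = onset_list.size();
  std::vector<std::vector<double>> onsets(n_subpop);
  std::vector<size_t> stim_ptr(n_subpop, 0);
  for (int s = 0; s < n_subpop; ++s) {
    NumericVector o = onset_list[s];
    onsets[s] = std::vector<double>(o.begin(), o.end());
  }
  const double A_e = stim["A_e"], A_i = stim["A_i"], nu_e = stim["nu_e"],
               nu_i = stim["nu_i"], T_intra = stim["T_intra"],
               stim_dur = stim["duration"];
  const int n_pulses = stim["n_pulses"];
  std::vector<double> I_sub(n_subpop > 0 ? n_subpop : 1, 0.0);

  // noise: geometric gaps reproduce the per-step Bernoulli event process
  const double p_noise = f_noise * h * 1e-3;
  const double log1mp = (p_noise > 0) ? std::log1p(-p_noise) : 0.0;
  const long long FAR = std::numeric_limits<long long>::max() / 4;
  std::vector<long long> next_noise(N, FAR);
  if (p_noise > 0) {
    for (int i = 0; i < N; ++i) {
      double u = unif_rand();
      next_noise[i] = 1 + (long long) std::floor(std::log(u) / log1mp);
    }
  }

  // emission ring buffer; spikes emitted before this call (still in flight
  // along axon or dendrite) are re-injected with non-positive emission steps
  const int L = std::max(ta_steps, td_steps) + 1;
  std::vector<std::vector<int>> ring(L);
  std::vector<long long> slot_step(L, std::numeric_limits<long long>::min());
  for (int q = 0; q < pending_es.size(); ++q) {
    long long es = (long long) pending_es[q];
    if (es <= -L || es > 0) continue;
    size_t sl = (size_t)(((es % L) + L) % L);
    if (slot_step[sl] != es) { ring[sl].clear(); slot_step[sl] = es; }
    ring[sl].push_back(pending_neuron[q]);
  }

  // recorders
  std::vector<int> spike_neuron;
  std::vector<double> spike_time;
  const int M = partition0.size();
  std::vector<int> subpop_of(N, -1);
  for (int s = 0; s < M; ++s) {
    IntegerVector idx = partition0[s];
    for (int k = 0; k < idx.size(); ++k) subpop_of[idx[k]] = s;
  }
  std::vector<int> edge_block(n_edge, -1);
  std::vector<double> block_count(M * M, 0.0);
  for (int e = 0; e < n_edge; ++e) {
    int bx = subpop_of[edge_pre[e]], by = subpop_of[edge_post[e]];
    if (bx >= 0 && by >= 0) { edge_block[e] = bx * M + by; block_count[edge_block[e]] += 1.0; }
  }
  std::vector<double> block_times, block_vals, meanw_vals;
  auto record_blocks = [&](double tnow) {
    if (block_every_steps <= 0) return;
    std::vector<double> bs(M * M, 0.0);
    double tot = 0.0;
    for (int e = 0; e < n_edge; ++e) {
      tot += w[e];
      if (edge_block[e] >= 0) bs[edge_block[e]] += w[e];
    }
    block_times.push_back(tnow);
    for (int b = 0; b < M * M; ++b) {
      block_vals.push_back(block_count[b] > 0 ? bs[b] / block_count[b] : NA_REAL);
    }
    meanw_vals.push_back(n_edge > 0 ? tot / n_edge : NA_REAL);
  };
  record_blocks(t0);

  std::vector<double> snap_steps(snapshot_steps.begin(), snapshot_steps.end());
  size_t snap_ptr = 0;
  List snapshots;
  std::vector<double> snap_times;

  bool aborted = false;
  long long abort_step = -1;

  for (long long n = 0; n < n_steps; ++n) {
    const double t_now = t0 + (double) n * h;        // state time at step start
    const long long step_now = n;                    // arrivals due: emission step == step_now

    // --- phase A1: postsynaptic (backpropagating) arrivals ---
    {
      long long es = step_now - td_steps;
      size_t sl = (size_t)(((es % L) + L) % L);
      if (slot_step[sl] == es) {
        std::vector<int> &emit = ring[sl];
        for (size_t q = 0; q < emit.size(); ++q) {
          int j = emit[q];
          double t_post = t0 + (double) es * h + t_d;
          for (int p = in_ptr[j]; p < in_ptr[j + 1]; ++p) {
            int e = in_edges[p];
            if (plastic && std::isfinite(last_pre[e])) {
              double dw = stdp_W(t_post - last_pre[e], eta, amp_neg, tau_p, tau_m);
              double nw = w[e] + dw;
              w[e] = nw < 0 ? 0 : (nw > 1 ? 1 : nw);
            }
            last_post[e] = t_post;
          }
        }
      }
    }

    // --- phase A2: presynaptic arrivals (delivery + STDP) ---
    {
      long long es = step_now - ta_steps;
      size_t sl = (size_t)(((es % L) + L) % L);
      if (slot_step[sl] == es) {
        std::vector<int> &emit = ring[sl];
        for (size_t q = 0; q < emit.size(); ++q) {
          int i = emit[q];
          double t_pre = t0 + (double) es * h + t_a;
          for (int p = out_ptr[i]; p < out_ptr[i + 1]; ++p) {
            int e = out_edges[p];
            gsyn[edge_post[e]] += kappa * w[e] / (double) N;
            if (plastic && std::isfinite(last_post[e])) {
              double dw = stdp_W(last_post[e] - t_pre, eta, amp_neg, tau_p, tau_m);
              double nw = w[e] + dw;
              w[e] = nw < 0 ? 0 : (nw > 1 ? 1 : nw);
            }
            last_pre[e] = t_pre;
          }
        }
      }
    }

    // --- stimulation current per subpopulation ---
    for (int s = 0; s < n_subpop; ++s) {
      double I = 0.0;
      std::vector<double> &on = onsets[s];
      size_t &ptr = stim_ptr[s];
      while (ptr < on.size() && on[ptr] + stim_dur <= t_now) ++ptr;
      for (size_t q = ptr; q < on.size() && on[q] <= t_now; ++q) {
        double rel = t_now - on[q];
        int p = (int) std::floor(rel / T_intra);
        if (p >= n_pulses) continue;
        double tau = rel - p * T_intra;
        if (tau < nu_e) I += A_e;
        else if (tau < nu_e + nu_i) I += A_i;
      }
      I_sub[s] = I;
    }

    // --- phases B-D: noise, integration, threshold ---
    const double dec_syn = 1.0 - h / tau_syn;
    for (int i = 0; i < N; ++i) {
      if (next_noise[i] == n) {
        gnoise[i] += kappa_noise;
        double u = unif_rand();
        next_noise[i] = n + 1 + (long long) std::floor(std::log(u) / log1mp);
      }
      // threshold relaxes at all times; overridden at plateau end
      Vth[i] += (h / tau_th) * (V_th_rest - Vth[i]);
      if (plateau[i] > 0) {
        plateau[i] -= 1;
        if (plateau[i] == 0) { V[i] = V_reset; Vth[i] = V_th_spike; }
      } else {
        double Istim = (membership[i] >= 0) ? I_sub[membership[i]] : 0.0;
        double dV = g_leak * (V_rest - V[i]) + (gsyn[i] + gnoise[i]) * (V_syn - V[i]) + Istim;
        V[i] += (h / C[i]) * dV;
      }
      gsyn[i] *= dec_syn;
      gnoise[i] *= dec_syn;
    }

    // clear the ring slot about to be written, then detect crossings
    {
      size_t sl = (size_t)((n + 1) % L);
      ring[sl].clear();
      slot_step[sl] = n + 1;
    }
    for (int i = 0; i < N; ++i) {
      if (plateau[i] == 0 && V[i] >= Vth[i]) {
        double t_sp = t0 + (double)(n + 1) * h;
        V[i] = V_spike;
        plateau[i] = tau_spike_steps;
        ring[(size_t)((n + 1) % L)].push_back(i);
        if (record_spikes && t_sp >= record_spikes_from) {
          spike_neuron.push_back(i + 1);
          spike_time.push_back(t_sp);
        }
      }
      if (!std::isfinite(V[i])) { aborted = true; abort_step = n; break; }
    }
    if (aborted) break;

    if (block_every_steps > 0 && (n + 1) % block_every_steps == 0) {
      record_blocks(t0 + (double)(n + 1) * h);
    }
    while (snap_ptr < snap_steps.size() && (double)(n + 1) == snap_steps[snap_ptr]) {
      snapshots.push_back(clone(w));
      snap_times.push_back(t0 + (double)(n + 1) * h);
      ++snap_ptr;
    }
    if ((n & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  if (aborted) stop("non-finite membrane potential at step %d", (int) abort_step);

  NumericVector plateau_out(N);
  for (int i = 0; i < N; ++i) plateau_out[i] = plateau[i] * h;

  // spikes still in flight at the end of the run (relative emission steps)
  std::vector<double> pend_es_out;
  std::vector<int> pend_nrn_out;
  for (int sl = 0; sl < L; ++sl) {
    long long es = slot_step[sl];
    if (es > n_steps - L && es <= n_steps) {
      for (size_t q = 0; q < ring[sl].size(); ++q) {
        pend_es_out.push_back((double)(es - n_steps));
        pend_nrn_out.push_back(ring[sl][q]);
      }
    }
  }

  return List::create(
    _["V"] = V, _["V_th"] = Vth, _["g_syn"] = gsyn, _["g_noise"] = gnoise,
    _["plateau"] = plateau_out, _["w"] = w,
    _["last_pre"] = last_pre, _["last_post"] = last_post,
    _["spike_neuron"] = wrap(spike_neuron), _["spike_time"] = wrap(spike_time),
    _["block_times"] = wrap(block_times), _["block_vals"] = wrap(block_vals),
    _["mean_w"] = wrap(meanw_vals),
    _["snapshots"] = snapshots, _["snapshot_times"] = wrap(snap_times),
    _["pending_es"] = wrap(pend_es_out), _["pending_neuron"] = wrap(pend_nrn_out),
    _["time"] = t0 + (double) n_steps * h);
}
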