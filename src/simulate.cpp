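#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Conductance-based LIF network integrator.
//
// Membrane equation (conductances dimensionless, relative to leak):
//   tau dV/dt = (V_rest - V) + g_ex (E_ex - V) + g_inh (E_inh - V)
// integrated by exponential Euler with g held constant over each step;
// synaptic conductances decay exactly (g *= exp(-dt/tau_syn)) and jump by
// dg_ex / dg_inh on presynaptic spikes, which take effect on the next step.
//
// Per step: (1) decay g; (2) apply recurrent increments from last step's
// spikes plus external (background + stimulus) spikes drawn for this step;
// (3) update V of non-refractory neurons; (4) threshold, reset, refractory.
//
// External drive: each neuron independently receives a background spike with
// probability p_bg per step (Bernoulli thinning of a Poisson process), and a
// stimulus spike with probability p_stim[t]. Sampled as a Binomial(N, p)
// count plus a uniformly chosen distinct subset, which is equivalent to N
// independent Bernoulli draws.
//
// Uses R's RNG stream, so results are reproducible via set.seed().

// exp(x) for x <= 0, table + cubic remainder, relative error < 1e-8 on
// [-8, 0]; the membrane update spends most of the integration time here
struct NegExp {
  double table[513];
  NegExp() {
    for (int i = 0; i <= 512; ++i) table[i] = std::exp(-i / 64.0);
  }
  inline double operator()(double x) const {
    if (x < -8.0) return std::exp(x);
    int i = (int)(x * -64.0);
    double r = x + i / 64.0; // in (-1/64, 0]
    return table[i] * (1.0 + r * (1.0 + r * (0.5 + r / 6.0)));
  }
};
static const NegExp neg_exp;

static void draw_distinct(int n_neurons, int k, std::vector<int> &out,
                          std::vector<char> &mark) {
  // k distinct uniform indices in [0, n_neurons); k << n_neurons in practice
  out.clear();
  while ((int)out.size() < k) {
    int i = (int)(unif_rand() * n_neurons);
    if (i >= n_neurons) i = n_neurons - 1;
    if (!mark[i]) {
      mark[i] = 1;
      out.push_back(i);
    }
  }
  for (int i : out) mark[i] = 0;
}

// [[Rcpp::export(name = ".sim_lif_cpp")]]
List sim_lif_cpp(IntegerVector adj_targets, IntegerVector adj_offsets,
                 LogicalVector is_excitatory, NumericVector v_init,
                 List params, double bg_rate, NumericVector p_stim,
                 int n_steps, int warmup_steps, bool record_traces,
                 int record_every, int delay_steps, int n_stim_targets,
                 bool record_v) {
  const int n = v_init.size();
  const double dt = as<double>(params["dt"]);
  const double tau_m = as<double>(params["tau_m"]);
  const double tau_ex = as<double>(params["tau_ex"]);
  const double tau_inh = as<double>(params["tau_inh"]);
  const double v_rest = as<double>(params["v_rest"]);
  const double v_thresh = as<double>(params["v_thresh"]);
  const double v_reset = as<double>(params["v_reset"]);
  const double e_ex = as<double>(params["e_ex"]);
  const double e_inh = as<double>(params["e_inh"]);
  const double t_ref = as<double>(params["t_ref"]);
  const double dg_ex = as<double>(params["dg_ex"]);
  const double dg_inh = as<double>(params["dg_inh"]);

  const double d_ex = std::exp(-dt / tau_ex);
  const double d_inh = std::exp(-dt / tau_inh);
  const int ref_steps = (int)std::lround(t_ref / dt);
  const double p_bg = bg_rate * dt / 1000.0; // rate in Hz, dt in ms
  if (p_bg >= 0.1)
    stop("background rate * dt = %f >= 0.1: time step too coarse", p_bg);

  std::vector<double> v(v_init.begin(), v_init.end());
  std::vector<double> g_ex(n, 0.0), g_inh(n, 0.0);
  std::vector<int> refcnt(n, 0);
  // ring buffer of spike lists: slot d holds spikes due in d steps
  if (delay_steps < 1) delay_steps = 1;
  std::vector< std::vector<int> > pending(delay_steps);
  std::vector<int> ext;           // scratch for external deliveries
  std::vector<char> mark(n, 0);

  std::vector<int> out_neuron;
  std::vector<double> out_time;
  const int total_steps = warmup_steps + n_steps;
  const int n_rec = record_traces ? (n_steps + record_every - 1) / record_every : 0;
  NumericVector rec_ex(n_rec), rec_inh(n_rec);
  std::vector<int> rec_cnt(n_rec, 0);
  const int n_vrec = record_v ? (n_steps + record_every - 1) / record_every : 0;
  NumericMatrix vrec(n_vrec, record_v ? n : 0);

  const bool have_stim = p_stim.size() > 0;

  for (int step = 0; step < total_steps; ++step) {
    // (1) conductance decay; fully decayed conductances are clamped to
    // zero so they cannot linger in the denormal range, where arithmetic
    // is microcoded and an order of magnitude slower
    for (int i = 0; i < n; ++i) {
      g_ex[i] = (g_ex[i] > 1e-12) ? g_ex[i] * d_ex : 0.0;
      g_inh[i] = (g_inh[i] > 1e-12) ? g_inh[i] * d_inh : 0.0;
    }
    // (2a) recurrent increments from spikes due this step
    std::vector<int> &due = pending[step % delay_steps];
    for (int pre : due) {
      const int lo = adj_offsets[pre], hi = adj_offsets[pre + 1];
      if (is_excitatory[pre]) {
        for (int e = lo; e < hi; ++e) g_ex[adj_targets[e]] += dg_ex;
      } else {
        for (int e = lo; e < hi; ++e) g_inh[adj_targets[e]] += dg_inh;
      }
    }
    due.clear();
    // (2b) external spikes (background, then stimulus), excitatory synapses
    if (p_bg > 0) {
      int k = (int)R::rbinom(n, p_bg);
      if (k > 0) {
        draw_distinct(n, k, ext, mark);
        for (int i : ext) g_ex[i] += dg_ex;
      }
    }
    if (have_stim && step >= warmup_steps) {
      double ps = p_stim[step - warmup_steps];
      if (ps > 0) {
        if (ps >= 0.1)
          stop("stimulus rate * dt >= 0.1 at step %d: time step too coarse",
               step - warmup_steps);
        const int nt = (n_stim_targets > 0 && n_stim_targets < n)
                           ? n_stim_targets : n;
        int k = (int)R::rbinom(nt, ps);
        if (k > 0) {
          draw_distinct(nt, k, ext, mark);
          for (int i : ext) g_ex[i] += dg_ex;
        }
      }
    }
    // (3) membrane update + (4) threshold
    double sum_iex = 0.0, sum_iinh = 0.0;
    for (int i = 0; i < n; ++i) {
      if (refcnt[i] > 0) {
        --refcnt[i];
        v[i] = v_reset;
      } else {
        const double gtot = 1.0 + g_ex[i] + g_inh[i];
        const double vinf = (v_rest + g_ex[i] * e_ex + g_inh[i] * e_inh) / gtot;
        v[i] = vinf + (v[i] - vinf) * neg_exp(-dt * gtot / tau_m);
        if (!std::isfinite(v[i]))
          stop("membrane potential non-finite at step %d, neuron %d", step, i + 1);
        if (v[i] >= v_thresh) {
          pending[step % delay_steps].push_back(i);
          v[i] = v_reset;
          refcnt[i] = ref_steps;
          if (step >= warmup_steps) {
            out_neuron.push_back(i + 1);
            out_time.push_back((step - warmup_steps) * dt);
          }
        }
      }
      if (record_traces && step >= warmup_steps) {
        sum_iex += g_ex[i] * (e_ex - v[i]);
        sum_iinh += g_inh[i] * (e_inh - v[i]);
      }
    }
    if (record_traces && step >= warmup_steps) {
      const int b = (step - warmup_steps) / record_every;
      rec_ex[b] += sum_iex / n;
      rec_inh[b] += sum_iinh / n;
      rec_cnt[b] += 1;
    }
    if (record_v && step >= warmup_steps &&
        (step - warmup_steps) % record_every == 0) {
      const int b = (step - warmup_steps) / record_every;
      for (int i = 0; i < n; ++i) vrec(b, i) = v[i];
    }
  }

  if (record_traces)
    for (int b = 0; b < n_rec; ++b)
      if (rec_cnt[b] > 0) {
        rec_ex[b] /= rec_cnt[b];
        rec_inh[b] /= rec_cnt[b];
      }

  List out = List::create(
      _["neuron"] = wrap(out_neuron), _["time"] = wrap(out_time),
      _["i_ex"] = record_traces ? rec_ex : NumericVector(0),
      _["i_inh"] = record_traces ? rec_inh : NumericVector(0),
      _["v"] = vrec);
  return out;
}
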