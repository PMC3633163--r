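#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Position wrap onto the ring [-L, L) of circumference 2L.
static inline double wrap_pos(double x, double L) {
  double p = 2.0 * L;
  double y = x + L;
  y -= p * std::floor(y / p);
  return y - L;
}

// Ring metric used by both tuning kernels: |a-b| if < L, else 2L - |a-b|.
static inline double wrapped_dist(double a, double b, double L) {
  double d = std::fabs(a - b);
  return (d < L) ? d : (2.0 * L - d);
}

// Time-stepped simulation of the feedforward LGN->V1 network.
//
// Per step, in order: (1) evaluate the protocol (x_f, A) and refresh the LGN
// Poisson rates if either changed; (2) draw LGN spikes as independent
// Bernoulli(R_j*dt) events; (3) apply the exact leak decay to all V1
// membranes, then one conductance jump per LGN spike using the PRE-depletion
// synaptic strength; (4) deplete fired synapses (S -> f*S); (5) apply the
// exact exponential recovery over dt to all synapses; (6) threshold-detect,
// reset, and record V1 spikes at the step's end time.
//
// LGN spikes are recorded at the step's START time so that the event-driven
// closed-form STD evolution (recover to the spike time, then deplete)
// reproduces the stepped S trajectory exactly.
//
// Bernoulli draws use exact geometric skipping under the bound
// p* = A*dt/1000 >= p_j with acceptance p_j/p*, so RNG cost scales with the
// expected spike count, not with N.
//
// segments: rows (t0, t1, xf0, slope, A); piecewise-linear x_f, piecewise-
// constant brightness. All times ms, rates spikes/s, positions in grid units.
// [[Rcpp::export]]
List sim_core(NumericVector positions, NumericMatrix W, List par,
              NumericMatrix segments, double duration,
              bool record_lgn, double sample_every_ms, bool record_S,
              IntegerVector record_V,
              NumericVector init_V, NumericVector init_S) {
  const int n = positions.size();
  const double g      = as<double>(par["g"]);
  const double sigma1 = as<double>(par["sigma1"]);
  const double f      = as<double>(par["f"]);
  const double tau_S  = as<double>(par["tau_S"]);
  const double tau_m  = as<double>(par["tau_m"]);
  const double V0     = as<double>(par["V0"]);
  const double VE     = as<double>(par["VE"]);
  const double V_th   = as<double>(par["V_th"]);
  const double V_rs   = as<double>(par["V_reset"]);
  const double dt     = as<double>(par["dt"]);
  const double L      = as<double>(par["L"]);

  if (W.nrow() != n || W.ncol() != n) stop("weight matrix does not match grid size");
  const long long n_steps = (long long) std::llround(duration / dt);

  const double decay_m = std::exp(-dt / tau_m);
  const double rec_S   = std::exp(-dt / tau_S);
  const double s1sq    = sigma1 * sigma1;

  std::vector<double> V(n), S(n);
  for (int i = 0; i < n; ++i) {
    V[i] = init_V[i];
    S[i] = init_S[i];
  }

  std::vector<double> p(n, 0.0);   // per-step firing probabilities
  double p_star = 0.0;             // upper bound A*dt/1000
  double cur_xf = NA_REAL, cur_A = NA_REAL;
  int seg = 0;
  const int n_seg = segments.nrow();

  std::vector<int> v1_idx, lgn_idx, fired;
  std::vector<double> v1_t, lgn_t;
  fired.reserve(32);

  const long long sample_steps =
      sample_every_ms > 0 ? (long long) std::llround(sample_every_ms / dt) : 0;
  std::vector<double> trace_t, S_mean, S_full, V_trace;
  const int n_rv = record_V.size();

  for (long long step = 0; step < n_steps; ++step) {
    const double t = step * dt;

    // ---- protocol lookup ----
    while (seg + 1 < n_seg && t >= segments(seg, 1)) ++seg;
    const double slope = segments(seg, 3);
    double xf = segments(seg, 2);
    if (slope != 0.0) xf += slope * (t - segments(seg, 0));
    xf = wrap_pos(xf, L);
    const double A = segments(seg, 4);
    if (xf != cur_xf || A != cur_A) {
      cur_xf = xf; cur_A = A;
      p_star = A * dt / 1000.0;
      if (p_star >= 0.1) stop("dt too large for peak rate: R*dt must stay below 0.1");
      if (p_star > 0.0) {
        for (int j = 0; j < n; ++j) {
          const double d = wrapped_dist(positions[j], xf, L);
          p[j] = p_star * std::exp(-d * d / s1sq);
        }
      }
    }

    // ---- record state at time t ----
    if (sample_steps > 0 && step % sample_steps == 0) {
      trace_t.push_back(t);
      double acc = 0.0;
      for (int j = 0; j < n; ++j) acc += S[j];
      S_mean.push_back(acc / n);
      if (record_S) for (int j = 0; j < n; ++j) S_full.push_back(S[j]);
      for (int k = 0; k < n_rv; ++k) V_trace.push_back(V[record_V[k] - 1]);
    }

    // ---- draw LGN spikes (exact heterogeneous Bernoulli via skipping) ----
    fired.clear();
    if (p_star > 0.0) {
      const double lg = std::log1p(-p_star);
      long long j = -1;
      for (;;) {
        const double u = unif_rand();
        j += 1 + (long long) std::floor(std::log(u) / lg);
        if (j >= n) break;
        if (unif_rand() * p_star < p[j]) fired.push_back((int) j);
      }
    }

    // ---- membrane leak (exact) ----
    for (int i = 0; i < n; ++i) V[i] = V0 + (V[i] - V0) * decay_m;

    // ---- deliver conductance jumps with pre-depletion strengths ----
    for (size_t k = 0; k < fired.size(); ++k) {
      const int j = fired[k];
      if (record_lgn) { lgn_idx.push_back(j + 1); lgn_t.push_back(t); }
      const double coef = g * S[j] / tau_m;
      const double *w = &W(0, j);
      for (int i = 0; i < n; ++i) V[i] += coef * w[i] * (VE - V[i]);
    }

    // ---- deplete, then recover all synapses over dt ----
    for (size_t k = 0; k < fired.size(); ++k) S[fired[k]] *= f;
    for (int j = 0; j < n; ++j) S[j] = 1.0 - (1.0 - S[j]) * rec_S;

    // ---- threshold / reset; V1 spike stamped at end-of-step ----
    for (int i = 0; i < n; ++i) {
      if (V[i] >= V_th) {
        v1_idx.push_back(i + 1);
        v1_t.push_back(t + dt);
        V[i] = V_rs;
      }
    }

    if ((step & 0x3FFF) == 0) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(V[i])) stop("non-finite membrane potential at t = %f ms", t);
    }
  }

  // final state sample
  if (sample_steps > 0) {
    trace_t.push_back(n_steps * dt);
    double acc = 0.0;
    for (int j = 0; j < n; ++j) acc += S[j];
    S_mean.push_back(acc / n);
    if (record_S) for (int j = 0; j < n; ++j) S_full.push_back(S[j]);
    for (int k = 0; k < n_rv; ++k) V_trace.push_back(V[record_V[k] - 1]);
  }

  List out = List::create(
    _["v1_neuron"] = wrap(v1_idx), _["v1_time"] = wrap(v1_t),
    _["lgn_neuron"] = wrap(lgn_idx), _["lgn_time"] = wrap(lgn_t),
    _["trace_time"] = wrap(trace_t), _["S_mean"] = wrap(S_mean),
    _["final_V"] = wrap(V), _["final_S"] = wrap(S));
  if (record_S) {
    NumericMatrix Sm((int) trace_t.size(), n);
    for (size_t r = 0; r < trace_t.size(); ++r)
      for (int j = 0; j < n; ++j) Sm(r, j) = S_full[r * n + j];
    out["S_full"] = Sm;
  }
  if (n_rv > 0) {
    NumericMatrix Vm((int) trace_t.size(), n_rv);
    for (size_t r = 0; r < trace_t.size(); ++r)
      for (int k = 0; k < n_rv; ++k) Vm(r, k) = V_trace[r * n_rv + k];
    out["V_trace"] = Vm;
  }
  return out;
}
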