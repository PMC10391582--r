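#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Clock-driven simulation core for the conductance-based E-I engram network.
//
// Integration: second-order Runge-Kutta on the membrane equation with
// conductances frozen within a step (dt is far below every kernel time
// constant), threshold crossings located by linear interpolation inside the
// step, reset + refractory afterwards.
//
// Conductance kernels: difference-of-exponentials, maintained by the exact
// two-accumulator recursion (one accumulator per exponential).  Synaptic
// increments travel through a ring buffer implementing the transmission
// latency rounded to the step grid.
//
// RNG: two independent mt19937_64 streams (external drive, rescue) derived
// from the user seed so that protocols are reproducible component-wise.

struct BiExp {
  double dec_d, dec_r;  // per-step decay factors
  double scale;         // mu / (tau_d - tau_r)
};

static BiExp make_biexp(List r, double dt) {
  double tau_r = as<double>(r["tau_r"]);
  double tau_d = as<double>(r["tau_d"]);
  double mu    = as<double>(r["mu"]);
  BiExp b;
  b.dec_d = std::exp(-dt / tau_d);
  b.dec_r = std::exp(-dt / tau_r);
  if (std::fabs(tau_d - tau_r) < 1e-9) {
    // alpha-function limit handled upstream (kernel_value); the network core
    // requires distinct time constants, enforced by config validation.
    stop("receptor rise and decay time constants must differ");
  }
  b.scale = mu / (tau_d - tau_r);
  return b;
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(int n,
              IntegerVector is_exc,
              IntegerVector edge_ptr,    // CSR by presynaptic neuron, length n+1
              IntegerVector edge_post,   // 0-based
              NumericVector edge_w0,
              IntegerVector edge_plastic,
              IntegerVector in_ptr,      // CSR of incoming plastic edges by post
              IntegerVector in_edge,
              IntegerVector in_pre,
              List neuron, List receptor, List stp_par,
              NumericVector block_end,   // ms, increasing, last >= duration
              NumericMatrix rate_hz,     // n x nblocks, aggregated external rate per neuron
              NumericVector g_O,   // per-neuron external weight
              List rescue, List plast,
              IntegerVector edge_group,  // snapshot group per edge (0 = ungrouped)
              int n_groups,
              double duration_ms, double dt,
              bool record_traces,
              int seed) {

  const double tau_E = as<double>(neuron["tau_E"]);
  const double tau_I = as<double>(neuron["tau_I"]);
  const double V_L = as<double>(neuron["V_L"]);
  const double V_th = as<double>(neuron["V_th"]);
  const double V_reset = as<double>(neuron["V_reset"]);
  const double E_E = as<double>(neuron["E_E"]);
  const double E_I = as<double>(neuron["E_I"]);
  const double t_ref = as<double>(neuron["t_ref"]);

  BiExp ampa = make_biexp(receptor["ampa"], dt);
  BiExp nmda = make_biexp(receptor["nmda"], dt);
  BiExp gaba = make_biexp(receptor["gaba"], dt);
  const double latency = as<double>(receptor["latency"]);
  int L = (int)std::lround(latency / dt);
  if (L < 1) stop("synaptic latency must be at least one time step");

  const double U = as<double>(stp_par["U"]);
  const double stp_dec_u = std::exp(-dt / as<double>(stp_par["tau_F"]));
  const double stp_dec_x = std::exp(-dt / as<double>(stp_par["tau_D"]));

  const bool resc_on = as<bool>(rescue["enabled"]);
  double resc_period = 0, resc_onms = 0, resc_start = 0, resc_prob = 0;
  IntegerVector chosen;
  if (resc_on) {
    resc_period = as<double>(rescue["period_ms"]);
    resc_onms   = as<double>(rescue["on_ms"]);
    resc_start  = as<double>(rescue["start_ms"]);
    resc_prob   = as<double>(rescue["prob"]);
    chosen      = as<IntegerVector>(rescue["chosen"]);
    for (int k = 0; k < chosen.size(); ++k)
      if (is_exc[chosen[k]]) stop("rescue target set contains excitatory neurons");
  }

  const bool pl_on = as<bool>(plast["enabled"]);
  double pl_t0 = 0, pl_t1 = 0, A = 0, B = 0, beta = 0, w_tilde = 1,
         delta1 = 0, w_min = 1e-3, w_max = -1, snap_ms = 1000;
  double tr_dec = 1, tr_dec_slow = 1;
  if (pl_on) {
    pl_t0 = as<double>(plast["t_start"]);
    pl_t1 = as<double>(plast["t_end"]);
    A = as<double>(plast["A"]);
    B = as<double>(plast["B"]);
    beta = as<double>(plast["beta"]);
    w_tilde = as<double>(plast["w_tilde"]);
    delta1 = as<double>(plast["delta1"]);
    w_min = as<double>(plast["w_min"]);
    w_max = as<double>(plast["w_max"]);
    snap_ms = as<double>(plast["snapshot_ms"]);
    tr_dec = std::exp(-dt / as<double>(plast["tau_stdp"]));
    tr_dec_slow = std::exp(-dt / as<double>(plast["tau_stdp_slow"]));
  }

  NumericVector edge_w = clone(edge_w0);
  const int n_edges = edge_w.size();

  std::vector<double> V(n, V_L), ref(n, 0.0);
  std::vector<double> aA_d(n, 0), aA_r(n, 0), aN_d(n, 0), aN_r(n, 0),
                      aG_d(n, 0), aG_r(n, 0);
  std::vector<double> u(n, U), x(n, 1.0), z(n, 0.0), zs(n, 0.0);

  const int ring_n = L + 1;
  std::vector<double> ring_exc((size_t)ring_n * n, 0.0);
  std::vector<double> ring_gab((size_t)ring_n * n, 0.0);

  std::mt19937_64 rng_ext((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 1ULL);
  std::mt19937_64 rng_resc((uint64_t)seed * 0xC2B2AE3D27D4EB4FULL + 2ULL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // external drive: per-neuron exponential waiting times, redrawn at each
  // rate-block boundary (exact by memorylessness)
  const int n_blocks = rate_hz.ncol();
  int cur_block = 0;
  std::vector<double> next_ext(n);
  auto draw_ext = [&](int i, double from) {
    double r = rate_hz(i, cur_block) / 1000.0;  // events per ms
    if (r <= 0) { next_ext[i] = R_PosInf; return; }
    next_ext[i] = from - std::log(1.0 - unif(rng_ext)) / r;
  };
  for (int i = 0; i < n; ++i) draw_ext(i, 0.0);

  const long n_steps = (long)std::lround(duration_ms / dt);
  const int steps_per_ms = (int)std::lround(1.0 / dt);

  std::vector<double> sp_t;   std::vector<int> sp_id;
  sp_t.reserve(1 << 16); sp_id.reserve(1 << 16);

  int nE = 0;
  for (int i = 0; i < n; ++i) nE += is_exc[i];
  int n_ms = record_traces ? (int)(duration_ms) : 0;
  NumericMatrix traces(record_traces ? n_ms : 0, 4);

  std::vector<double> snap_t_v;
  std::vector<double> snap_mean_v;   // n_groups per snapshot
  std::vector<double> snap_min_v;
  long snap_every = pl_on ? (long)std::lround(snap_ms / dt) : 0;

  auto take_snapshot = [&](double tnow) {
    std::vector<double> sum(n_groups, 0.0);
    std::vector<long> cnt(n_groups, 0);
    double mn = R_PosInf;
    for (int e = 0; e < n_edges; ++e) {
      if (!edge_plastic[e]) continue;
      if (edge_w[e] < mn) mn = edge_w[e];
      int g = edge_group[e];
      if (g > 0) { sum[g - 1] += edge_w[e]; cnt[g - 1]++; }
    }
    snap_t_v.push_back(tnow);
    for (int g = 0; g < n_groups; ++g)
      snap_mean_v.push_back(cnt[g] ? sum[g] / cnt[g] : NA_REAL);
    snap_min_v.push_back(mn);
  };
  if (pl_on) take_snapshot(0.0);

  std::vector<int> spikers; spikers.reserve(n);
  std::vector<double> spiker_t; spiker_t.reserve(n);

  for (long s = 0; s < n_steps; ++s) {
    double t = s * dt;

    // rate-block boundary
    while (cur_block + 1 < n_blocks && t >= block_end[cur_block]) {
      cur_block++;
      for (int i = 0; i < n; ++i) draw_ext(i, t);
    }

    // deliver latency-delayed synaptic increments
    {
      size_t off = (size_t)(s % ring_n) * n;
      for (int i = 0; i < n; ++i) {
        double e = ring_exc[off + i];
        if (e != 0.0) {
          aA_d[i] += e; aA_r[i] += e;
          aN_d[i] += e; aN_r[i] += e;
          ring_exc[off + i] = 0.0;
        }
        double g = ring_gab[off + i];
        if (g != 0.0) {
          aG_d[i] += g; aG_r[i] += g;
          ring_gab[off + i] = 0.0;
        }
      }
    }

    // external Poisson events (immediate AMPA, no STP)
    double t_next = t + dt;
    for (int i = 0; i < n; ++i) {
      while (next_ext[i] < t_next) {
        aA_d[i] += g_O[i]; aA_r[i] += g_O[i];
        double r = rate_hz(i, cur_block) / 1000.0;
        next_ext[i] -= std::log(1.0 - unif(rng_ext)) / r;
      }
    }

    // rescue resets (before integration: prevents firing in this step)
    if (resc_on && t >= resc_start) {
      double q = (t - resc_start) / resc_period;
      double phase = (q - std::floor(q)) * resc_period;
      if (phase < resc_onms) {
        for (int k = 0; k < chosen.size(); ++k) {
          int i = chosen[k];
          if (ref[i] <= 0 && unif(rng_resc) < resc_prob) V[i] = V_L;
        }
      }
    }

    // voltage integration
    spikers.clear(); spiker_t.clear();
    double sumV = 0, sumIe = 0, sumIi = 0;
    bool rec_now = record_traces && (s % steps_per_ms == 0) && (s / steps_per_ms) < n_ms;
    for (int i = 0; i < n; ++i) {
      double tau = is_exc[i] ? tau_E : tau_I;
      double GE = tau * (ampa.scale * (aA_d[i] - aA_r[i]) +
                         nmda.scale * (aN_d[i] - aN_r[i]));
      double GI = tau * gaba.scale * (aG_d[i] - aG_r[i]);
      if (rec_now && is_exc[i]) {
        sumV += V[i];
        sumIe += GE * (E_E - V[i]);
        sumIi += GI * (E_I - V[i]);
      }
      if (ref[i] > 0) { ref[i] -= dt; V[i] = V_reset; continue; }
      double v0 = V[i];
      double k1 = (V_L - v0 + GE * (E_E - v0) + GI * (E_I - v0)) / tau;
      double vmid = v0 + dt * k1;
      double k2 = (V_L - vmid + GE * (E_E - vmid) + GI * (E_I - vmid)) / tau;
      double v1 = v0 + 0.5 * dt * (k1 + k2);
      if (v1 >= V_th) {
        double frac = (V_th - v0) / (v1 - v0);
        if (!(frac >= 0 && frac <= 1)) frac = 1.0;
        double ts = t + frac * dt;
        spikers.push_back(i); spiker_t.push_back(ts);
        V[i] = V_reset;
        ref[i] = t_ref - (1.0 - frac) * dt;  // refractory measured from spike time
      } else {
        if (!std::isfinite(v1)) stop("membrane potential diverged (check parameters)");
        V[i] = v1;
      }
    }
    if (rec_now) {
      int row = (int)(s / steps_per_ms);
      traces(row, 0) = t;
      traces(row, 1) = sumV / nE;
      traces(row, 2) = sumIe / nE;
      traces(row, 3) = sumIi / nE;
    }

    // conductance accumulator decay (end-of-step)
    for (int i = 0; i < n; ++i) {
      aA_d[i] *= ampa.dec_d; aA_r[i] *= ampa.dec_r;
      aN_d[i] *= nmda.dec_d; aN_r[i] *= nmda.dec_r;
      aG_d[i] *= gaba.dec_d; aG_r[i] *= gaba.dec_r;
    }

    // STP and trace decay (exact exponential relaxation)
    for (int i = 0; i < n; ++i) {
      if (!is_exc[i]) continue;
      u[i] = U + (u[i] - U) * stp_dec_u;
      x[i] = 1.0 + (x[i] - 1.0) * stp_dec_x;
    }
    if (pl_on) {
      for (int i = 0; i < n; ++i) {
        if (!is_exc[i]) continue;
        z[i] *= tr_dec; zs[i] *= tr_dec_slow;
      }
    }

    // spike handling
    if (!spikers.empty()) {
      size_t off_w = (size_t)((s + L) % ring_n) * n;
      bool pl_window = pl_on && t >= pl_t0 && t < pl_t1;

      // pre-spike plasticity terms first (depression + transmitter-induced)
      if (pl_window && (B != 0 || delta1 != 0)) {
        for (size_t k = 0; k < spikers.size(); ++k) {
          int j = spikers[k];
          if (!is_exc[j]) continue;
          for (int e = edge_ptr[j]; e < edge_ptr[j + 1]; ++e) {
            if (!edge_plastic[e]) continue;
            double w = edge_w[e] - B * z[edge_post[e]] + delta1;
            if (w < w_min) w = w_min;
            if (w_max > 0 && w > w_max) w = w_max;
            edge_w[e] = w;
          }
        }
      }
      // post-spike terms (triplet potentiation + heterosynaptic)
      if (pl_window && (A != 0 || beta != 0)) {
        for (size_t k = 0; k < spikers.size(); ++k) {
          int i = spikers[k];
          if (!is_exc[i]) continue;
          double het_z3 = z[i] * z[i] * z[i];
          for (int p = in_ptr[i]; p < in_ptr[i + 1]; ++p) {
            int e = in_edge[p];
            double dwh = (edge_w[e] - w_tilde) / w_tilde;
            double w = edge_w[e] + A * z[in_pre[p]] * zs[i]
                       - beta * het_z3 * dwh * dwh * dwh;
            if (w < w_min) w = w_min;
            if (w_max > 0 && w > w_max) w = w_max;
            edge_w[e] = w;
          }
        }
      }

      // transmission + STP release + trace increments
      for (size_t k = 0; k < spikers.size(); ++k) {
        int j = spikers[k];
        sp_t.push_back(spiker_t[k]); sp_id.push_back(j);
        if (is_exc[j]) {
          u[j] += U * (1.0 - u[j]);       // facilitation before release
          double rel = u[j] * x[j];
          x[j] -= rel;
          for (int e = edge_ptr[j]; e < edge_ptr[j + 1]; ++e)
            ring_exc[off_w + edge_post[e]] += edge_w[e] * rel;
          if (pl_on) { z[j] += 1.0; zs[j] += 1.0; }
        } else {
          for (int e = edge_ptr[j]; e < edge_ptr[j + 1]; ++e)
            ring_gab[off_w + edge_post[e]] += edge_w[e];
        }
      }
    }

    if (pl_on && snap_every > 0 && (s + 1) % snap_every == 0)
      take_snapshot((s + 1) * dt);
  }

  List out = List::create(
    _["spike_t"] = NumericVector(sp_t.begin(), sp_t.end()),
    _["spike_id"] = IntegerVector(sp_id.begin(), sp_id.end()),
    _["weights"] = edge_w);
  if (record_traces) out["traces"] = traces;
  if (pl_on) {
    int ns = snap_t_v.size();
    NumericMatrix sm(ns, n_groups);
    for (int r = 0; r < ns; ++r)
      for (int g = 0; g < n_groups; ++g)
        sm(r, g) = snap_mean_v[(size_t)r * n_groups + g];
    out["snapshot_t"] = NumericVector(snap_t_v.begin(), snap_t_v.end());
    out["snapshot_mean"] = sm;
    out["snapshot_min"] = NumericVector(snap_min_v.begin(), snap_min_v.end());
  }
  return out;
}
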