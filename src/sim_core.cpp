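#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fixed-timestep integrator for the conductance-based excitatory
// integrate-and-fire network.
//
// Per step (length dt):
//   1. every conductance decays by the exact factor exp(-dt/tau_ex);
//   2. non-refractory neurons take one forward-Euler step of
//        tau dV/dt = (V_rest - V) + g (E_ex - V) + I_ext (+ noise),
//      refractory neurons stay clamped at V_rest while ref_remaining
//      decreases by dt;
//   3. neurons crossing V_theta emit a spike: the spike indicator stays on
//      for spike_width steps, V resets to V_rest, ref_remaining <- t_ref;
//   4. all neurons with the indicator on contribute conductance increments
//      K_i/(N-1) * sum_j w_ij y_j, applied at the end of the step so they
//      first influence the next step's membrane update.
//
// Coupling strengths may follow a piecewise-linear schedule:
// K_i(t) = k_mean(t) + delta_k(t) * k_base[i]; a constant run passes a
// single schedule row with k_mean = 0, delta_k = 1 and k_base = K_i.
// w_ = R_NilValue selects the uniform all-to-all matrix (w_ij = 1, i != j).
//
// Uses R's RNG for the membrane noise so seeding happens on the R side.

// [[Rcpp::export]]
List sim_core(NumericVector k_base, NumericMatrix sched, Nullable<NumericMatrix> w_,
              double tau, double tau_ex, double v_rest, double v_theta, double e_ex,
              double t_ref, int spike_width, double dt, double nsteps_d, double t0,
              double noise_sd, NumericVector v0, NumericVector g0,
              NumericVector ref0, IntegerVector yw0,
              bool record_traces, int trace_stride, double max_events) {
  const int N = k_base.size();
  const long nsteps = (long) nsteps_d;
  const bool uniform = w_.isNull();
  NumericMatrix w;
  if (!uniform) w = NumericMatrix(w_);

  std::vector<double> V(v0.begin(), v0.end());
  std::vector<double> g(g0.begin(), g0.end());
  std::vector<double> ref(ref0.begin(), ref0.end());
  std::vector<int> yw(yw0.begin(), yw0.end());

  const double decay = std::exp(-dt / tau_ex);
  const double h = dt / tau;
  const double noise_fac = noise_sd * std::sqrt(dt) / tau;
  const int nsched = sched.nrow();
  int si = 0;

  std::vector<int> ev_n;
  std::vector<double> ev_t;
  ev_n.reserve(4096);
  ev_t.reserve(4096);
  std::vector<int> spikers;
  spikers.reserve(N);

  std::vector<double> vtr, gtr, ttr;
  if (record_traces) {
    long ntr = nsteps / trace_stride + 1;
    vtr.reserve((size_t) ntr * N);
    gtr.reserve((size_t) ntr * N);
    ttr.reserve(ntr);
  }

  double km = sched(0, 1), dk = sched(0, 2), iext = sched(0, 3);

  for (long step = 0; step < nsteps; ++step) {
    const double t = t0 + (step + 1) * dt;

    if (nsched > 1) {
      while (si + 1 < nsched && t >= sched(si + 1, 0)) ++si;
      if (si + 1 < nsched) {
        const double f = (t - sched(si, 0)) / (sched(si + 1, 0) - sched(si, 0));
        km = sched(si, 1) + f * (sched(si + 1, 1) - sched(si, 1));
        dk = sched(si, 2) + f * (sched(si + 1, 2) - sched(si, 2));
        iext = sched(si, 3) + f * (sched(si + 1, 3) - sched(si, 3));
      } else {
        km = sched(si, 1);
        dk = sched(si, 2);
        iext = sched(si, 3);
      }
    }

    for (int i = 0; i < N; ++i) g[i] *= decay;

    for (int i = 0; i < N; ++i) {
      if (ref[i] > 0.0) {
        ref[i] -= dt;
        if (ref[i] < 1e-12) ref[i] = 0.0;
        V[i] = v_rest;
      } else {
        V[i] += h * ((v_rest - V[i]) + g[i] * (e_ex - V[i]) + iext);
        if (noise_fac > 0.0) V[i] += noise_fac * norm_rand();
        if (V[i] >= v_theta) {
          yw[i] = spike_width;
          V[i] = v_rest;
          ref[i] = t_ref;
          ev_n.push_back(i);
          ev_t.push_back(t);
        }
      }
    }

    spikers.clear();
    for (int j = 0; j < N; ++j)
      if (yw[j] > 0) spikers.push_back(j);

    if (!spikers.empty()) {
      const double S = (double) spikers.size();
      if (uniform) {
        for (int i = 0; i < N; ++i) {
          const double m = S - (yw[i] > 0 ? 1.0 : 0.0);
          if (m > 0.0) g[i] += (km + dk * k_base[i]) * m / (N - 1.0);
        }
      } else {
        for (int i = 0; i < N; ++i) {
          double s = 0.0;
          for (size_t u = 0; u < spikers.size(); ++u) {
            const int j = spikers[u];
            if (j != i) s += w(i, j);
          }
          if (s != 0.0) g[i] += (km + dk * k_base[i]) * s / (N - 1.0);
        }
      }
      for (size_t u = 0; u < spikers.size(); ++u) --yw[spikers[u]];
      if ((double) ev_n.size() > max_events)
        stop("spike event cap (%g) exceeded at t = %.3f ms; the network may be firing at every step",
             max_events, t);
    }

    if (record_traces && (step % trace_stride == 0)) {
      ttr.push_back(t);
      for (int i = 0; i < N; ++i) {
        vtr.push_back(V[i]);
        gtr.push_back(g[i]);
      }
    }

    if ((step & 1023) == 0) {
      for (int i = 0; i < N; ++i)
        if (!std::isfinite(V[i]) || !std::isfinite(g[i]))
          stop("non-finite state (V or g) for neuron %d at t = %.3f ms", i + 1, t);
      Rcpp::checkUserInterrupt();
    }
  }

  List out = List::create(
    _["neuron"] = IntegerVector(ev_n.begin(), ev_n.end()),
    _["time"] = NumericVector(ev_t.begin(), ev_t.end()),
    _["v"] = NumericVector(V.begin(), V.end()),
    _["g"] = NumericVector(g.begin(), g.end()),
    _["ref"] = NumericVector(ref.begin(), ref.end()),
    _["yw"] = IntegerVector(yw.begin(), yw.end()),
    _["t_end"] = t0 + nsteps * dt);

  if (record_traces) {
    const int nr = (int) ttr.size();
    NumericMatrix vm(nr, N), gm(nr, N);
    for (int r = 0; r < nr; ++r)
      for (int i = 0; i < N; ++i) {
        vm(r, i) = vtr[(size_t) r * N + i];
        gm(r, i) = gtr[(size_t) r * N + i];
      }
    out["trace_time"] = NumericVector(ttr.begin(), ttr.end());
    out["trace_v"] = vm;
    out["trace_g"] = gm;
  }
  return out;
}
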