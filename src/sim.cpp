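#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
#include <cstdint>
using namespace Rcpp;

// Fast double-precision exp via 2^k * exp(r) range reduction and a
// degree-7 Taylor polynomial on |r| <= ln(2)/2 (relative error < 3e-14,
// far below the forward-Euler truncation error). The membrane update
// evaluates exp once per neuron per step, which dominates the run time
// with the libm call; this inline version vectorizes.
static inline double fexp(double x) {
  // clamp: arguments beyond +-700 only arise transiently at the spike
  // ceiling, where the result is immediately reset
  if (x > 700.0) x = 700.0;
  else if (x < -700.0) return 0.0;
  const double log2e = 1.4426950408889634074;
  const double ln2_hi = 6.93147180369123816490e-01;
  const double ln2_lo = 1.90821492927058770002e-10;
  double kd = std::nearbyint(x * log2e);
  double r = (x - kd * ln2_hi) - kd * ln2_lo;
  // exp(r) on [-0.3466, 0.3466]
  double p = 1.0 + r * (1.0 + r * (0.5 + r * (1.0 / 6 + r * (1.0 / 24 +
             r * (1.0 / 120 + r * (1.0 / 720 + r * (1.0 / 5040 +
             r * (1.0 / 40320))))))));
  int64_t k = (int64_t) kd;
  int64_t bits;
  std::memcpy(&bits, &p, sizeof bits);
  bits += k << 52;
  std::memcpy(&p, &bits, sizeof p);
  return p;
}

// Forward-Euler integration of the AdEx membrane equations with the
// spike/reset rule: on V >= Vpeak the spike is recorded at the end of the
// step, V -> Vrst and q -> q + b.  Spikes detected in step k reach the
// conductances in step k+1 (one-step axonal delay).

// [[Rcpp::export]]
List adex_sim_cpp(NumericVector I_inp, double dt,
                  double C, double gL, double EL, double eta, double VT,
                  double Vpeak, double Vrst, double a, double b,
                  double tau_q,
                  double w_self, double tau_exc, double Ee,
                  bool keep_trace) {
  const int nsteps = I_inp.size();
  double V = EL, q = 0.0, g = 0.0;
  const double fE = std::exp(-dt / tau_exc);
  bool pending = false;
  std::vector<double> spikes;
  NumericVector Vtr, qtr;
  if (keep_trace) { Vtr = NumericVector(nsteps); qtr = NumericVector(nsteps); }
  for (int k = 0; k < nsteps; ++k) {
    g *= fE;
    if (pending) { g += w_self; pending = false; }
    const double Isyn = g * (Ee - V);
    const double dV = (-gL * (V - EL) + gL * eta * fexp((V - VT) / eta)
                       - q + Isyn + I_inp[k]) * dt / C;
    const double dq = (a * (V - EL) - q) * dt / tau_q;
    V += dV; q += dq;
    if (!std::isfinite(V) || !std::isfinite(q))
      stop("non-finite neuron state at t = %f ms", k * dt);
    if (V >= Vpeak) {
      spikes.push_back((k + 1) * dt);
      V = Vrst; q += b;
      if (w_self > 0.0) pending = true;
    }
    if (keep_trace) { Vtr[k] = V; qtr[k] = q; }
  }
  return List::create(_["spikes"] = wrap(spikes),
                      _["V"] = Vtr, _["q"] = qtr,
                      _["g_end"] = g);
}

// Full motor-map simulation.  Neurons live on a rectangular grid with u
// varying fastest (index n = iu + n_u*iv).  Lateral coupling is the
// difference-of-Gaussians kernel, separable along the two map axes, scaled
// by the postsynaptic s_n and divided by pop_scale.  The electrode field is
// precomputed per neuron and gated by the rectangular pulse.

// [[Rcpp::export]]
List sc_sim_cpp(int n_u, int n_v,
                NumericVector tau_q, NumericVector s,
                double du, double dv,
                double C, double gL, double EL, double eta, double VT,
                double Vpeak, double Vrst, double a, double b,
                double Ee, double Ei, double tau_exc, double tau_inh,
                double wbar_exc, double wbar_inh,
                double sigma_exc, double sigma_inh, double pop_scale,
                NumericVector field,
                double t_on, double DS,
                bool lateral, double dt, double t_end,
                IntegerVector trace_idx, double trace_dt) {
  const int N = n_u * n_v;
  if (tau_q.size() != N || s.size() != N || field.size() != N)
    stop("per-neuron vectors must have length n_u * n_v");
  const int nsteps = (int) std::lround(t_end / dt);
  const double fE = std::exp(-dt / tau_exc);
  const double fI = std::exp(-dt / tau_inh);

  std::vector<double> V(N, EL), q(N, 0.0), gE(N, 0.0), gI(N, 0.0);
  std::vector<double> accE(N), accI(N);
  // postsynaptic scale factors (nS per unit kernel sum)
  std::vector<double> sE(N), sI(N);
  for (int n = 0; n < N; ++n) {
    sE[n] = s[n] * wbar_exc / pop_scale;
    sI[n] = s[n] * wbar_inh / pop_scale;
  }
  // separable kernel lookup tables along each axis
  std::vector<double> KuE(n_u), KvE(n_v), KuI(n_u), KvI(n_v);
  for (int i = 0; i < n_u; ++i) {
    const double d = i * du;
    KuE[i] = std::exp(-d * d / (2.0 * sigma_exc * sigma_exc));
    KuI[i] = std::exp(-d * d / (2.0 * sigma_inh * sigma_inh));
  }
  for (int j = 0; j < n_v; ++j) {
    const double d = j * dv;
    KvE[j] = std::exp(-d * d / (2.0 * sigma_exc * sigma_exc));
    KvI[j] = std::exp(-d * d / (2.0 * sigma_inh * sigma_inh));
  }

  std::vector<int> sp_idx;      // spikes pending for next step's stamps
  std::vector<int> ev_neuron;   // raster
  std::vector<double> ev_time;

  const int n_trace = trace_idx.size();
  const int trace_every = n_trace > 0 ? std::max(1, (int) std::lround(trace_dt / dt)) : 0;
  std::vector<double> trV, trq, trgE, trgI, trt;

  for (int k = 0; k < nsteps; ++k) {
    const double t = k * dt;
    const bool pulse_on = (t >= t_on) && (t < t_on + DS);
    const bool has_stamps = lateral && !sp_idx.empty();
    if (has_stamps) {
      std::memset(accE.data(), 0, N * sizeof(double));
      std::memset(accI.data(), 0, N * sizeof(double));
      for (size_t m = 0; m < sp_idx.size(); ++m) {
        const int iu0 = sp_idx[m] % n_u;
        const int iv0 = sp_idx[m] / n_u;
        for (int j = 0; j < n_v; ++j) {
          const double kvE = KvE[std::abs(j - iv0)];
          const double kvI = KvI[std::abs(j - iv0)];
          double *aE = accE.data() + (size_t) j * n_u;
          double *aI = accI.data() + (size_t) j * n_u;
          const int base = iu0;
          for (int i = 0; i < n_u; ++i) {
            const int di = i >= base ? i - base : base - i;
            aE[i] += kvE * KuE[di];
            aI[i] += kvI * KuI[di];
          }
        }
      }
      sp_idx.clear();
    } else if (lateral) {
      sp_idx.clear();
    }

    const double dtC = dt / C;
    const double gLeta = gL * eta;
    const double inv_eta = 1.0 / eta;
    double bad = 0.0;
    for (int n = 0; n < N; ++n) {
      double ge = gE[n] * fE;
      double gi = gI[n] * fI;
      if (has_stamps) { ge += sE[n] * accE[n]; gi += sI[n] * accI[n]; }
      const double Vn = V[n];
      double Iin = ge * (Ee - Vn) + gi * (Ei - Vn);
      if (pulse_on) Iin += field[n];
      const double dV = (-gL * (Vn - EL) + gLeta * fexp((Vn - VT) * inv_eta)
                         - q[n] + Iin) * dtC;
      double Vn1 = Vn + dV;
      double qn1 = q[n] + (a * (Vn - EL) - q[n]) * dt / tau_q[n];
      bad += dV;  // accumulates NaN if any state went non-finite
      if (Vn1 >= Vpeak) {
        Vn1 = Vrst; qn1 += b;
        ev_neuron.push_back(n + 1);
        ev_time.push_back((k + 1) * dt);
        if (lateral) sp_idx.push_back(n);
      }
      V[n] = Vn1; q[n] = qn1; gE[n] = ge; gI[n] = gi;
    }
    if (!std::isfinite(bad)) {
      for (int n = 0; n < N; ++n)
        if (!std::isfinite(V[n]) || !std::isfinite(q[n]))
          stop("non-finite state for neuron %d at t = %f ms", n + 1, t);
      stop("non-finite state at t = %f ms", t);
    }

    if (n_trace > 0 && ((k + 1) % trace_every == 0)) {
      trt.push_back((k + 1) * dt);
      for (int m = 0; m < n_trace; ++m) {
        const int n = trace_idx[m] - 1;
        trV.push_back(V[n]); trq.push_back(q[n]);
        trgE.push_back(gE[n]); trgI.push_back(gI[n]);
      }
    }
  }

  List out = List::create(_["neuron"] = wrap(ev_neuron),
                          _["time"] = wrap(ev_time));
  if (n_trace > 0) {
    out["trace_time"] = wrap(trt);
    out["trace_V"] = wrap(trV);
    out["trace_q"] = wrap(trq);
    out["trace_gexc"] = wrap(trgE);
    out["trace_ginh"] = wrap(trgI);
  }
  return out;
}
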