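// Clock-driven core for current-based LIF neurons with exponential PSCs.
//
// Subthreshold integration uses the exact propagator of the linear system
//   C_m dV/dt = -g_m (V - V_L) + I_ex(t) + I_in(t) + I_const
//   tau_s dI_s/dt = -I_s                      (s in {ex, in})
// over a fixed step dt, so zero-input decay toward V_L is exact to machine
// precision. Spikes are detected on the grid; delivery (recurrent and
// background) lands in the current buffers at the end of a step and therefore
// affects the membrane from the next step: a single global delay of one step.
//
// All randomness goes through R's RNG (GetRNGstate/PutRNGstate via Rcpp), so
// results are bit-for-bit reproducible under set.seed(). Background spike
// counts per neuron per step are Poisson(rate_khz * dt); for speed they are
// drawn by inverted-CDF lookup from a per-neuron table built once per call,
// falling back to R::rpois in the (rare) far tail.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// cumulative Poisson probabilities up to kmax; returns table of size kmax+1
std::vector<double> pois_cdf_table(double mu, int kmax) {
  std::vector<double> cdf(kmax + 1);
  double p = std::exp(-mu); // P(0)
  double c = p;
  cdf[0] = c;
  for (int k = 1; k <= kmax; ++k) {
    p *= mu / k;
    c += p;
    cdf[k] = c;
  }
  return cdf;
}

inline int pois_draw(const std::vector<double>& cdf, double mu) {
  double u = unif_rand();
  const int kmax = static_cast<int>(cdf.size()) - 1;
  for (int k = 0; k <= kmax; ++k) {
    if (u <= cdf[k]) return k;
  }
  // far tail (prob < ~1e-12): exact fallback
  return static_cast<int>(R::rpois(mu));
}

} // namespace

// [[Rcpp::export(name = ".advance_core")]]
List advance_core(NumericVector V_in, NumericVector I_ex_in,
                  NumericVector I_in_in, NumericVector refr_in,
                  NumericVector lambda_in,
                  NumericVector V_L, NumericVector V_thr, NumericVector V_res,
                  NumericVector tau_m, NumericVector C_m,
                  NumericVector tau_ref,
                  NumericVector tau_syn_ex, NumericVector tau_syn_in,
                  NumericVector I_const,
                  NumericVector bg_rate_khz, NumericVector bg_weight,
                  IntegerVector csr_ptr, IntegerVector csr_tgt,
                  NumericVector csr_w,
                  double t0, double dt, int n_steps,
                  double tau_rate_ms) {
  const int n = V_in.size();
  RNGScope rng;

  // work on copies: the caller's state must not be mutated, and state
  // vectors may alias parameter vectors (e.g. V initialized from V_L)
  NumericVector V = clone(V_in), I_ex = clone(I_ex_in), I_in = clone(I_in_in),
                refr = clone(refr_in), lambda = clone(lambda_in);

  // per-neuron propagator constants
  std::vector<double> Pm(n), Dex(n), Din(n), Gex(n), Gin(n), Rdc(n);
  for (int i = 0; i < n; ++i) {
    const double em = std::exp(-dt / tau_m[i]);
    const double eex = std::exp(-dt / tau_syn_ex[i]);
    const double ein = std::exp(-dt / tau_syn_in[i]);
    Pm[i] = em;
    Dex[i] = eex;
    Din[i] = ein;
    // contribution of an exponential current with amplitude I to V over dt;
    // C_m arrives in pF so pA * ms / pF = mV
    const double te = tau_syn_ex[i], ti = tau_syn_in[i], tm = tau_m[i];
    Gex[i] = (std::abs(tm - te) < 1e-12)
                 ? dt * em / C_m[i]
                 : (tm * te) / (C_m[i] * (te - tm)) * (eex - em);
    Gin[i] = (std::abs(tm - ti) < 1e-12)
                 ? dt * em / C_m[i]
                 : (tm * ti) / (C_m[i] * (ti - tm)) * (ein - em);
    Rdc[i] = (tau_m[i] / C_m[i]) * (1.0 - em); // DC gain for I_const
  }

  std::vector<double> bg_mu(n);
  std::vector<std::vector<double> > bg_cdf(n);
  for (int i = 0; i < n; ++i) {
    bg_mu[i] = bg_rate_khz[i] * dt;
    if (bg_mu[i] > 0) {
      // table out to mean + 10 sd (>= 8): tail mass negligible
      int kmax = static_cast<int>(std::ceil(bg_mu[i] + 10.0 * std::sqrt(bg_mu[i]) + 8.0));
      bg_cdf[i] = pois_cdf_table(bg_mu[i], kmax);
    }
  }

  std::vector<double> t_last(n, t0); // last rate-filter update per neuron
  std::vector<int> spike_id;
  std::vector<double> spike_t;
  std::vector<double> bg_count(n, 0.0);

  const double inv_tau_spk = 1000.0 / tau_rate_ms; // 1/tau in spikes/s

  for (int s = 1; s <= n_steps; ++s) {
    const double t = t0 + s * dt;
    int first_spike = -1;
    int n_new = 0;
    for (int i = 0; i < n; ++i) {
      const double Vprop = V_L[i] + (V[i] - V_L[i]) * Pm[i] +
                           I_ex[i] * Gex[i] + I_in[i] * Gin[i] +
                           I_const[i] * Rdc[i];
      I_ex[i] *= Dex[i];
      I_in[i] *= Din[i];
      if (refr[i] > 0.0) {
        refr[i] -= dt;
        V[i] = V_res[i]; // clamped during refractoriness
      } else {
        V[i] = Vprop;
        if (V[i] >= V_thr[i]) {
          // spike: reset, refractory clock, exact rate-filter recursion
          V[i] = V_res[i];
          refr[i] = tau_ref[i];
          lambda[i] = lambda[i] * std::exp(-(t - t_last[i]) / tau_rate_ms) +
                      inv_tau_spk;
          t_last[i] = t;
          spike_id.push_back(i + 1);
          spike_t.push_back(t);
          if (first_spike < 0) first_spike = static_cast<int>(spike_id.size()) - 1;
          ++n_new;
        }
      }
      if (!std::isfinite(V[i])) {
        stop("non-finite membrane potential in neuron %d at t = %f ms", i + 1, t);
      }
      // background input (delivered into next step's currents)
      if (bg_mu[i] > 0.0) {
        const int k = pois_draw(bg_cdf[i], bg_mu[i]);
        if (k > 0) {
          I_ex[i] += k * bg_weight[i];
          bg_count[i] += k;
        }
      }
    }
    // recurrent delivery of this step's spikes (one-step delay)
    if (n_new > 0 && csr_ptr.size() > 1) {
      for (int q = first_spike; q < first_spike + n_new; ++q) {
        const int src = spike_id[q] - 1;
        for (int e = csr_ptr[src]; e < csr_ptr[src + 1]; ++e) {
          const double w = csr_w[e];
          const int tgt = csr_tgt[e] - 1;
          if (w >= 0.0) I_ex[tgt] += w; else I_in[tgt] += w;
        }
      }
    }
  }

  // decay all rate filters to the end time so lambda is synchronous
  const double t_end = t0 + n_steps * dt;
  for (int i = 0; i < n; ++i) {
    if (t_end > t_last[i]) {
      lambda[i] *= std::exp(-(t_end - t_last[i]) / tau_rate_ms);
    }
  }

  return List::create(
      _["V"] = V, _["I_ex"] = I_ex, _["I_in"] = I_in, _["refr"] = refr,
      _["lambda"] = lambda,
      _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
      _["spike_t"] = NumericVector(spike_t.begin(), spike_t.end()),
      _["bg_count"] = NumericVector(bg_count.begin(), bg_count.end()));
}
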