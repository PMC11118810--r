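#include <Rcpp.h>
using namespace Rcpp;

// Per-trial coupled phase-diffusion simulation and iPLV readout.
//
// For each trial: the seed phase follows phi0 + 2*pi*f*t + Wiener noise on
// an axis extended by `pad` samples at both ends (to allow lagged drives);
// each target runs its own independent walk psi and is pulled toward the
// lagged seed phase minus its offset with convex weight kappa. The
// per-trial iPLV over the first `n_epoch` core samples is
// |mean(sin(phi_seed - phi_target))|; the seed phase at the last core
// sample (the pulse) is returned wrapped to (-pi, pi].
//
// RNG: uses R's RNG stream (set.seed() in R controls reproducibility).
// [[Rcpp::export]]
List cpp_phase_iplv(int n_trials, int n_core, int n_epoch, int pad,
                    double dt, double f, double sigma,
                    NumericVector offsets, NumericVector detune,
                    IntegerVector lag_samp, NumericMatrix kappa) {
  int n_t = offsets.size();
  int n_ext = n_core + 2 * pad;
  double sdt = sigma * std::sqrt(dt);
  double w = 2 * M_PI * f * dt;

  NumericMatrix iplv(n_trials, n_t);
  NumericVector phase_pulse(n_trials);
  std::vector<double> phi_s(n_ext), psi(n_core);

  RNGScope scope;
  for (int k = 0; k < n_trials; ++k) {
    double ph = R::runif(-M_PI, M_PI);
    for (int t = 0; t < n_ext; ++t) {
      phi_s[t] = ph;
      ph += w + sdt * norm_rand();
    }
    for (int i = 0; i < n_t; ++i) {
      double kap = kappa(k, i);
      double wi = 2 * M_PI * (f + detune[i]) * dt; // own natural frequency
      double pp = R::runif(-M_PI, M_PI);
      for (int t = 0; t < n_core; ++t) {
        psi[t] = pp;
        pp += wi + sdt * norm_rand();
      }
      double acc = 0.0;
      int shift = pad - lag_samp[i];
      for (int t = 0; t < n_epoch; ++t) {
        double drive = phi_s[t + shift] - offsets[i] - psi[t];
        drive -= 2 * M_PI * std::round(drive / (2 * M_PI));
        double phi_t = psi[t] + kap * drive;
        acc += std::sin(phi_s[t + pad] - phi_t);
      }
      iplv(k, i) = std::fabs(acc / n_epoch);
    }
    double p0 = phi_s[pad + n_core - 1];
    p0 = std::atan2(std::sin(p0), std::cos(p0));
    if (p0 == -M_PI) p0 = M_PI;
    phase_pulse[k] = p0;
  }
  return List::create(_["iplv"] = iplv, _["phase_at_pulse"] = phase_pulse);
}
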