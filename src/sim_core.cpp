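#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama integration of the fully connected delayed-pulse-coupled
// noisy LIF network in dimensionless voltage units (threshold 1, rest 0).
//
// Per step: leak + drive + noise update, then the inhibitory kick from the
// population spike count 'delay_steps' ago (K/N per presynaptic spike),
// then the threshold test; units above threshold emit a spike timestamped
// at this step and are reset within the step. Uses R's RNG so results are
// reproducible under set.seed().
//
// [[Rcpp::export]]
List sim_lif_cpp(int N, int n_steps, double dt, double tau_m, double K,
                 double D, double V_R, int delay_steps, NumericVector I_E,
                 bool record_snapshots, int snapshot_stride) {
  const double V_T = 1.0;
  NumericVector v = runif(N, V_R, V_T);   // initial condition
  std::vector<int> count(n_steps, 0);
  std::vector<int> spike_unit;
  std::vector<double> spike_time;
  spike_unit.reserve(n_steps / 10 + 64);
  spike_time.reserve(n_steps / 10 + 64);
  NumericVector mean_v(n_steps);
  const double a = dt / tau_m;
  const double noise_sd = std::sqrt(2.0 * D * dt / tau_m);
  const double kick = K / (double)N;

  int n_snap = 0;
  NumericMatrix snaps;
  IntegerVector snap_steps;
  if (record_snapshots) {
    n_snap = (n_steps + snapshot_stride - 1) / snapshot_stride;
    snaps = NumericMatrix(N, n_snap);
    snap_steps = IntegerVector(n_snap);
  }
  int isnap = 0;

  for (int t = 0; t < n_steps; ++t) {
    NumericVector xi = rnorm(N);
    double inh = 0.0;
    if (t >= delay_steps && count[t - delay_steps] > 0)
      inh = kick * count[t - delay_steps];
    const double drive = I_E[t];
    int c = 0;
    double mv = 0.0;
    for (int i = 0; i < N; ++i) {
      double vi = v[i] + a * (drive - v[i]) + noise_sd * xi[i] - inh;
      if (!std::isfinite(vi))
        stop("non-finite membrane potential at step %d; reduce dt or drive",
             t);
      if (vi >= V_T) {
        spike_unit.push_back(i + 1);
        spike_time.push_back(t * dt);
        vi = V_R;
        ++c;
      }
      v[i] = vi;
      mv += vi;
    }
    count[t] = c;
    mean_v[t] = mv / N;
    if (record_snapshots && t % snapshot_stride == 0) {
      for (int i = 0; i < N; ++i) snaps(i, isnap) = v[i];
      snap_steps[isnap] = t;
      ++isnap;
    }
  }
  List out = List::create(
    _["spike_unit"] = wrap(spike_unit),
    _["spike_time"] = wrap(spike_time),
    _["count"] = wrap(count),
    _["mean_v"] = mean_v);
  if (record_snapshots) {
    out["snapshots"] = snaps;
    out["snapshot_steps"] = snap_steps;
  }
  return out;
}

// Scalar (uncoupled, noiseless) deterministic LIF reference used by tests.
// [[Rcpp::export]]
NumericVector lif_deterministic_period_cpp(double I_E, double V_R,
                                           double tau_m) {
  NumericVector out(1);
  out[0] = tau_m * std::log((I_E - V_R) / (I_E - 1.0));
  return out;
}

// Forward-Euler integration of the Gaussian-drift delay differential
// equation. The population rate is the drift current of a fixed-variance
// Gaussian across threshold, clipped at zero for downward drift. With
// 'with_reset', at the end of each population spike (sign change of dmu/dt
// from + to - after the cycle produced rate above 'rate_floor') the mean is
// shifted down by (V_T - V_R) times the saturation, and the rate is clipped
// to zero for one delay window (the reset makes dmu/dt transiently positive
// again, which would otherwise register as a spurious population spike).
//
// [[Rcpp::export]]
List dde_cpp(int n_steps, double dt, double tau_m, double K, double D,
             double V_R, int delay_steps, NumericVector I_E, double mu0,
             bool with_reset, double rate_floor, NumericVector s_ref) {
  const double V_T = 1.0;
  NumericVector mu(n_steps), r(n_steps), mudot(n_steps);
  std::vector<double> reset_t, reset_from, reset_to;
  const double norm = 1.0 / std::sqrt(2.0 * M_PI * D);
  double m = mu0;
  bool cycle_active = false;     // rate exceeded floor since last spike end
  int clip_until = -1;           // rate clipped to zero up to this step
  for (int t = 0; t < n_steps; ++t) {
    double r_del = (t >= delay_steps) ? r[t - delay_steps] : 0.0;
    double dm = (I_E[t] - K * tau_m * r_del - m) / tau_m;
    double rate = 0.0;
    if (dm > 0.0 && t > clip_until)
      rate = dm * norm * std::exp(-(V_T - m) * (V_T - m) / (2.0 * D));
    mu[t] = m;
    mudot[t] = dm;
    r[t] = rate;
    if (rate > rate_floor) cycle_active = true;
    // end of population spike: dmu/dt crosses + -> -
    if (t > 0 && mudot[t - 1] >= 0.0 && dm < 0.0 && cycle_active) {
      if (with_reset) {
        double mu_max = m;
        // reset magnitude: saturation from the closed-form cycle theory at
        // the current drive when available (s_ref >= 0), else from the
        // suprathreshold Gaussian mass at the detected peak
        double s = (s_ref[t] >= 0.0)
          ? s_ref[t]
          : 0.5 * erfc((V_T - mu_max) / std::sqrt(2.0 * D));
        double mu_reset = mu_max - (V_T - V_R) * s;
        reset_t.push_back(t * dt);
        reset_from.push_back(mu_max);
        reset_to.push_back(mu_reset);
        m = mu_reset;
        mu[t] = m;
        clip_until = t + delay_steps;
        r[t] = 0.0;
      }
      cycle_active = false;
    }
    if (!std::isfinite(m))
      stop("non-finite mean membrane potential at step %d", t);
    m += dt * dm;
  }
  return List::create(
    _["mu"] = mu, _["r"] = r, _["mudot"] = mudot,
    _["reset_t"] = wrap(reset_t), _["reset_from"] = wrap(reset_from),
    _["reset_to"] = wrap(reset_to));
}
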