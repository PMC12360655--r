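#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integrator for the laminar mean-field network.
//
// Node kinds: 0 = mean-field rate node (FI curve + per-node OU noise),
//             1 = spiking pacemaker node (population of Izhikevich neurons,
//                 mean-field input/output conversion).
// Rates are in Hz throughout; currents in nA; time in seconds.
// All randomness is drawn from R's RNG so set.seed() at the R level makes
// runs bit-reproducible. Draw order per step: nodes in index order
// (one N(0,1) per mean-field node, n_neurons per pacemaker node).

static inline double fi_rate_c(double I, double lambda, double beta, double theta) {
  double x = lambda * I - beta;
  double r;
  if (std::fabs(x) < 1e-9) {
    r = 1.0 / theta;
  } else {
    r = x / (1.0 - std::exp(-theta * x));
  }
  return r > 0.0 ? r : 0.0;
}

// [[Rcpp::export]]
List cpp_simulate(IntegerVector node_kind,
                  NumericVector fi_lambda,
                  NumericVector fi_beta,
                  NumericVector fi_theta,
                  NumericVector i_base,
                  NumericVector sigma_eps,
                  NumericVector tau_eps,
                  IntegerVector c_src,
                  IntegerVector c_tgt,
                  IntegerVector c_delay,
                  NumericVector c_w,
                  NumericVector c_tau,
                  NumericVector c_gamma,
                  NumericMatrix ext,
                  double dt,
                  int n_steps,
                  int pace_n,
                  double pace_a,
                  double pace_b,
                  double pace_c,
                  double pace_d,
                  double pace_mu,
                  double pace_sigma,
                  double pace_gain,
                  int pace_noise_quenched,
                  double rate_guard) {
  const int n_nodes = node_kind.size();
  const int n_conn  = c_src.size();

  NumericMatrix rates(n_steps, n_nodes);
  NumericVector s(n_conn);          // synaptic gates, start at 0
  NumericVector eps(n_nodes);       // OU noise state, start at 0
  NumericVector r_prev(n_nodes);    // rates at t = 0 (delay-buffer seed)
  long clamp_count = 0;

  // Pacemaker membrane state, one block per pacemaker node
  std::vector<int> pace_slot(n_nodes, -1);
  int n_pace = 0;
  for (int i = 0; i < n_nodes; ++i)
    if (node_kind[i] == 1) pace_slot[i] = n_pace++;
  std::vector<std::vector<double> > pv(n_pace), pu(n_pace), peta(n_pace);
  for (int p = 0; p < n_pace; ++p) {
    pv[p].assign(pace_n, -70.0);
    pu[p].assign(pace_n, pace_b * -70.0);
  }
  std::vector<char> spiked(pace_n);

  // initial rates: mean-field nodes at the FI value of their base current
  for (int i = 0; i < n_nodes; ++i) {
    r_prev[i] = (node_kind[i] == 0)
      ? fi_rate_c(i_base[i], fi_lambda[i], fi_beta[i], fi_theta[i])
      : 0.0;
  }

  RNGScope rngscope;
  const double izh_dt = dt * 1000.0 / 2.0; // two substeps, in ms (Izhikevich units)

  // quenched mode: the per-neuron Gaussian term is frozen at trial start
  if (pace_noise_quenched) {
    for (int p = 0; p < n_pace; ++p) {
      peta[p].resize(pace_n);
      for (int n = 0; n < pace_n; ++n) peta[p][n] = R::norm_rand();
    }
  }

  for (int t = 0; t < n_steps; ++t) {
    // 1. synaptic gates, driven by delayed presynaptic rates
    for (int k = 0; k < n_conn; ++k) {
      int tl = t - 1 - c_delay[k];
      double rd = (tl >= 0) ? rates(tl, c_src[k]) : r_prev[c_src[k]];
      double sk = s[k] + dt * (-s[k] / c_tau[k] + c_gamma[k] * (1.0 - s[k]) * rd);
      if (sk < 0.0) { sk = 0.0; ++clamp_count; }
      else if (sk > 1.0) { sk = 1.0; ++clamp_count; }
      s[k] = sk;
    }

    // 2. node updates
    for (int i = 0; i < n_nodes; ++i) {
      double I = i_base[i] + ext(t, i);
      for (int k = 0; k < n_conn; ++k)
        if (c_tgt[k] == i) I += c_w[k] * s[k];

      double r;
      if (node_kind[i] == 0) {
        // OU noise: Euler-Maruyama scaled so stationary SD = sigma_eps
        if (sigma_eps[i] > 0.0) {
          eps[i] = eps[i] * (1.0 - dt / tau_eps[i]) +
            sigma_eps[i] * std::sqrt(2.0 * dt / tau_eps[i]) * R::norm_rand();
        } else if (eps[i] != 0.0) {
          eps[i] = eps[i] * (1.0 - dt / tau_eps[i]);
        }
        I += eps[i];
        r = fi_rate_c(I, fi_lambda[i], fi_beta[i], fi_theta[i]);
      } else {
        // pacemaker population: per-neuron scaled input + Gaussian noise
        int p = pace_slot[i];
        std::vector<double> &v = pv[p], &u = pu[p];
        int n_spk = 0;
        std::fill(spiked.begin(), spiked.end(), 0);
        for (int n = 0; n < pace_n; ++n) {
          double In = 4.0 * I + pace_mu + pace_sigma *
            (pace_noise_quenched ? peta[p][n] : R::norm_rand());
          for (int sub = 0; sub < 2; ++sub) {
            if (v[n] >= 30.0) {
              spiked[n] = 1;
              v[n] = pace_c;
              u[n] += pace_d;
            }
            double vn = v[n];
            v[n] = vn + izh_dt * (0.04 * vn * vn + 5.0 * vn + 140.0 - u[n] + In);
            u[n] = u[n] + izh_dt * (pace_a * (pace_b * vn - u[n]));
          }
        }
        for (int n = 0; n < pace_n; ++n) n_spk += spiked[n];
        r = pace_gain * (double)n_spk / (double)pace_n / dt;
      }

      // pacemaker output is bounded by gain/dt by construction; the rate
      // guard protects against mean-field blow-up only
      if (!std::isfinite(r) || (node_kind[i] == 0 && r > rate_guard))
        stop("numerical divergence at step %d, node %d (rate %g)", t + 1, i + 1, r);
      rates(t, i) = r;
    }
  }

  return List::create(_["rates"] = rates,
                      _["gates"] = s,
                      _["clamped"] = (double)clamp_count);
}

// Single Izhikevich population driven by a prescribed node-current trace.
// Used for the isolated-pacemaker analyses; shares the stepping code path
// conventions with cpp_simulate (two 0.5 ms membrane substeps per 1 ms step).
// [[Rcpp::export]]
List cpp_population(NumericVector drive,
                    double dt,
                    int pace_n,
                    double pace_a,
                    double pace_b,
                    double pace_c,
                    double pace_d,
                    double pace_mu,
                    double pace_sigma,
                    double pace_gain,
                    double w_self,
                    double tau_self,
                    double gamma_self,
                    int pace_noise_quenched) {
  const int n_steps = drive.size();
  NumericVector rate(n_steps), frac(n_steps);
  std::vector<double> v(pace_n, -70.0), u(pace_n, pace_b * -70.0);
  std::vector<char> spiked(pace_n);
  double s_self = 0.0;
  RNGScope rngscope;
  const double izh_dt = dt * 1000.0 / 2.0;
  std::vector<double> eta(pace_n);
  if (pace_noise_quenched)
    for (int n = 0; n < pace_n; ++n) eta[n] = R::norm_rand();

  for (int t = 0; t < n_steps; ++t) {
    double I = drive[t] + w_self * s_self;
    int n_spk = 0;
    std::fill(spiked.begin(), spiked.end(), 0);
    for (int n = 0; n < pace_n; ++n) {
      double In = 4.0 * I + pace_mu + pace_sigma *
        (pace_noise_quenched ? eta[n] : R::norm_rand());
      for (int sub = 0; sub < 2; ++sub) {
        if (v[n] >= 30.0) {
          spiked[n] = 1;
          v[n] = pace_c;
          u[n] += pace_d;
        }
        double vn = v[n];
        v[n] = vn + izh_dt * (0.04 * vn * vn + 5.0 * vn + 140.0 - u[n] + In);
        u[n] = u[n] + izh_dt * (pace_a * (pace_b * vn - u[n]));
      }
      if (!std::isfinite(v[n])) stop("numerical divergence in population at step %d", t + 1);
      n_spk += spiked[n];
    }
    double f = (double)n_spk / (double)pace_n;
    frac[t] = f;
    double r = pace_gain * f / dt;
    rate[t] = r;
    s_self += dt * (-s_self / tau_self + gamma_self * (1.0 - s_self) * r);
    if (s_self < 0.0) s_self = 0.0;
    if (s_self > 1.0) s_self = 1.0;
  }
  return List::create(_["rate"] = rate, _["fraction"] = frac);
}
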