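#include <Rcpp.h>
using namespace Rcpp;

// Single-compartment pacemaker integrator (fixed-step explicit Euler).
// Units: mV, ms, uM, mS/cm2, uA/cm2, C_m = 1 uF/cm2.  Injected and noise
// currents are supplied in pA and divided by the membrane area (pF <->
// cm2 through 1 uF/cm2).  The SK conductance is calcium-gated with Hill
// activation; phi right-shifts the half-activation (reduced sensitivity).

static inline double sig(double v, double v0, double k) {
  return 1.0 / (1.0 + std::exp(-(v - v0) / k));
}

// [[Rcpp::export(name = ".pacemaker_core")]]
List pacemaker_core(List par, double duration_ms, double dt,
                    double step_pA, double step_on_ms, double step_off_ms,
                    int out_every) {
  const double gNa = par["g_na"], gK = par["g_k"], gCa = par["g_ca"],
               gSK = par["g_sk"], gA = par["g_a"], gL = par["g_leak"];
  const double k_half = par["sk_k_half"], hill = par["sk_hill"],
               phi = par["phi"];
  const double k_ca = par["ca_gain"], tau_ca = par["ca_tau"],
               ca_rest = par["ca_rest"];
  const double sigma = par["noise_pA"], tau_ou = par["noise_tau_ms"];
  const double area_um2 = par["area_um2"];
  const double tau_b = par["tau_a_inact"];
  const double eNa = 55.0, eK = -90.0, eCa = 120.0, eL = par["e_leak"];

  const double pA_to_uAcm2 = 1.0 / (area_um2 * 0.01); // area_um2*1e-8 cm2; pA=1e-6 uA
  const double k_eff = k_half * (1.0 + 2.0 * phi);
  const long n_steps = (long)std::ceil(duration_ms / dt);
  const long n_out = n_steps / out_every + 1;

  NumericVector V_out(n_out), ca_out(n_out);
  std::vector<double> spikes;

  double V = -60.0, h = 0.8, n = 0.1, b = 0.2, ca = ca_rest, Iou = 0.0;
  const double ou_decay = std::exp(-dt / tau_ou);
  const double ou_sd = sigma * std::sqrt(1.0 - ou_decay * ou_decay);

  bool above = false;
  double peak_v = 0.0, peak_t = 0.0;

  RNGScope rng;
  long oi = 0;
  V_out[oi] = V; ca_out[oi] = ca; ++oi;

  for (long i = 1; i <= n_steps; ++i) {
    const double t = i * dt;
    const double minf = sig(V, -38.0, 4.5);
    const double hinf = sig(-V, 52.0, 7.0);   // 1/(1+exp((V+52)/7))
    const double tauh = 0.5 + 12.0 / (1.0 + std::exp((V + 45.0) / 8.0));
    const double ninf = sig(V, -30.0, 8.0);
    const double taun = 1.0 + 5.0 / (1.0 + std::exp((V + 30.0) / 10.0));
    const double ainf = sig(V, -45.0, 8.0);
    const double binf = sig(-V, 70.0, 6.0);
    const double cinf = sig(V, -20.0, 4.0);

    const double INa = gNa * minf * minf * minf * h * (V - eNa);
    const double IK  = gK * n * n * n * n * (V - eK);
    const double ICa = gCa * cinf * (V - eCa);
    const double can = std::pow(ca, hill);
    const double ISK = gSK * can / (can + std::pow(k_eff, hill)) * (V - eK);
    const double IA  = gA * ainf * ainf * ainf * b * (V - eK);
    const double IL  = gL * (V - eL);

    double Iinj = 0.0;
    if (step_pA != 0.0 && t >= step_on_ms && t < step_off_ms) Iinj = step_pA;
    const double Iext = (Iinj + Iou) * pA_to_uAcm2;

    const double dV = -(INa + IK + ICa + ISK + IA + IL) + Iext;
    V += dt * dV;
    h += dt * (hinf - h) / tauh;
    n += dt * (ninf - n) / taun;
    b += dt * (binf - b) / tau_b;
    ca += dt * (-k_ca * ICa - (ca - ca_rest) / tau_ca);
    if (ca < 0.0) ca = 0.0;
    if (sigma > 0.0) Iou = Iou * ou_decay + ou_sd * R::norm_rand();

    if (!R_FINITE(V) || std::fabs(V) > 200.0)
      stop("pacemaker integration diverged (|V| > 200 mV) at t = %f ms; "
           "reduce dt or check conductances", t);

    // peak-based spike times: track the maximum between -10 mV crossings
    if (!above && V >= -10.0) { above = true; peak_v = V; peak_t = t; }
    else if (above) {
      if (V > peak_v) { peak_v = V; peak_t = t; }
      if (V < -10.0) { above = false; spikes.push_back(peak_t); }
    }

    if (i % out_every == 0 && oi < n_out) { V_out[oi] = V; ca_out[oi] = ca; ++oi; }
  }

  return List::create(_["V"] = V_out, _["ca"] = ca_out,
                      _["spike_ms"] = NumericVector(spikes.begin(), spikes.end()),
                      _["dt_ms"] = dt * out_every);
}
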