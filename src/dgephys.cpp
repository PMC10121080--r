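#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with explicit initial state.
// b, a: coefficient vectors (a[0] must be non-zero); zi: length max(na,nb)-1.
// [[Rcpp::export(".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x,
                         NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nf = std::max(na, nb);
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0), z(nf - 1, 0.0);
  double a0 = a[0];
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  if ((int)zi.size() != nf - 1) stop("zi must have length max(na, nb) - 1");
  for (int i = 0; i < nf - 1; ++i) z[i] = zi[i];

  int n = x.size();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int j = 0; j < nf - 2; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    z[nf - 2] = bb[nf - 1] * xi - aa[nf - 1] * yi;
    y[i] = yi;
  }
  return y;
}

// Adaptive leaky integrate-and-fire neuron with a slow inactivation gate.
//
// Membrane:   C dV/dt = -gL (V - EL) + I(t) - w
// Adaptation: dw/dt = -w / tauw,  w += b at each spike
// Gate:       dh/dt = (hinf(V) - h) / tauh,  h *= (1 - hdec) at each spike,
//             hinf(V) = 1 / (1 + exp((V - vh) / kh))
// A spike is emitted when V >= Vth while h >= hblock (gate open); the
// recorded waveform is a brief plateau at Vspike followed by a reset to
// Vreset and an absolute refractory clamp. When h < hblock no spikes are
// emitted and V is capped at Vcap: a depolarized spikeless plateau.
//
// Units: mV, pA, nS, pF, ms. Current step: I = I_pA on [onset, onset+dur).
// The trace is recorded every `record_every` integration steps.
// [[Rcpp::export(".alif_integrate")]]
List alif_integrate(double I_pA, double onset_ms, double dur_ms,
                    double total_ms, double dt_ms, int record_every,
                    double C, double gL, double EL, double Vth, double Vreset,
                    double Vspike, double spike_ms, double refrac_ms,
                    double b, double tauw,
                    bool block_on, double hdec, double tauh, double vh,
                    double kh, double hblock, double Vcap) {
  if (dt_ms <= 0 || dt_ms > 0.05)
    stop("dt_ms must be in (0, 0.05] for a stable explicit integration");
  int nsteps = (int)std::round(total_ms / dt_ms);
  int nrec = nsteps / record_every;
  NumericVector V_out(nrec);
  std::vector<double> spikes;

  double V = EL, w = 0.0, h = 1.0;
  int spike_hold = 0, refrac_hold = 0;
  int spike_len = std::max(1, (int)std::round(spike_ms / dt_ms));
  int refrac_len = (int)std::round(refrac_ms / dt_ms);
  int irec = 0;

  for (int i = 0; i < nsteps; ++i) {
    double t = i * dt_ms;
    double I = (t >= onset_ms && t < onset_ms + dur_ms) ? I_pA : 0.0;

    if (spike_hold > 0) {
      V = Vspike;
      if (--spike_hold == 0) { V = Vreset; refrac_hold = refrac_len; }
    } else if (refrac_hold > 0) {
      V = Vreset;
      --refrac_hold;
    } else {
      double dV = (-gL * (V - EL) + I - w) / C;
      V += dt_ms * dV;
      bool gate_open = !block_on || h >= hblock;
      // 1e-9 mV tolerance: the asymptotic approach to threshold at exactly
      // rheobase stalls just below Vth in double precision
      if (V >= Vth - 1e-9 && gate_open) {
        spikes.push_back((t + dt_ms) / 1000.0);
        w += b;
        if (block_on) h *= (1.0 - hdec);
        spike_hold = spike_len;
        V = Vspike;
      } else if (block_on && !gate_open && V > Vcap) {
        V = Vcap;
      }
    }

    w += dt_ms * (-w / tauw);
    if (block_on) {
      double hinf = 1.0 / (1.0 + std::exp((V - vh) / kh));
      h += dt_ms * (hinf - h) / tauh;
    }

    if ((i + 1) % record_every == 0) V_out[irec++] = V;
  }

  return List::create(_["V_mV"] = V_out,
                      _["spike_times_s"] = NumericVector(spikes.begin(), spikes.end()),
                      _["h_final"] = h);
}
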