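#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Leaky integrate-and-fire network integrator.
//
// Membrane:  dV/dt = (mu - V)/tau + I_syn, exponential-Euler update with
// I_syn held constant over the step. Threshold crossing at the end of a
// step emits a spike at that step's time, resets V and holds the neuron
// for the absolute refractory period.
//
// Synapses: each presynaptic spike contributes J * F(t - t0) with
// F(t) = (exp(-t/tau2) - exp(-t/tau1)) / (tau2 - tau1). Realized exactly
// as the difference of two exponentially decaying accumulators per
// (postsynaptic neuron x presynaptic class); a spike increments both
// accumulators of its targets by J, and
// I = (a2 - a1)/(tau2 - tau1) summed over the two presynaptic classes.
//
// Connectivity arrives in compressed-sparse-column form (columns =
// presynaptic neuron), so spike propagation walks one column slice.
// All randomness (biases, initial voltages) is drawn in R; the kernel is
// deterministic given its inputs.
//
// [[Rcpp::export]]
List simulate_lif_cpp(IntegerVector wp, IntegerVector wi, NumericVector wx,
                      IntegerVector isExc, NumericVector tauM,
                      NumericVector bias, NumericVector v0,
                      double vTh, double vRe, double refractoryMs,
                      double tauRise, double tauDecayE, double tauDecayI,
                      double dtMs, double durationS) {
  const int n = isExc.size();
  const long nSteps = (long)std::llround(durationS * 1000.0 / dtMs);

  std::vector<double> V(v0.begin(), v0.end());
  // accumulators: E-class (decay tau2E / rise tau1), I-class likewise
  std::vector<double> aE1(n, 0.0), aE2(n, 0.0), aI1(n, 0.0), aI2(n, 0.0);
  std::vector<double> refractUntil(n, -1.0);

  const double dE1 = std::exp(-dtMs / tauRise);
  const double dE2 = std::exp(-dtMs / tauDecayE);
  const double dI1 = std::exp(-dtMs / tauRise);
  const double dI2 = std::exp(-dtMs / tauDecayI);
  const double invDenE = 1.0 / (tauDecayE - tauRise);
  const double invDenI = 1.0 / (tauDecayI - tauRise);

  // per-neuron membrane decay over one step
  std::vector<double> decayV(n), oneMinusDecay(n), tauOf(n);
  for (int i = 0; i < n; ++i) {
    tauOf[i] = tauM[i];
    decayV[i] = std::exp(-dtMs / tauOf[i]);
    oneMinusDecay[i] = 1.0 - decayV[i];
  }

  std::vector<int> spikeNeuron;
  std::vector<double> spikeTime;
  spikeNeuron.reserve(1024);
  spikeTime.reserve(1024);
  std::vector<int> firedThisStep;
  firedThisStep.reserve(64);

  for (long step = 0; step < nSteps; ++step) {
    const double tMs = (step + 1) * dtMs;  // time at end of step
    firedThisStep.clear();
    for (int i = 0; i < n; ++i) {
      // decay synaptic accumulators
      aE1[i] *= dE1; aE2[i] *= dE2; aI1[i] *= dI1; aI2[i] *= dI2;
      if (tMs <= refractUntil[i]) continue;  // held at reset
      const double I = (aE2[i] - aE1[i]) * invDenE + (aI2[i] - aI1[i]) * invDenI;
      // exponential Euler: V <- mu_eff + (V - mu_eff) e^{-dt/tau}
      const double muEff = bias[i] + tauOf[i] * I;
      V[i] = muEff + (V[i] - muEff) * decayV[i];
      if (!std::isfinite(V[i]))
        stop("non-finite membrane potential for neuron %d at t = %f ms",
             i + 1, tMs);
      if (V[i] >= vTh) {
        V[i] = vRe;
        refractUntil[i] = tMs + refractoryMs;
        spikeNeuron.push_back(i + 1);
        // timestamp at the start of the step in which threshold was
        // crossed, keeping all times inside [0, duration)
        spikeTime.push_back(step * dtMs / 1000.0);
        firedThisStep.push_back(i);
      }
    }
    // propagate this step's spikes into target accumulators (contributes
    // zero current at the spike instant since both accumulators cancel)
    for (int k = 0; k < (int)firedThisStep.size(); ++k) {
      const int j = firedThisStep[k];
      const bool exc = isExc[j] != 0;
      for (int idx = wp[j]; idx < wp[j + 1]; ++idx) {
        const int post = wi[idx];
        const double w = wx[idx];
        if (exc) { aE1[post] += w; aE2[post] += w; }
        else     { aI1[post] += w; aI2[post] += w; }
      }
    }
    if (step % 200000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["neuron"] = wrap(spikeNeuron),
                      _["time"] = wrap(spikeTime));
}
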