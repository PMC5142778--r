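---
title: "Shared variability in spiking networks: models, metrics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared variability in spiking networks: models, metrics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the spiking
network model and its integrator, the factor-analysis machinery and its
derived metrics, the subsampling protocols, and — importantly — the
numerical and design choices that the underlying methods leave open,
with the rationale for each.

## 1. The spiking network

The simulator implements a recurrent network of leaky integrate-and-fire
neurons in the balanced regime: strong recurrent excitation dynamically
cancelled by strong inhibition, producing irregular spontaneous firing
with no external stimulus. Each neuron obeys

$$\dot V = \frac{\mu - V}{\tau} + I_{\mathrm{syn}},$$

with voltages normalized so that reset is 0 and threshold is 1 (roughly
-65 mV and -50 mV). Membrane time constants are 15 ms (excitatory) and
10 ms (inhibitory); the constant bias $\mu$ is drawn once per simulation,
uniformly in [1.1, 1.2] for E cells and [1.0, 1.05] for I cells, giving
each neuron a slightly suprathreshold drive and heterogeneous intrinsic
rates. A spike triggers reset and a 5 ms absolute refractory period.

Synaptic input is a weighted sum of presynaptic spike trains convolved
with the difference-of-exponentials kernel

$$F(t) = \frac{e^{-t/\tau_2} - e^{-t/\tau_1}}{\tau_2 - \tau_1},$$

with rise constant $\tau_1 = 1$ ms and decay $\tau_2 = 3$ ms (excitatory)
or 2 ms (inhibitory). $F$ integrates to one, so each weight $J$ carries
the full charge of a single spike; the weight matrices of the canonical
configuration are $J^{EE}=0.024$, $J^{EI}=-0.045$, $J^{IE}=0.014$,
$J^{II}=-0.057$ with connection probabilities $p^{EE}=0.2$ and 0.5 for
all pairs involving inhibition. The clustered variant partitions the 4000
excitatory neurons into 50 clusters of 80 and replaces the homogeneous
E–E rule with $p^{EE}_{in}=0.4854$, $J^{EE}_{in}=0.0456$ within clusters
and $p^{EE}_{out}=0.1942$, $J^{EE}_{out}=0.024$ between; the pair-count-
weighted mean of the two probabilities recovers 0.2, which the
configuration validity check enforces. Clustering produces slow,
coordinated switching of cluster activation — the source of genuinely
shared, low-dimensional count variability.

### Integration scheme and other choices the model leaves open

* **Integrator and step.** Exponential-Euler for the membrane leak
  (exact for the linear part, synaptic current held constant over the
  step) at `dt = 0.05` ms, configurable. The synaptic kernel is realized
  exactly as the difference of two exponentially decaying accumulators
  per (neuron × presynaptic class); a presynaptic spike increments both
  accumulators of its targets by $J$, so no convolution history is
  stored and the impulse response is exact at machine precision.
* **Threshold tie.** $V \ge 1$ at the end of a step emits a spike
  assigned to that step; refractoriness is a hold-until timestamp.
  With `dt = 0.05` ms the simulated interspike interval of an uncoupled
  neuron matches the closed form
  $\tau \ln\frac{\mu - V_{re}}{\mu - V_{th}} + t_{ref}$ within one step
  (asserted in the tests).
* **Initial conditions and burn-in.** Initial voltages are uniform on
  [reset, threshold) from the dynamics seed; synaptic states start at
  zero; the first 2 s of every run are discarded before binning
  (configurable) to remove the initial-condition transient.
* **Self-connections** are excluded (zero diagonal), the usual
  convention.
* **Trials.** One "trial" is one 1-s bin of a single continuous run — no
  state reset between trials. Disjoint trial sets used in the repeat
  protocols are therefore contiguous, non-overlapping segments of
  simulated time.
* **Determinism.** All randomness is drawn in R from two explicit seeds
  (connectivity and dynamics); the compiled integrator is deterministic
  given its inputs, so identical (config, seeds) reproduce the spike
  record bit for bit.
* **Convergence caveat.** The coupled network is chaotic: halving `dt`
  changes individual spike trains. Convergence is therefore asserted per
  neuron on uncoupled populations (deterministic trajectories) and at
  the population-mean-rate level (< 1% under `dt` halving) for recurrent
  networks.

### Desk-scale variants

`toyNetworkConfig(scale)` shrinks the canonical network while preserving
its connectivity structure: cluster size
`min(80, round(400 * scale))`, excitatory count rounded to a multiple of
it (`scale = 0.1` gives 400 E in 10 clusters of 40 plus 100 I), the
within/between probability *ratio* 0.4854/0.1942 kept exactly, and the
pair-weighted mean probability kept at 0.2. Synaptic weights are
multiplied by $1/\sqrt{\mathrm{scale}}$, the standard balanced-network
convention ($J \propto 1/\sqrt{N}$): it preserves the input *variance*
$J^2 K$ per neuron, and without it the reduced network fires almost
clock-like (Fano factors near 0.05). Two finite-size effects remain and
are intrinsic, not tunable away: firing rates run higher than cortical
spontaneous rates, and pairwise correlations — which scale as $1/N$ in
balanced networks — are roughly ten times larger than at full scale. The
second effect matters for null results: the *non-clustered* desk-scale
network carries a weak but statistically detectable shared mode
(a few percent shared variance at 40 neurons × 300 trials), whereas the
full-scale network's corresponding result is indistinguishable from
zero at comparable neuron/trial counts. Desk-scale runs therefore
demonstrate the clustered vs non-clustered *dissociation in degree*, not
a literal zero.

## 2. Factor analysis

Spike counts are modeled as $x \sim N(\mu, LL^T + \Psi)$ with diagonal
$\Psi$: `LL'` is covariance shared across neurons, $\Psi$ the
independent remainder. The EM fit runs on the sample covariance (the
Gaussian sufficient statistic), so each iteration costs $O(p^2 m)$
regardless of trial count; likelihoods use the Woodbury identity and the
matrix determinant lemma, factorizing only $m \times m$ systems. Counts
enter raw — no square-root transform or z-scoring — since the model is
stated directly on counts.

Choices the method leaves open, and what this package does:

* **Initialization** (deterministic, no jitter): $L$ starts at the top-m
  principal directions of the sample covariance scaled by the square
  root of each eigenvalue's excess over the mean initial $\Psi$; $\Psi$
  starts at the sample variances. Fits are reproducible from the data
  alone.
* **Convergence**: stop when the relative log-likelihood change falls
  below `1e-8` (unit tests) or after 3000 iterations, whichever first;
  non-convergence is recorded in the model metadata. The experiment
  wrappers use a looser `1e-6` / 500 iterations, which changes the
  metrics by far less than subsampling variability.
* **Heywood cases**: $\Psi$ is floored at $10^{-6}$ times each neuron's
  sample variance, keeping the model covariance positive definite.
* **Cross-validation**: 4 folds, trial-level random splits from an
  explicit seed; the selected $m^\*$ maximizes the mean held-out
  log-likelihood with ties broken toward the smallest $m$. The default
  search is coarse-to-fine (unit steps to 10, then steps of 2, then unit
  refinement around the coarse argmax) to bound the number of fits at
  large $m$.
* **The 95% rule**: `d_shared` is the smallest number of leading
  eigenmodes of `LL'` reaching 95% of its trace, computed on the model
  refit on all trials at $m^\*$ (the CV fold models are discarded). The
  rationale: with abundant training data the held-out likelihood curve
  is flat over a range of $m$, so $m^\*$ itself is noisy, while the 95%
  eigenvalue cut is stable across runs.
* **Degenerate neurons**: `fitFA` refuses zero-variance neurons
  (instructing the caller to drop or jitter); the experiment wrappers
  screen pools with `activeNeurons()` (mean rate ≥ 1 spike/s and
  positive variance — the same kind of screening applied to recorded
  units) and drop any column that becomes constant within a trial
  subset.

Derived metrics (all validated against algebraic identities in the test
suite): percent shared variance per neuron
$100\,L_k L_k^T / (L_k L_k^T + \Psi_k)$ with the population value an
unweighted mean; per-mode fractions $100\,\lambda_i / \sum_j \lambda_j$;
and the per-mode split of percent shared variance
$100\,\lambda_i u_{ik}^2 / (L_k L_k^T + \Psi_k)$ averaged over $k$,
whose sum over modes equals the population percent shared variance
exactly ($\sum_i \lambda_i u_{ik}^2 = (LL^T)_{kk}$).

## 3. Comparing mode subspaces across neuron counts

Modes estimated from different neuron counts live in different spaces.
The package compares them by keeping only the loading-matrix rows of a
common neuron core (default 20 neurons contained in every subset),
eigendecomposing the restricted shared covariance, and measuring
principal angles between the spans of the top five modes (singular
values of $Q_A^T Q_B$ after orthonormalization, clipped to [0, 1],
ascending). Two open points and the choices made:

* Restricted eigenvector sets are orthogonal by construction, but both
  bases are orthonormalized (QR) before the angle computation anyway —
  angles are invariant to that, and it makes the routine safe for
  arbitrary input bases.
* The chance reference is the rotation-invariant ensemble: two
  independent k-dimensional subspaces from orthonormalized Gaussian
  matrices, summarized as mean ± sd per ordered angle. For k = 1 in the
  plane the angle is uniform on [0°, 90°] (mean 45°), which the tests
  use as an analytic anchor.
* Eigenvector signs follow the largest-magnitude-entry-positive
  convention so serialized modes are reproducible; angles are
  sign-invariant regardless.

## 4. Subsampling protocols

Neuron sweeps draw *nested* subsets (each larger sample augments the
previous one) so curves reflect added information, not resampling noise;
repeat structure follows the model-network protocol of 5 disjoint neuron
sets × 5 disjoint contiguous trial blocks (25 repeats) with mean ± SE
across repeats, or single samples for array-style data. Neuron pools are
excitatory-only in the network experiments, since inhibitory neurons
carry no cluster structure. Cluster-balanced sampling draws N clusters
and 50/N neurons from each (N dividing 50), isolating the effect of
cluster representation at fixed sample size. The exchangeable-trials
assumption behind factor analysis is checked two ways: per-neuron count
autocorrelation across trials (near zero beyond lag 0 at 1-s bins) and
re-running the metrics on adjacent / skip-1 / skip-2 / random trial
samplings of equal size.

## 5. Synthetic-data generators

`sampleFACounts()` inverts the factor model ($z \sim N(0, I)$,
$x = \mu + Lz + \varepsilon$), optionally Poissonizing each draw (rate
truncated at zero) as a coarse emulation of spiking discreteness — the
generator reproduces first and second moments, not the full count
distribution. `makeInvivoLikeParams()` builds a parameter set with the
structure reported for spontaneous V1 population activity at 1-s bins:
a dominant same-sign first mode (entries $|N(1, 0.25)|$, normalized)
carrying 65% of the shared variance by default, four weaker mixed-sign
modes with geometrically decaying eigenvalues, log-normal mean counts,
and $\Psi_k$ set per neuron so that every neuron's percent shared
variance — hence the population mean — equals the requested 51.8%
exactly. What passing tests on these generators do *not* show: anything
about higher moments, temporal structure, or non-Gaussian features of
real recordings.

## 6. Problem sizes, runtime, and limitations

The shipped experiments run at desk scale by choice: 400 E + 100 I
neurons, ~300 one-second trials, factor analyses at 10–80 neurons, which
keeps the full test suite in the low minutes on one CPU. The canonical
full-scale configurations (4000 + 1000 neurons, $10^4$ trials, analyses
at 500 neurons) are shipped as presets and run with the same code, at
CPU-hours cost. Known limitations: current-based synapses without
plasticity, spatial structure, or external stimuli; finite-size effects
at desk scale (elevated rates and correlations, discussed above);
Gaussian likelihoods on integer counts; and exchangeability of 1-s
trials, which is checked, not assumed, by the autocorrelation and
trial-spacing diagnostics.
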