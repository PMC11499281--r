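---
title: "Models and methods: line-attractor dynamics, perturbation analysis and the mechanistic network"
author: "lineattractor package"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lineattractor)
```

This vignette is the package's own account of the models it implements,
the choices made where the design was genuinely open, and what the
synthetic-data tests do and do not demonstrate about real recordings.

## The recurrent switching linear dynamical system

Population calcium activity `y_t` (neurons x frames, 10 Hz) is modelled as
a noisy linear readout of a low-dimensional latent state `x_t` whose linear
dynamics switch between `K` discrete regimes `z_t`:

* transitions: `p(z_{t+1} | z_t = k, x_t) = softmax(R_k x_t + r_k)` — the
  next regime depends on where the latent state is (the "recurrent" part);
* dynamics: `x_t = A_{z_t} x_{t-1} + b_{z_t} + B_{z_t} u_t + eps_t`,
  `eps_t ~ N(0, Q_{z_t})`, with `u_t` an optional binary intruder-presence
  input;
* emission: `y_t = C x_t + d + delta_t`, `delta_t ~ N(0, diag(S))`.

An approximate line attractor appears in this family as one latent
dimension whose per-frame eigenvalue is close to 1: activity along it
relaxes very slowly (the *integration dimension*, `x1`), while the
orthogonal dimension (`x2`) relaxes within a second or so.

One convention worth stating: the first latent state carries a free prior
`N(x0, P0)` and the dynamics terms run from the second frame.  This makes
the one-state M-step exact, so for `K = 1` the EM objective is the exact
marginal log-likelihood and is provably non-decreasing; the test suite
asserts this.  For `K > 1` the recorded objective is the joint
log-likelihood at the most-probable discrete path, a surrogate that can
fluctuate in early iterations while the partition settles.

### Fitting

`fitRSLDS()` uses a structured variational EM:

1. Continuous latents: an exact Kalman smoother (C++, information-form
   update exploiting the diagonal observation covariance) run under the
   current most-probable discrete path, returning smoothed means, marginal
   covariances and lag-one cross-covariances.
2. Discrete states: forward-backward over the softmax chain given the
   smoothed latent means, yielding marginal and pairwise state weights and
   a Viterbi path.
3. M-steps: closed-form weighted regressions for `{A_k, b_k, B_k, Q_k}`
   and `{C, d, S}` using the full smoothed second moments; the softmax
   parameters `{R_k, r_k}` by ridge-penalized multinomial logistic
   regression (the ridge, `1e-3`, prevents separation blow-ups on nearly
   deterministic partitions).

Initialization follows the standard recipe: factor analysis for `C`, `d`
and the latents (PCA fallback if the FA optimizer fails), k-means on the
latents for the discrete states, ridge least squares for the per-state
dynamics.  One detail matters a great deal in practice: the softmax
transition parameters are themselves initialized by fitting the k-means
state path.  If the first forward-backward pass instead runs with flat
transitions, states are partitioned by dynamics residuals rather than by
latent position, and the fitted slowest-state eigenvalue drifts toward 1 —
in our recovery experiments a planted 5 s time constant came back as
13–106 s.  With position-gated initialization the same experiments recover
it within a few percent (median over seeds).

### Validation quantities

* `crossValidatedR2()`: five-fold cross-validation over *contiguous* time
  blocks (avoiding temporal leakage); the held-out block is reconstructed
  as `C x + d` from latents inferred under the training-fold parameters,
  and variance explained is computed against training-fold neuron means.
  Models are expected to reach at least 70% before downstream use.
* `forwardSimAccuracy()`: variance explained by a noise-free rollout of
  the mean dynamics from the inferred initial state.  The quantity is
  referred to in the literature without a formula; this n-step-ahead
  interpretation is our documented choice.
* `stateCountSweep()` selects `K` by the cvR2 criterion.

### Attractor metrics

* `timeConstants()`: `tau = |1 / log|lambda||` per eigenvalue of the
  dynamics matrix, natural log, giving tau in frames; divided by the frame
  rate for seconds.  `|lambda| = 1` is flagged infinite, `|lambda| = 0`
  zero, `|lambda| > 1` unstable.  When `K > 1` every state is reported and
  the state with the largest leading tau is marked as the
  attractor-expressing state; whether published per-session values use the
  slowest or the most-occupied state is not documented anywhere we know
  of, so both are accessible.
* `lineAttractorScore()`: `log2(t_n / t_{n-1})` of the two largest taus —
  scale-free, so the frames/seconds convention does not affect it.
* `autocorrelation()` uses the biased (1/T) autocovariance estimator;
  `autocorrHalfWidth()` reports the first 0.5-crossing of `r_k` with
  linear interpolation between integer lags, censored at the maximum lag.
  The threshold and interpolation are our choices; "half width" is not
  defined more precisely in the source material.
* `flowField()` evaluates the one-frame mean displacement on a grid, with
  the discrete state at each grid point taken as the argmax of the softmax
  logits averaged over previous states.  The scalar speed over the grid is
  a deliberately simplified velocity landscape.
* `rampDecayMetrics()`: ramp rate is the least-squares slope in a 10 s
  window after bout onset; decay tau is an exponential fit
  (`minpack.lm::nlsLM`) from bout offset to the next onset.  The decay can
  alternatively be taken from the fitted dynamics eigenvalue.

## Synthetic sessions

`generateLineAttractorSession()` plants the structure the analysis is
meant to detect: a diagonal two-dimensional dynamics matrix with
eigenvalues `exp(-1/(tau * rate))` for a slow (default 100 s) and a fast
(default 1 s) dimension; a binary intruder input entering chiefly the slow
dimension, scaled so the slow latent approaches ~3 stationary SDs under
sustained input; an emission matrix with disjoint dominant-weight groups
(half the cells on each dimension); emission noise with SD equal to a
fraction (default 0.2) of each neuron's signal SD.  Behaviour bouts are
derived from the input schedule (bout = contiguous input-on period,
labelled "attack") plus distractor bouts in the off periods; positions are
uniform over a 500 um field of view by default (no spatial clustering, as
observed in the real tissue), with an optional clustered mode for decoder
positive controls.  All randomness descends from one session seed split
into named substreams, which is what makes the stimulation replay exact.

What this generator does *not* emulate: calcium indicator nonlinearity and
photophysics, non-Gaussian noise, slow drifts, cell-extraction artefacts,
or any behaviour not reducible to the binary input.  Passing tests
therefore demonstrate internal correctness of the estimators under the
model's own assumptions, not performance on real data.

Defaults worth knowing (all overridable): 100 neurons, 3000 frames at
10 Hz, three intruder epochs.  Two analyses use different conditions, both
deliberate: parameter-recovery tests plant 5 s / 0.5 s taus because
recovering a 100 s tau from a 300 s recording is statistically impossible
at the stated tolerance (the AR-coefficient standard error alone spans
several-fold in tau); decoder tests use a 10 s integrator with five
epochs, since with a 100 s tau the slow latent barely decays between
epochs and per-frame decoding carries no information.

## Perturbation analysis

`simulateTargetedStim()` replays the session's generative model with an
added latent drive during pulses, directed along the normalized sum of the
targeted neurons' emission rows (`C^T` weighting) — stimulating
x1-dominant cells pushes the slow latent, x2-dominant cells the fast one.
Because the noise is replayed, a zero-gain protocol returns the original
session bit-for-bit, and differences between perturbed and unperturbed
runs isolate the stimulation effect exactly.

Quantification mirrors the optogenetics analyses: projection onto a latent
dimension (posterior inference, or a pseudo-inverse readout for speed —
which was used originally is not documented, so both are provided);
per-ISI means and peaks with an integration flag (strictly increasing ISI
means over the first three pulses, with a 5% relative-increment guard) and
a saturation flag (increment below 10% of the previous level); Euclidean
state-space displacement from the pre-stimulation point to each pulse's
stim-end and ISI-end points.  ISI analysis windows skip the first second
after pulse offset to avoid transient contamination — a window choice of
ours.

`influenceScores()` computes, for unitary (single-target) runs, each
follower's mean z-scored activity in the post-pulse ISI windows, z-scored
against the pre-stimulation baseline per neuron.  Self pairs and cells
within the 50 um exclusion radius are masked (off-target conservatism);
the 15 um off-target radius is carried for reporting.
`connectivityFraction()` thresholds at the highest x1-to-x2 score and
returns the fraction of x1-to-x1 scores strictly above it;
`stabilityConnectivityCorrelation()` regresses a per-session connectivity
metric (mean evoked z or trapezoidal AUC) on the per-session integration
time constant.

## The mechanistic spiking network

`buildWeightMatrix()` realizes the two-block random connectivity: an
integration subnetwork of `Np = 200` of `N = 1000` neurons with density
`sigma` and weights `U(0, 1/sqrt(Np))`, background density 1% with weights
`U(0, 1/sqrt(N))`, zero diagonal.  The background density is not specified
by the source material; 1% keeps its spectral contribution near 0.16 so
subnetwork dynamics dominate and `tau_n` approaches `tau_s` as
`sigma -> 0`.  The spectral radius is computed by power iteration (the
matrix is nonnegative, so the dominant eigenvalue is the real Perron
root; tolerance 1e-8, dense fallback), on the full matrix by default with
a subnetwork-only mode available.

`analyticNetworkTau()` is `tau_n = tau_s / |1 - lambda_max|`, flagged
unstable at `lambda_max >= 1`.  `phaseDiagram()` averages `tau_n` over
weight-matrix seeds on a density x `tau_s` grid, masking unstable cells.
A property test checks the formula against the slowest decay mode of the
linearized rate dynamics `tau_s dp/dt = -p + W p` (agreement within 10%).

`simulateLIF()` / `simulateLIFInhibition()` integrate the membrane and
synaptic-current equations by Euler steps of 1 ms (C++), with membrane
time constant 20 ms, threshold 0.1, reset to zero with a one-timestep unit
rate impulse, and per-step Gaussian noise `N(0,1)/5` entering the membrane
equation like an input current (entering it as a raw per-step state
increment would swamp the threshold and produce tens of hertz of baseline
firing).  The inhibition variant adds a single graded unit with a 50 ms
time constant, driven by the population-mean rate and subtracted from
every membrane with gain `g_inh`.

`makePulseInput()` builds the four-pulse, 20 s-ISI smoothened step input
driving a random 25% of neurons.  The input amplitude is not specified in
the source material; the default (2, driving targeted cells to
near-saturation rates during pulses) is the regime in which a 20 s
synaptic filter accumulates enough drive across pulses for the dense
(36%) subnetwork to express stepwise persistent activity under feedback
inhibition, while a 100 ms filter decays back to baseline between pulses.
`rateToCalcium()` convolves binned rates with a causal exponential kernel
(default 1.5 s, GCaMP7s-like, unit peak so a lone spike produces a
unit-height transient and a constant rate `rho` plateaus at
`rho * kernel_tau`).

## Decoders

* `framewiseAttackDecoder()`: bouts separated by under 5 s are merged into
  trials; frames are balanced across classes by seeded undersampling of
  the majority class (the balancing method is unspecified in the source
  material); the classifier is an exhaustive 1-D threshold search
  maximizing balanced accuracy — for one dimension this is the linear SVM,
  but fully deterministic.  Accuracy is the leave-one-trial-out average of
  held-out frame accuracy (the per-frame vs per-trial ambiguity resolved
  as per-trial-averaged frame accuracy).  `shuffleNull()` permutes labels
  across bouts and refits per shuffle; `crossConditionDecode()` applies a
  frozen threshold to a second condition.
* `spatialClusterDecoder()`: a linear SVM (`e1071`) on cell (x, y)
  positions, scored by 5-fold cross-validation against a label-shuffled
  null (20 shuffles).
* `motionGLM()`: ridge regression of each neuron on motion features at
  lags 0..10 s, contiguous 10-fold cross-validation, ridge strength by
  inner cross-validation (`glmnet`) unless fixed.  The motion features are
  synthetic stand-ins (unit-variance low-pass noise) for video-SVD
  components; the extraction itself is out of scope.

## Numerical choices and degenerate inputs

Innovation and observation variances are floored at `1e-8` in the M-steps;
dynamics and emission Gram matrices carry a tiny proportional ridge.
Zero-variance activity, single-class bout tables, zero-variance series for
the autocorrelation, zero emission columns for the subspace angle, and
empty pair classes for the connectivity fraction are all rejected with
errors rather than propagated.  Tie-breaks are deterministic everywhere
(top-neuron selection prefers the lower index; the threshold decoder's
search is exhaustive and order-based, hence invariant to monotone signal
transforms).

## Problem sizes

The test-suite and acceptance computations use 40–60 neurons, 1200–6000
frames, 10 recovery seeds, 20 weight-matrix seeds per density, and three
~105 s spiking simulations — sizes at which every estimator is
well-conditioned and the full suite runs in minutes on one CPU.

## Known limitations

The discrete-state machinery uses hard paths for smoothing and latent
means for the discrete likelihood (no Polya-gamma augmentation or full
posterior over parameters); for `K > 1` the objective is a surrogate and
per-state dynamics near `lambda = 1` remain only weakly identified when
states are not position-separated.  The spiking model is current-based,
single-compartment, purely excitatory plus one global inhibitory unit, and
makes no attempt at biological rate regimes beyond the qualitative
integration/non-integration contrast.
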