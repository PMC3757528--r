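---
title: "Synthesizing spike-pattern detectors with synaptic kernels: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing spike-pattern detectors with synaptic kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(skimnet)
```

# The model

`skimnet` synthesizes two-layer spiking networks that recognize fixed
spatio-temporal spike patterns.  The network has no hidden neurons: the
hidden layer is made of synapses.  Writing $x_{i,t} \in \{0,1\}$ for the
spike train on input channel $i$ at integer timestep $t$:

1. **Random projection.** Each of $M$ dendritic branches receives one
   synapse from each of the $L$ input neurons, with a fixed random weight
   $w^{(1)}_{ji} \sim U(-0.5, 0.5)$.  The weighted instantaneous sum is
   $u_{j,t} = \sum_i w^{(1)}_{ji} x_{i,t}$.
2. **Synaptic kernel filtering.** Each spike arriving at a dendrite
   launches a scaled copy of that dendrite's kernel impulse response;
   copies superpose additively, giving the linear dendritic potential
   $v_j = h_j * u_j$.  The kernels both *persist* the spikes in time
   (memory of recent input) and, through their randomized time constants
   or delays, make the $M$ dendrites a diverse basis of temporal
   features.
3. **Compression.** The dendritic activation is
   $a_{j,t} = \frac{1}{1+e^{-k\,v_{j,t}}} - \tfrac12$ (or a scaled tanh).
   Compressing the *superposition* makes the synapse depressively
   adaptive: a spike riding on the tail of an earlier one contributes
   less.  This is the nonlinearity that makes the random projection more
   than a linear filter bank.
4. **Linear soma and one-step solution.** The soma potential is
   $y = W A$ with $A$ the $M \times K$ activation matrix.  Training is a
   single regularized least-squares solve $W = Z A^+$ against an analog
   target $Z$; there is no iteration and no learning rate.
5. **Thresholding.** The axon hillock emits a spike at each rising-edge
   crossing of $y$ above $\theta$.

## Assumptions

* Time is a discrete grid; `dt` (ms per step, default 1) is metadata
  only.  Inputs are binary events — at most one spike per channel per
  step.
* The output weights are the only solved parameters; input weights and
  kernels stay fixed after synthesis ("the network is synthesized, not
  trained").
* The target is built from *known* pattern end times (supervised
  synthesis).

# Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `M` | 100 | dendrites (features).  More dendrites lower the training residual monotonically; 100 suffices for the bundled 5-channel task. |
| `family` | `"alpha"` | kernel family.  Alpha, $(t/\tau_s)e^{-t/\tau_s}$, is the standard postsynaptic-current model; its half-height width is 244.6% of $\tau_s$, so pass windows widen linearly with the time constant, which is what gives tolerance to linear time warping. |
| `t_max` | 200 | longest interval (timesteps) over which spikes must be remembered — the nominal pattern duration.  Alpha/leaky/resonant time constants are drawn $\tau_s \sim U(1, t_{max}/2)$; `ts_mode = "heuristic"` pins $\tau_s = t_{max}/2$ instead.  The lower bound 1 avoids degenerate sub-step kernels. |
| `k` | 5 | compression gain.  At the default weight scale this puts typical dendritic potentials in the gently saturating part of the logistic. |
| `ridge` | 1e-8 | least-squares regularizer.  Sparse spike trains can make $A$ rank-deficient; a tiny ridge stabilizes the solve while changing well-conditioned solutions by a negligible amount.  `ridge = 0` selects an SVD pseudoinverse with a relative singular-value cutoff (`sv_tol`). |
| `width`, `delay` | 10, 10 | target pulse shape: each desired output spike is widened to a 10-step square pulse displaced 10 steps past the end of the input pattern, giving the target enough energy to anchor the regression and leaving time for the kernel responses to peak.  Raising the width or amplitude further strengthens sparse targets. |
| `threshold_fraction` | 0.25 | firing threshold as a fraction of the target amplitude.  The least-squares fit trades pulse height for width, so fitted peaks sit well below the nominal amplitude; 25% is the recommended operating point and measurably better than 50%. |
| `order` | `filter_then_nonlinearity` | see "Order of filter and nonlinearity" below. |
| `polarity` | `"mixed"` | `per_dendrite` constrains every synapse on a dendrite to one sign, for biologically realistic excitatory/inhibitory splits, at some cost in versatility. |

# The synthetic benchmark generator

`make_pattern()` / `embed_pattern()` generate the study conditions used
throughout the tests: a 9-spike pattern over 5 channels in a 200-step
window, embedded as a Poisson process (~580 presentations per $10^5$
steps, overlaps allowed and frequent at that rate) among uniform Poisson
noise spikes whose expected count equals the expected number of pattern
spikes.  Collisions are resolved by OR — the raster stays binary.
Presentations are exact copies by default; uniform time warping
(e.g. factors in [0.76, 1.24]) and Gaussian spike jitter are opt-in,
applied per presentation.

A presentation's recorded *end time* is one step past its last input
spike — the end of the input sequence — because the training target is
placed relative to when the input information ends.  Anchoring the
target at the nominal 200-step window end instead would put it tens of
steps past the last spike for a typical random pattern, where only the
slowest kernels retain signal; detection degrades badly.

What the generator does **not** emulate: structured inter-spike
correlations of real neural data, per-channel firing-rate constraints
(an optional `max_per_channel` cap exists), bursting, or the
cochlear-style sparse encodings of spoken-digit corpora.  Passing tests
on this generator therefore demonstrate the synthesis machinery, not
performance on any external recording.

# Numerical choices

* **Truncation.** Kernels are truncated to finite support for
  convolution: $18\tau_s$ for alpha/leaky/resonant, $\Delta T + 18\tau_s$
  for delayed alpha, $\Delta T + 11\sigma$ for the delayed Gaussian.
  These lengths keep the dropped tail below $10^{-6}$ of the peak in
  magnitude and below $10^{-4}$ of the response in L1 mass (both
  property-tested).
* **Convolution.** Dendrite-batched FFT convolution with power-of-two
  padding (`mvfft`), verified against `stats::convolve` and against a
  literal per-spike superposition oracle.  Arbitrary-length FFTs on
  $10^5+$-step sequences are avoided because non-smooth lengths are
  orders of magnitude slower.
* **Least squares.** With `ridge > 0` the solve is a QR factorization of
  the ridge-augmented system; with `ridge = 0`, an SVD pseudoinverse with
  relative cutoff (minimum-norm for underdetermined systems, which also
  trigger a warning).  The recursive solver keeps a symmetrized inverse
  correlation matrix initialized at $(1/\text{ridge}) I$ and matches the
  batch solution to $10^{-6}$ relative Frobenius error.
* **FWHM and preferred delay.** Computed on the continuous kernel form:
  grid bracketing at $10^{-3}$ timestep, then golden-section/bisection
  refinement; kernels with a second local maximum above half height
  (e.g. long damped resonances) are rejected as multimodal.  For kernels
  that peak at $t = 0$ (leaky) the left half-height crossing clamps to 0.
* **Delayed Gaussian.** The bump is centred $5\sigma$ after the hard
  delay so the response is causal (exactly zero before $\Delta T$, below
  $4\times10^{-6}$ of the peak at the cut) yet keeps the standard
  $2\sigma\sqrt{2\ln 2}$ width at half maximum.  Centering the Gaussian
  *at* the cutoff would halve the bump and break that identity.
* **Degenerate inputs.** Empty rasters, empty end-time lists, and
  all-zero weight rows are either well-defined no-ops or explicit errors
  (e.g. `weight_concentration` on a zero row).
* **Saturation.** Logistic/tanh activations are strictly inside
  $(-0.5, 0.5)$ mathematically; in double precision they touch $\pm 0.5$
  once $|k\,v| \gtrsim 36$ (logistic) or $\gtrsim 19$ (tanh).  Tests
  acknowledge this.

# Design choices where the design was open

**Order of filter and nonlinearity.**  The default compresses the
superposed dendritic potential (step 3 above).  The alternate order —
compressing each spike's amplitude *before* filtering, so every event is
scaled independently of history — is implemented as
`order = "nonlinearity_then_filter"`.  The general argument for the
default is computational power: per-event scaling makes the features
linear in the event sequence and forfeits spike-history adaptation.  On
the bundled benchmark, however, detecting a *fixed* pattern in Poisson
noise is close to a matched-filtering problem, and the near-linear
alternate order can fit the analog target comparably or better; the
power argument is about the class of computable input–output maps, not a
per-task guarantee.  The order is therefore exposed as configuration,
with the superposition order as the method's canonical default.

**Merged output events and scoring.**  Closely overlapping recognitions
merge into one supra-threshold event.  `threshold_spikes()` emits one
discrete spike per rising edge (the canonical event-based output).  For
*scoring*, `skim_evaluate()` defaults to state semantics — a presentation
counts as detected if the soma is at or above threshold anywhere in its
scoring window — so a merged event credits both overlapping
presentations, matching how the soma trace is read; `semantics = "edge"`
gives the stricter one-event-per-onset rule.  Scoring windows are one
nominal pattern duration (200 steps) centred on the trained target
pulse, the continuous-sequence analogue of per-utterance scoring; the
complement is tiled into negative windows of the same length.

**Error-metric denominators.**  The detection error is
$\text{fn}/\#\text{positives} + \text{fp}/\#\text{negatives}$ by
default, using ground-truth counts — well-defined even when nothing is
detected, and on a 50/450 utterance split it reproduces the scale of the
historical spoken-digit scores.  The literal detected-count reading
(`interpretation = "detected"`, dividing by tp and tn) is available but
errors when a denominator is zero.

**Pruning sizes and importance.**  Two-pass pruning over-provisions by
10x and keeps the dendrites with the largest summed $|w^{(2)}|$ across
outputs (a scale-fair aggregate for multi-output models), then
*re-solves* — mandatory, since the survivors' old weights are no longer
optimal.  The 10x experiment in the acceptance suite uses 1000 synapses
pruned to 100, i.e. 200 dendrites to 20 at $L = 5$ — the recipe counts
synapses, and one dendrite carries $L$ of them.  The benefit of
selection is real when the final bank is small; note that least-squares
weight magnitude partly reflects feature scale rather than usefulness,
so over-provisioned selection into a generously sized bank can fail to
beat a fresh random bank of the same size.

**Soma reset.**  `skim_run(reset = TRUE)` zeroes all pending dendritic
contributions when an output fires (stepwise simulation).  It is off by
default; the solved trajectory does not depend on the pre-spike history
being reset, and experiments show no systematic benefit.

**Model files.**  Models serialize to a JSON container (full IEEE
precision, `format_version` attribute) holding the weight matrices, the
kernel parameter table and the scalar attributes; loading is bit-exact
and validates required datasets and version.

# Problem sizes used by the test and acceptance suites

Unit tests run on small instances (sequences of $10^3$–$3\times10^4$
steps, 5–60 dendrites) and finish in seconds.  The acceptance suite runs
the benchmark at its native scale: weight concentration and end-to-end
detection on $10^5$-step sequences with ~580 presentations (10 seeds
each, about two minutes apiece), solver-oracle equivalence on 100 random
systems up to $50\times500$, and the two-pass pruning comparison on
$5\times10^4$-step sequences (10 seeds).  `scripts/acceptance.R`
recomputes the kernel widths and the concentration shares from scratch
under a caller-supplied seed.

# Known limitations

* Detection quality at the densest benchmark configuration is limited by
  the least-squares objective: fitted response peaks vary with the local
  overlap of presentations, and with $M = 100$ dendrites not every
  instantiation reaches a detection error below 0.2 on held-out data
  (the acceptance suite measures this).  A square-pulse target scored by
  thresholding is a crude surrogate for detection-optimal training.
* Solved weight mass is more concentrated than a Gaussian profile: the
  top quarter of dendrites typically holds more than half of the total
  magnitude (the acceptance suite and `scripts/acceptance.R` compute the
  exact shares), because dendrites whose kernels peak near the target
  delay are systematically more useful.
* No recurrence, cascades, or feedback of outputs into inputs; no
  conductance-based (shunting) synapses; no continuous-time event
  streams or hardware address-event formats.
* The spoken-digit (per-utterance) evaluation machinery is exercised on
  synthetic utterances only; the original cochlear-encoded corpus is
  external data and out of scope.
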