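# skimnet

Synthesis of two-layer spiking neural networks for spatio-temporal spike
pattern recognition, by the synaptic kernel inverse method.

## The problem and the method

Given multichannel spike trains in which a fixed spatio-temporal pattern
of spikes is hidden among random noise spikes, the task is to *synthesize*
— not iteratively learn — a spiking network that emits an output spike
whenever the pattern occurs.  The method builds a network in which the
hidden layer is made of synapses rather than neurons:

1. `L` input neurons connect to `M` dendritic branches of an output
   neuron through fixed random weights `w⁽¹⁾ ~ U(−0.5, 0.5)` (one synapse
   per input per dendrite);
2. each dendrite filters its weighted spike sum
   `u_{j,t} = Σᵢ w⁽¹⁾_{ji} x_{i,t}` with a synaptic kernel — by default
   the alpha function `r(t) = (t/τ_s)·e^(−t/τ_s)` with `τ_s` drawn
   uniformly per dendrite (damped resonances, delayed alpha/Gaussian
   kernels and leaky integrators are also available) — giving the spikes
   persistence in time;
3. the filtered signal is compressed by a saturating nonlinearity
   `a_{j,t} = 1/(1 + e^(−k·v_{j,t})) − 0.5`, which together with the
   random weights forms a nonlinear random projection into `M`
   dimensions and gives the synapse depressive adaptation;
4. the linear soma `y = w⁽²⁾ a` is solved in **one step** by regularized
   least squares / pseudoinverse, `W = Z A⁺`, against an analog target
   `Z` built by widening each desired output spike into a square pulse
   (width 10, delayed 10 steps past the end of the input pattern);
5. the axon hillock thresholds the soma potential at 25% of the target
   amplitude to emit output spikes.

The package provides the full toolkit: spike-raster I/O, the kernel
library with analysis utilities (FWHM, preferred delay), the forward
pass, batch and recursive (online) solvers, magnitude-based synaptic
pruning (two-pass over-provisioning and iterative discard/replace), a
generator for benchmark tasks (patterns embedded in Poisson noise, with
optional time warping and jitter), windowed detection scoring with the
`error = fn/#positives + fp/#negatives` metric, and a command-line
interface.

## Worked example

```r
library(skimnet)

# a 9-spike pattern over 5 channels in a 200-step window,
# embedded ~150 times in a 50,000-step sequence with equal noise
pattern <- make_pattern(L = 5, n_spikes = 9, duration = 200, seed = 7)
train   <- embed_pattern(pattern, K = 50000, presentation_rate = 300/1e5, seed = 8)
train
#> <embedded_sequence> 148 presentations in 50000 steps; 1325 pattern + 1262 noise spike cells

# synthesize the detector in a single linear solve
model <- skim_train(train$raster, train$presentation_end_times, M = 100, seed = 9)
model
#> <skim_model> L = 5 inputs, M = 100 dendrites, N = 1 outputs
#>   kernels: alpha x100
#>   threshold = 0.25 (target amplitude 1), dt = 1 ms, seed = 9

# score on an independently generated sequence
test <- embed_pattern(pattern, K = 50000, presentation_rate = 300/1e5, seed = 10)
res  <- skim_evaluate(model, test$raster, test$presentation_end_times)
res$counts
#> <eval_counts> tp 81 / fn 0 (of 81 positive), fp 4 / tn 180 (of 184 negative)
res$error
#> 0.022
```

All 81 (merged) pattern presentations in the held-out sequence are
detected, with 4 false alarms across 184 pattern-free windows, for a
detection error of 0.022 (0 is perfect, 2 is maximally wrong).  The
solved weights concentrate on a minority of dendrites,

```r
weight_concentration(model)
#> <concentration_curve> M = 100; share at top 25/50/100: 68.7%/89.0%/100.0%
```

which is why magnitude pruning (`prune_two_pass()`,
`prune_iterative()`) can shrink the network with little loss.  Kernel
analysis utilities report, e.g., the half-height width that governs
jitter and time-warp tolerance:

```r
kernel_fwhm(kernel_spec("alpha", ts = 10))
#> 24.46386
```

The same pipeline is available from the shell via the installed launcher
(`system.file("cli", "skim", package = "skimnet")`):

```sh
skim generate --length 50000 --presentations 150 --seed 8 --out spikes.csv --truth truth.csv
skim train    --spikes spikes.csv --channels 5 --length 50000 --targets truth.csv \
              --dendrites 100 --kernel alpha --tmax 200 --seed 9 --out model.json
skim eval     --model model.json --spikes spikes.csv --channels 5 --length 50000 --truth truth.csv
skim kernel-info --kernel alpha --tau 10
```

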