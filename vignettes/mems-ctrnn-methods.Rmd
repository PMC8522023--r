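---
title: "MEMS-based continuous-time recurrent networks for activity detection: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MEMS-CTRNN methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(memsctrnn)
```

This vignette is the package's account of the science it implements: the
physical neuron model and its numerics, the preprocessing and augmentation
devices, the training machinery, what the synthetic benchmark does and does
not emulate, and the design decisions taken where the problem was genuinely
open.

## The node models

### Electrostatic MEMS neuron

Each neuron is a parallel-plate electrostatic MEMS device reduced to a
single mechanical degree of freedom, the displacement $z_i \in [0, d)$ of
the proof mass toward the fixed electrode across the gap $d$ (default
$42\,\mu\mathrm{m}$). Damping dominates inertia, so the dynamics are first
order:

$$
\tau \,\dot z_i + z_i \;=\;
\frac{\varepsilon A}{2k\,(d - z_i)^2}\,V_i^2
\;+\; \frac{1}{\omega_n^2} \sum_k w_{\mathrm{in},ik}\, u_k(t),
\qquad \tau = \frac{2\zeta}{\omega_n}.
$$

The left side is a damped spring; the first forcing term is the
parallel-plate electrostatic attraction under node voltage $V_i$, whose
$(d-z)^{-2}$ divergence produces the pull-in instability; the second term
is the input forcing (only input-layer neurons have nonzero rows of
$w_{\mathrm{in}}$), normalized by the stiffness scale $\omega_n^2$.

Node voltages couple the network. Each neuron's voltage is its bias plus
the weighted voltages of neurons currently *firing* into it,
$V_j = \sum_k w_{jk} V_k U_k + \theta_j$, where $U_k$ indicates that
neuron $k$'s displacement has crossed the firing threshold. This recursion
is cyclic in a recurrent network; we break the cycle by holding the firing
pattern of the *previous* Euler substep fixed, under which the voltages are
the fixed point of a linear system solved exactly at every substep
(`node_voltages()`). A one-substep delay at millisecond substeps is far
below every physical timescale in the model.

Two displacement thresholds close the model. The proof mass is stopped at
$0.95\,d$ (a mechanical stop short of the electrode; the electrostatic term
is singular at contact), and the neuron *fires* at $0.9\,d$. Both are
configurable fractions in `mems_params()`. The device is bistable between
the pull-in voltage $V_{pi} = \sqrt{8kd^3/27\varepsilon A}$ and the much
lower release voltage set by the force balance at the stop; this hysteresis
is the network's memory.

### Choice of physical constants

The gap $d = 42\,\mu$m and the time constant $\tau = 0.0017$ s are fixed
design targets of this model family; the remaining device constants are
open hardware choices. We chose $\zeta = 8.5$, $\omega_n = 10^4\,$rad/s (so $\tau = 2\zeta/\omega_n
= 0.0017$ s exactly, and the device is heavily damped as the model
assumes), and $A = 10^{-7}\,\mathrm{m}^2$, $k = 4\times10^{-5}\,$N/m so
that $V_{pi} \approx 1\,$V. The last choice is deliberate: it places
trained voltage weights and biases at order one, where a single learning
rate conditions all voltage-like parameter groups equally. Any other
$(A, k)$ pair with the same $V_{pi}$ behaves identically up to a rescaling
of the weights.

### Reference CTRNN

The software baseline replaces the MEMS node by the standard
continuous-time recurrent neuron
$\tau_i \dot y_i = -y_i + \sum_j w_{ij}\,\sigma(y_j) + h_i + I_i$ with
logistic $\sigma$, integrated with the same sub-stepping policy so that
engine comparisons isolate the node model. Its default time constant is
the MEMS design value.

## Numerics

Explicit Euler with `substeps` per 50 Hz input sample; each input sample is
held constant over its sampling interval. Stability of the homogeneous
equation requires $dt < 2\tau$; with $\tau = 0.0017$ s the default is 16
substeps ($dt = 1.25$ ms $\approx 0.74\,\tau$), and every entry point
refuses to integrate outside the stability region. Time-constant sweeps
that rescale $\omega_n$ raise the substep count as needed
(`stable_substeps()`).

Pull-in snap-through is a genuine singularity for explicit integrators:
near contact the electrostatic term can move the mass many gaps in one
step. The production simulator caps the per-substep displacement increment
at $d/2$ (configurable), resolving the snap over a few substeps; the
single-step operator `mems_step()` with the cap disabled instead raises an
error when a pre-clamp overshoot exceeds $2d$, which is the correct
diagnosis when the *time step* (rather than the snap) is at fault. The cap
does not move equilibria, so pull-in and release voltages are unaffected
(verified against a root-tracking oracle in the tests). After every
substep, displacements are clamped to $[0, 0.95\,d]$ and firing indicators
recomputed.

## Classification pipeline

Windows of multichannel signal enter the network either ternary-quantized
or raw-standardized. The readout applies a dense $2 \times N$ map to the
**window-averaged firing activity** of each neuron and the two scores are
softmaxed. We read out the mean activity rather than only the terminal
state because a firing-rate summary is the natural window-level statistic
of a spiking device and carries far more gradient signal; the terminal
state of a sub-second window is dominated by the last few samples.

### Ternary quantization

Consecutive-sample differences are mapped to $\{+1, 0, -1\}$ using a
per-channel threshold $\epsilon$; the rule $\epsilon = \mu + \sigma/2$
(`select_epsilon()`) is applied to *mean-centered* channel samples. The
centering matters: the code operates on differences, which are blind to the
channel mean, and on a gravity-offset axis an uncentered mean would inflate
$\epsilon$ by an order of magnitude and silence the channel. Thresholds
are fitted on the training split only and frozen
(`fit_quantizer()` / `quantize_dataset()`); the same leakage rule applies
to the standardization statistics in the non-quantized mode. A window of
raw length $\ell + 1$ becomes a ternary window of length $\ell$.

The quantizer's symbol orientation follows its source convention (`+1`
flags a step *down* to the next sample); since the alphabet is symmetric,
orientation is irrelevant to the classifier, and we keep it fixed for
reproducibility.

### Mutation augmentation

Activity windows are a small minority of any realistic recording, so the
training split is rebalanced by mutation: each positive window spawns `K`
copies, each differing at exactly one random (sample, channel) position,
moved to a different level within `M` quantization levels (continuous
windows move on a per-channel grid of spacing sd/4). The default `K` is
chosen at augmentation time to bring the positive class to about one half.
We read the augmentation operator as "K copies with one mutation each"; a
config switch provides the alternative reading (one copy with K mutated
positions). Augmentation is a training-only device, and the pipeline
raises an error if it is applied to a test split.

## Training

Training minimizes the mean cross-entropy of the softmaxed scores by
mini-batch SGD with momentum (0.9) and global gradient-norm clipping,
backpropagating through the discretized dynamics. Three devices make this
work on a pull-in network:

* **Surrogate firing.** The unit step is not differentiable, and worse,
  sub-pull-in displacements never exceed $d/3$ while firing happens at
  $0.9\,d$: any *narrow* smooth surrogate has identically zero gradient on
  the whole sub-pull-in branch. The training forward pass therefore
  replaces the step with a logistic of steepness `surrogate_beta`
  (default $1.2\times10^5$ 1/m, a transition width comparable to the gap)
  in both the voltage gating and the activity summary, and sharpens it
  geometrically by a factor `beta_growth` (default 30) over the epochs so
  the final solution transfers to the hard-step evaluator. Evaluation and
  prediction always use the hard step: reported accuracies are those of
  the physical model.
* **Group rescaling.** Input weights act through $1/\omega_n^2$, so their
  useful magnitude is $\sim d\,\omega_n^2 \approx 4\times10^3$ while
  voltage weights are order one. The optimizer rescales each weight group
  to dimensionless units before clipping and stepping — plain clipped SGD
  on normalized parameters. Initialization follows the same scales: MEMS
  input weights at $2\,d\,\omega_n^2 \times$ `init_scale` (unit-amplitude
  inputs can reach pull-in), CTRNN input weights at $4 \times$
  `init_scale` (inputs span the sigmoid).
* **Exact adjoints.** The backward pass differentiates through the
  per-substep voltage solve (one transpose solve per step) and treats the
  displacement clamp and increment cap as piecewise-constant regions with
  zero gradient. Backpropagated gradients match central finite differences
  to $10^{-4}$ relative on every weight group (tested).

Loss, optimizer, initialization and the surrogate are engineering choices
of this package — the simplest defensible stack — and every knob is
exposed in `train_config()`.

## The synthetic benchmark

`generate_recording()` emulates waist-worn 50 Hz tri-axial accelerometry:
a gravity-like constant baseline with AR(1) noise (band-limited, as sensor
noise at 50 Hz is), into which annotated activity segments are placed at
random non-overlapping positions. One oscillatory activity ("walk": a
2 Hz sinusoid spread over all three axes with distinct per-axis amplitudes
and phases, and raised-cosine onset/offset ramps) and four step-like
postural transitions (smooth one-axis bumps) are provided; default class
proportions mirror a strongly imbalanced real-world mix (15.8% walk, under
1% per transition), which is the situation mutation augmentation exists to
repair. Per-subject gains and offsets emulate placement variability; a
`separability` knob scales all template amplitudes against the noise, with
0 yielding a pure null benchmark.

Two template choices deserve explanation because qualitative protocol
results depend on them:

* Walk bouts default to 4–8 s with 0.6 s amplitude ramps, a few analysis
  windows long. Bout-core windows are clean (this is what makes the
  benchmark high-separability and learnable to $\ge 90\%$), while windows
  straddling bout edges carry both intermediate activity *fractions* and
  weak signal. Those boundary windows are exactly where a 50% and a 75%
  labeling threshold disagree; because their signal is weak, the lower
  threshold dilutes the positive class with hard examples and scores
  worse — the qualitative threshold effect the evaluation protocol
  expects. Without ramps (instant full-amplitude gait) the effect
  *reverses*, since boundary windows would then be easy positives.
* The walk signal spans all three axes unequally, so dropping an axis
  discards real signal and the 2-channel ablation scores below the
  3-channel baseline without making the 2-channel task hopeless.

What the generator does **not** emulate: biomechanics (harmonics, impacts,
jerk), orientation drift, sensor saturation, inter-subject style
differences beyond gain/offset, or label noise. Passing tests on this
benchmark demonstrate that the simulator, preprocessing, augmentation and
trainer work as specified — not that any accuracy level transfers to real
recordings.

A note on the null-model check: a deterministic classifier trained on
shuffled (hence uninformative) labels collapses toward a constant
decision, so its plain accuracy on an imbalanced test split equals a class
share rather than 1/2. The package therefore reports *balanced* accuracy
(`balanced_accuracy()`) alongside plain accuracy; any uninformed
classifier scores 1/2 balanced accuracy in expectation, which makes it the
correct null yardstick.

## Evaluation protocols

`split_dataset()` partitions windows 70/30 at the window level (seeded); a
by-subject mode exists for leakage-sensitive designs.
`evaluate_activity_detection()` runs the full leak-free pipeline: subset
channels, split, fit preprocessing on the training part, augment the
training part, train, evaluate hard-step accuracy on both parts.
`run_grid()` crosses engines, hidden sizes (canonically 3/6/9/16),
quantization, channel subsets, labeling thresholds (0.5/0.75),
natural-frequency multipliers $P \in \{1/5,\dots,1/2, 1,\dots,10\}$
(time constant $\tau/P$), activities and seeds, catching per-cell failures.
Problem sizes in the package's tests — five subjects, 110 s each, 65-sample
windows at stride 64, about 425 windows, 25 epochs — were chosen as the
smallest configuration at which the end-to-end claims are comfortably
reproducible on a laptop core in minutes.

## Power model

The physical network's switching power is modeled as capacitor charging:
each switching event stores $\tfrac12 C V_{op}^2$, so $n$ neurons
switching at $f$ Hz dissipate $n \cdot \tfrac12 C V_{op}^2 f$ — with the
default 0.5 pF, 5 V, 100 Hz worst case, 0.625 nW per neuron and 62.5 nW
for 100 neurons. (Published figures for this model quote 0.625 nW per
neuron but 6.25 nW per 100 neurons; the pair is inconsistent by a factor
of ten, and the package implements the closed form, which reproduces the
per-neuron figure.)

## Known limitations

* The voltage fixed point can be ill-conditioned if trained recurrent
  weights approach unit spectral radius on the fired subnetwork; the
  solver reports the offending neuron rather than continuing with garbage.
* Gradients are blind to intervals where a neuron sits on a stop (clamp)
  or its increment is capped; training relies on the transitions carrying
  signal, as is usual with surrogate-gradient methods.
* Per-neuron heterogeneous time constants are representable
  (`ctrnn_params()` accepts a vector) but not trained.
* The raw-recording reader targets the public smartphone-archive text
  layout as fixture-tested here; it is best-effort against future layout
  changes.
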