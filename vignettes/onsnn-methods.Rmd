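---
title: "Online neuroplasticity spiking networks: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online neuroplasticity spiking networks: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onsnn)
```

## The problem

`onsnn` implements a streaming classifier for short multichannel
time-series segments — the motivating application is personalized
EEG-based recognition of cognitive states (stress / neutral / positive
affect) from a handful of channels — under the constraints of genuine
online learning: each sample is seen once, memory is bounded by the model
(not the data), and the data distribution may drift while the model is in
use. The classifier is a three-layer spiking neural network whose every
learning mechanism operates on the fly: there is no offline training
phase, and the network is evaluated test-then-train, so each sample is
predicted before anything is learned from it.

## The model

**Encoding (AER).** A segment (channels × time, e.g. 4 × 1280 for 5 s at
256 Hz) is converted to a ternary event train by address event
representation: per channel, the temporal difference
$\mathrm{td}_t = x_t - x_{t-1}$ is compared with an adaptive threshold
$\mu(\mathrm{td}) + f\,\sigma(\mathrm{td})$ computed over the segment
($\sigma$ is the population standard deviation; $f = 0.7$ by default). A
difference above the threshold emits an excitatory event (+1), below its
negation an inhibitory event (−1), otherwise nothing. The encoding is
amplitude-invariant by construction — rescaling a channel rescales its
threshold — so class information must reside in the *temporal structure*
of the events, not their count alone. Two readings of the emission rule
are possible; the dense reading (an event at every step) contradicts the
sparse rasters this architecture is known for, so the symmetric
three-state convention is used, with strict inequalities (a tie emits
nothing).

**Hidden layer (LIF + intrinsic plasticity).** The events drive
$N = 100$ leaky integrate-and-fire neurons through a dense synaptic
matrix $W$ (channels × $N$), initialized from a zero-mean Gaussian
($\sigma_{\mathrm{init}} = 0.1$) and clipped to $[-0.5, 0.5]$; positive and
negative weights realize excitatory and inhibitory synapses. Membrane
potentials follow $\tau_m \dot v = v_{\mathrm{rest}} - v + R I_t$ with
$\tau_m = RC = 10$ steps, integrated by forward Euler with one step per
signal sample ($I_{j,t} = \sum_i W_{ij} s_{i,t}$, with $s$ the signed
events). A neuron whose potential reaches its threshold fires and resets
to $v_{\mathrm{rest}}$; there is no refractory period. Each neuron owns an
adaptive threshold: after a spiking step it rises by
$N \theta_+ v_{\mathrm{init}}$ (0.005 at the defaults), after a silent
step it falls by $N \theta_- v_{\mathrm{init}}$ (5 × 10⁻⁶). This
intrinsic plasticity enforces firing-rate homeostasis and is what makes
the hidden code temporally sparse. Down-regulation is floored at 10% of
$v_{\mathrm{init}}$; an unbounded decay would eventually drive thresholds
to the resting potential and cause pathological firing.

**Synaptic learning (STDP).** Input→hidden weights adapt by
spike-timing-dependent plasticity with exponential windows:
$\Delta t = t_{\mathrm{post}} - t_{\mathrm{pre}} > 0$ potentiates by
$A_+ e^{-\Delta t/\tau_+}$, $\Delta t < 0$ depresses by
$A_- e^{\Delta t/\tau_-}$ ($A_\pm = 10^{-3}$, $\tau_\pm = 10$). The
cumulative change over all pre/post pairs of a sample is applied once at
sample end and clipped to the bounds; this granularity admits an exact
brute-force oracle (and the suite checks equivalence to 10⁻¹²). Pairs
further apart than `pair_window` = 5·max($\tau_+,\tau_-$) = 50 steps are
ignored — beyond 5τ a pair contributes less than $e^{-5} A$, so the
cutoff is numerically immaterial. Pre-synaptic events of either polarity
count as spikes for timing; polarity enters only through the current.

**Output layer (evolving rank-order classifier).** Each output neuron
stores a weight vector over the hidden neurons plus a class label. For
every sample a *candidate* vector is built from the hidden raster: the
$r$-th hidden neuron to fire first receives $\alpha \cdot
\mathrm{mod}^r$ ($\alpha = 1$, $\mathrm{mod} = 0.8$; never-firing neurons
receive 0), then a drift of $+d$ per subsequent spiking step and $-d$ per
silent step ($d = 10^{-3}$) is accumulated. Classification is
nearest-neighbour by Euclidean distance over stored neurons (ties go to
the oldest). The repository starts empty: the first 15 samples each
evolve one labelled neuron (the initiation set); afterwards a neuron is
evolved only when the prediction was wrong. On errors the hidden layer
additionally *self-prunes* — neurons with accumulated spike count below
`sp_thresh` = 1 have their threshold raised to the population maximum,
silencing them until homeostatic decay revives them — and evolved output
neurons that have won at least `min_errors` = 3 misclassifications, more
than their correct wins, are eliminated (a class is never emptied, and
initiation neurons are never eliminated). Without structural plasticity
the same network evolves one neuron per sample, never prunes and never
eliminates: that configuration is the online baseline (O-RSNN); the batch
baseline (B-RSNN) builds one neuron per training sample on a 70/30 split
and classifies the test samples with all learning frozen.

**Evaluation.** Online runs are scored prequentially: the running mean of
0/1 correctness, updated incrementally as
$\mathrm{acc}(t) = \mathrm{acc}(t-1) + (c_t - \mathrm{acc}(t-1)) /
(t - t_{\mathrm{init}} + 1)$. The reference point $t_{\mathrm{init}}$ is
the end of initiation: predictions are logged from the second sample
onward but scoring (and the error-driven machinery) begins once the
initiation set is complete. This reading is forced by arithmetic —
published accuracy traces for this architecture reach a running mean of
80% within 30–40 samples and end above 0.9, which is impossible if the
low-accuracy initiation samples were inside the mean. Sensitivity is the
true-positive rate of the designated stress class, and the efficiency of
the hidden code is summarized by the ratio of spikes generated by the
hidden layer to spikes received by it.

## Interpretation choices worth knowing about

Several points are under-determined by the method's published
description; the package resolves them as follows.

* **STDP sign convention.** The timing difference is post minus pre;
  post-after-pre potentiates. The prose description that accompanies the
  equations swaps the roles of pre and post in one sentence; the formula
  and its worked consequences are followed.
* **Self-pruning window.** "Low spiking probability" is judged on spike
  counts accumulated over the stream so far, not over the single sample
  last seen. The per-sample reading silences every neuron that happened
  to be silent for one sample (about half the population per error),
  which collapses the hidden layer at realistic error rates; the
  accumulated reading matches the batch ancestor of this pruning rule,
  where firing probability is estimated over a dataset, and produces the
  intended gentle dimensionality reduction.
* **Membrane state across samples.** Segments are excerpts from separate
  stimulus presentations, not a contiguous recording, so the fast state
  (membrane potential, last-spike flag) is reset between samples while
  the slow homeostatic thresholds persist.
* **Initiation-neuron updates.** A per-pass weight update for initiation
  neurons exists behind `update_init_neurons` but is off by default: no
  numerically sane reading of the published description was found (a
  literal per-step ±d accumulation diverges over a long stream), and the
  frozen-initiation variant is well defined.
* **Elimination rule.** No formula is published for "eliminate or
  preserve … based on the classification errors"; the counter rule above
  (with `min_errors` = 3) bounds memory and is configurable.

## The synthetic-data generator

Real recordings for this task are not publicly deposited, so the package
ships a generator that emulates the statistical structure the method
assumes. Each class is a mixture of the four canonical EEG bands (delta
1–4 Hz, theta 4–8, alpha 8–13, beta 13–30): per channel, one sinusoid per
band at a random in-band frequency and phase, scaled by a class- and
channel-specific amplitude profile, plus 1/f and white noise. Defaults
mirror the acquisition geometry of the motivating study: 4 channels (FP1,
FP2, T7, T8), 256 Hz, 5-s segments, 72 segments per stream, 24 per class.
The default profiles encode the standard stress-EEG contrast — alpha
suppression with frontal-dominant, right-lateralized beta elevation under
stress; temporally-dominant alpha elevation under positive affect — so
streams are both learnable and channel-asymmetric (the interpretability
analyses need topography to recover). The noise is low-passed at 50 Hz
because the method consumes *preprocessed* EEG, which has already been
band-limited; full-bandwidth noise would corrupt the temporal differences
in a way real inputs never do. Drift is injected explicitly: input drift
rescales the signal from a chosen sample onward (labels untouched);
concept drift permutes the class labels from a chosen sample onward
(generators untouched).

What the generator does **not** emulate: amplitude bursts and artifacts,
non-stationary topography within a class, cross-channel phase coupling,
and session-level autocorrelation. Real EEG class contrasts are stronger
and more redundant than a stationary band mixture, so passing results
here demonstrate the machinery works end-to-end and in the right
direction — not that the headline accuracy on real recordings would be
reproduced. On the default streams a trivial nearest-band-power
classifier exceeds 90%, while the spiking pipeline — whose every
representation-shaping constant is fixed by the method's published
hyperparameter table, with no per-subject tuning of the intrinsic
plasticity rates (the original work tuned them per subject by an
unpublished criterion) — reaches a nearest-neighbour ceiling of roughly
0.78 on its candidate vectors and final prequential accuracies around
0.7 on stationary streams, in the high 0.5s under mid-stream drift.

## Problem sizes and numerics

The test suite exercises full-size streams (72 × 4 × 1280) where a check
depends on the study geometry, and 12-sample, 0.5-s streams elsewhere;
the directional comparisons repeat over 10 weight initializations. All
randomness flows through explicit integer seeds (weights, stream
composition, per-segment synthesis), so any run is bit-reproducible from
its configuration. Ties in first-spike rank are broken by neuron index;
classification ties by neuron age then id. Weight clipping is applied
after the cumulative STDP update, so a saturated synapse stays exactly at
the bound. An all-silent hidden raster yields a flagged all-zero
candidate; classification still proceeds against the repository.

## Known limitations

The hidden representation is shaped entirely by unsupervised rules with
constants fixed a priori; nothing adapts them to a particular subject or
stream. Under a hard mid-stream label swap the protected initiation
neurons retain their stale labels indefinitely, which bounds how quickly
any amount of neuron evolution can recover — a structural property of
the method, visible in the drift experiments. The LIF solver is plain
forward Euler at one step per sample period; this matches the event
cadence but makes $\tau_m$ effectively a step count, not a physical
time constant.
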