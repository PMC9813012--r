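---
title: "Collaborative multimodal reservoir computing: model, stimuli and metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collaborative multimodal reservoir computing: model, stimuli and metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

comodal simulates a pair of echo-state reservoir modules — one per sensory
modality — whose linear readouts teach each other. The scientific question
it addresses is how recurring, co-occurring stimulus pairs ("chunks", here
a spoken-letter sequence paired with an image) can be segmented from
continuous multimodal streams *without labels*, purely from the statistics
of co-occurrence. This vignette documents the model, the stimulus
generators, the evaluation metrics, the numerical choices, and — candidly —
what the simulator does and does not reproduce.

## The model

Each module is an echo-state network of `N` rate neurons with membrane
variable `x` and rate `r = tanh(x)`, integrated by forward Euler at
`dt = 1` ms:

    tau dx/dt = -x + g W r + W_in i(t) + W_back z + k xi(t)

* `W` is a fixed Bernoulli(`p`)-sparse recurrent matrix with N(0, 1/(pN))
  weights; `g = 1` places the network at the edge of the chaotic regime.
* `W_in` connects each reservoir neuron to exactly one input line with an
  N(0, 1) weight.
* The `O = 3` linear readouts `z = W_out r` each read a random subset of
  `S` neurons and project back to all neurons through `W_back` (uniform on
  [-1, 1]).
* `k xi(t)` is i.i.d. Gaussian noise, `k = 0.2`.

Only `W_out` is plastic. It is trained online by FORCE (recursive least
squares with inverse-correlation matrix `P`, initialized to `I/alpha`,
`alpha = 100`), against a teaching signal derived from the *partner*
module's readouts. The partner's readouts are first normalized to zero mean
and unit variance with sliding-window statistics over the last
`T = 15000` ms, then passed through a soft winner-take-all transform,

    f_i = [ tanh( (zhat_i - gamma (sum_j zhat_j - zhat_i)) / beta ) ]_+

with `beta = 3`, `gamma = 0.5` (with three readouts, the competition term
is exactly the mean of the other two). The error `e = z - f` drives the RLS
update at every step. Because the transform is equivariant under index
permutation, readouts with the same index in the two modules come to
respond to the same chunk if selectivity emerges, and the fixed association
output `o = delta (z1 + z2)`, `delta = 0.5`, then reads out the agreement.

Three alternative coupling architectures replace the cross-fed teacher
(which becomes module-local) with structural links: `a1` couples the
reservoirs directly (Bernoulli(0.1) cross-matrices), `a2` feeds each
module's readouts back into the partner's reservoir (uniform [-1, 1]), and
`a3` couples the readouts all-to-all. For these, a Hebbian association
layer with subtractive normalization (`assoc_output_and_hebb()`) learns to
align the modules' independently organized readouts; its learning-rate
multiplier (default `1e-4`) is a package choice, as the Hebbian equation is
scale-free.

## Stimuli

All inputs are synthetic. The text-tone channel has 26 input lines, one per
letter; a letter occupies a 50 ms slot, with a rectangular pulse over the
leading 80% of the slot. The image channel encodes a 60x60 RGB raster as a
30-dimensional time series: each RGB component is cut into 10 horizontal
bands, and a narrow window (2 px) scans each band left to right with mean
pooling, with as many scan positions as the paired text-tone has time
steps, so the two modalities of an epoch are always duration-aligned.
Chunks pair a letter sequence with a procedurally drawn image ("apple",
"grape", "banana"); random separators pair a uniformly random 5-8 letter
string with a fresh Gaussian-noise image. Schedules alternate chunk epochs
with separators (or not), and two manipulations break co-occurrence: pair
replacement with probability `m` (one modality of a chunk epoch is replaced
by another chunk's signal or a random segment, chosen uniformly) and an
inter-modal delay `d` implemented as a global shift of one modality's
stream (zero-filled at the head).

Two stimulus-design choices deserve emphasis, because getting them wrong
changes the science qualitatively:

* **Chunk images are full-field.** The procedural shapes are drawn on a
  mid-gray background whose mean intensity matches the noise images. With
  shapes on an empty background, the separator images are the *most
  consistent* stimulus category on the image channel (every noise image
  pools to the same bright platform), and the mutual-teaching rule — which
  rewards consistency — converges to a degenerate separator detector. The
  photographs such images stand in for are full-field, so the gray
  background is the faithful choice, not a cosmetic one.
* **The scanning window is narrow.** Mean pooling over a wide window
  averages the pixel noise of every separator image to nearly the same
  series; a 2 px window keeps each noise image's encoding unique, which is
  what makes the separators *separators*.

Two parameters the underlying model description leaves open are calibrated
by mechanism-level criteria measured on untrained networks (never against
benchmark outcomes): the letter-pulse amplitude (default 5) is set at the
knee of the trial-to-trial trajectory-reliability curve of the text-driven
reservoir, which a unit pulse leaves badly initial-condition-sensitive at
`g = 1`; and the readout feedback uses the raw `z` (the literal dynamics
equation), which preserves cold-start trajectory reliability, rather than
the normalized readouts, which inject order-one normalized noise into the
reservoir from the first step (`build_model(feedback = "normalized")`
remains available).

## Evaluation

The association output is convolved with a causal Gaussian kernel (s.d.
20 ms, truncated at 3 s.d., replicate-padded at the start), min-max
normalized to [0, 1] per unit, and scored per annotated epoch by the epoch
mean (peak optionally); the winning unit must reach a no-response threshold
(default 0.3), otherwise the epoch is scored as silence, which is the
correct answer for random separators. Because learning is unsupervised, the
unit-to-chunk assignment is chosen to maximize the confusion-matrix
diagonal (exhaustive over permutations), and accuracy is the maximal
diagonal sum over the total epoch count.

Population dynamics are characterized by PCA of the pooled reservoir rate
history: per-chunk trials are aligned at the presentation midpoint, and the
separation degree between two chunks' trajectories is the summed ratio of
their deviations to their center distance over +/-100 steps around the
midpoint (smaller is better separated). The eigenvalue spectrum gives the
cumulative contribution curve and the effective dimensionality
`1 / sum(lambda_hat^2)` (spectrum normalized to unit sum, so that `n`
equally loaded components give exactly `n`). Activation phases (circular
mean times of min-max-normalized rates) sort readout-projecting neurons by
when in a chunk they fire.

## Numerical choices

* Forward Euler at `dt = 1` ms (exposed for convergence checks).
* The per-step reservoir noise is drawn from an internal mt19937-64 +
  Box-Muller generator seeded from R's RNG stream, so `set.seed()` controls
  every random element while keeping ~1e8 draws per run affordable.
* In the simulation loop the recurrent matvec `W r` runs in single
  precision; its rounding (~1e-7 relative) is five orders of magnitude
  below the injected noise `k xi`. The exported single-step and
  single-update functions are full double precision.
* RLS maintains only the lower triangle of the symmetric `P` (BLAS
  `dsymv`/`dsyr`) and mirrors it on exit; the update is algebraically the
  standard `P <- P - (P r)(P r)'/(1 + r'P r)`.
* Sliding statistics use an incremental circular buffer; below a standard
  deviation floor of `1e-6` the normalized readout is set to 0 (cold-start
  guard). A configurable warm-up (default one full window `T`) precedes
  weight updates.
* Early in training the windowed sigma is near zero and the normalized
  readouts are extremely sensitive to rounding; trajectories of the
  coupled learning system are therefore chaotic with respect to
  perturbations at machine precision. Identical seeds reproduce bitwise;
  numerically equivalent reorderings do not stay close, which is a
  property of the model, not of the integrator.

## What the simulator reproduces, and what it does not

The package's tests compute the following, all at desk scale (`N = 600`,
`S = 200`, `C = 300` training epochs with separators, evaluation on a
held-out track of `C/4` epochs; the architecture comparison uses
`C = 80` in the test suite and `C = 100` in the acceptance script; the
full-size study configuration `N = 1200`, `S = 300`,
`C = 2200` is available but not exercised by the default suite):

* **The readout pipeline can express and learn the chunk-selective
  solution.** With an idealized one-hot teacher passed through the same
  FORCE loop (`train(..., teacher = chunk_teacher(track))`), accuracy
  exceeds 0.8, and random epochs are answered with silence.
* **The cross-fed teacher approximately preserves that solution.**
  Continuing to train the organized model with the self-organized mutual
  teacher keeps accuracy above 0.6 over a further full training track —
  the organized state is (approximately) a fixed point of the printed
  learning rule.
* **Self-organization from random initialization does not reach that
  state in this implementation.** Across every resolution of the
  under-determined details we explored — input amplitudes and timescales,
  image statistics, warm-up lengths, RLS gain, teaching sharpness,
  separators on or off, training lengths up to and including the full-size
  configuration — the mutual teacher converges to degenerate attractors:
  with raw feedback, a slow winner-rotation limit cycle on the
  normalization-window timescale that ends in a single readout responding
  everywhere; with normalized feedback, a diffuse state whose
  chunk-conditioned bias never sharpens because the instantaneous
  winner-take-all is decided by readout noise. The acceptance suite
  measures this honestly: the end-to-end learning, co-occurrence-
  degradation and architecture-ordering checks fail at desk scale, and
  their failing values are reported as computed. The population-trajectory
  metrics (finite separation degrees, bounded effective dimension,
  monotone cumulative contribution) hold on the trained models regardless.

The synthetic stimuli emulate the *structure* of the original experiments
(paired recurring patterns in two concurrent channels, separator
inconsistency, duration alignment) but not the feature statistics of
natural photographs or audio; conclusions from passing tests transfer to
real data only insofar as those structural properties are what matters.

## Problem sizes and runtime

A desk-scale train-plus-evaluate experiment is roughly 30-50 s on one CPU
core; the default test suite runs the five-seed learning experiment, two
three-cell manipulation sweeps sharing their clean baselines, and a
forty-run architecture comparison. `run_parameter_sweep()` exposes the
(tau, g, N, S, p, k, C) grids of the full study for users who want the
surfaces.
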