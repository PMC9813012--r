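# comodal

Simulator for **collaborative multimodal reservoir computing**: two
echo-state networks, one per sensory modality, whose linear readouts teach
each other and thereby segment recurring, co-occurring stimulus pairs
("chunks") from continuous two-channel input streams without any labels.
It is aimed at computational neuroscientists studying multisensory
integration and unsupervised temporal segmentation with neural population
dynamics.

## The model

Each module is an echo-state network of `N` rate neurons,

```
tau dx/dt = -x + g W r + W_in i(t) + W_back z + k xi(t),   r = tanh(x),
z = W_out r,
```

with fixed recurrent (`W ~ sparse N(0, 1/(pN))`), input (one line per
neuron, `N(0,1)`) and feedback (`uniform [-1,1]`) weights. Only the readout
`W_out` is plastic: it is trained online by FORCE (recursive least
squares) against a teaching signal computed from the *partner* module's
readouts — normalized to zero mean and unit variance over a sliding window
`T`, then passed through a soft winner-take-all:

```
f_i = [ tanh( (zhat_i - gamma * (sum_j zhat_j - zhat_i)) / beta ) ]_+
e_i = z_i - f_i
```

Whichever readout dominates in one module reinforces the same-indexed
readout in the other, so chunk selectivity can only come from consistent
co-occurrence across the modalities. An association layer reads out the
agreement, `o = delta (z1 + z2)`; alternative architectures (`a1`
reservoir-to-reservoir, `a2` cross-module readout feedback, `a3`
readout-readout coupling) close the teacher within each module and align
the modules with a Hebbian association layer instead.

The package also provides the full stimulus machinery (text-tone letter
pulses, procedurally drawn and scanned RGB images, random-sequence
separators, pair-replacement probability `m` and inter-modal delay `d`
manipulations), confusion-matrix accuracy with optimal unit-to-chunk
assignment, and population-dynamics metrics (PCA trajectory separation,
activation phases, effective dimensionality).

## Worked example

Train a desk-scale model with an idealized one-hot teacher pushed through
the same FORCE loop (the supervised upper-bound probe), then score a
held-out stream:

```r
library(comodal)
set.seed(42)

stim   <- stim_params()
chunks <- default_chunks(stim)
track  <- generate_track(schedule_params(C = 120), chunks, stim)
track
#> <rc_track> 35250 steps (dt = 1 ms), 120 epochs
#>  apple banana  grape random
#>     26     21     13     60

model <- build_model("original",
                     model_params(N = 400, S = 150, I = 26),
                     model_params(N = 400, S = 150, I = 30))
model <- train(model, track, teacher = chunk_teacher(track))

test <- generate_track(schedule_params(C = 40), chunks, stim)
evaluate_run(run_inference(model, test))
#> <rc_eval> accuracy = 0.925 (RC1 0.475 / RC2 1 )
#>         unit
#> label     1 2 3 no_response
#>   apple  11 0 0           0
#>   grape   0 3 0           0
#>   banana  0 0 6           0
#>   random  0 1 2          17
```

The accuracy (0.925) counts every epoch: each chunk row lands on its own
unit after the optimal assignment, and 17 of 20 random separators are
correctly answered by silence (no unit above the response threshold).
Replacing `teacher = ...` with nothing runs the self-organized mutual
teacher — see the vignette for an honest account of when that does and
does not organize from scratch.

Self-organized experiments, manipulation sweeps and architecture
comparisons are one call each:

```r
ex <- run_learning_experiment(experiment_config(), seed = 1)
tb <- run_cooccurrence_sweep(experiment_config(), m_grid = c(0, 0.5, 1), seeds = 1:3)
tv <- run_variant_comparison(experiment_config(C = 100), seeds = 1:10)
```

A thin command-line front-end (`exec/comodal`) exposes
`gen-stim` / `train` / `eval` / `sweep` with a YAML config.

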