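# vvsreadout

Tools for asking a sharp question about visual discrimination tasks: **is a
linear readout of a ventral-visual-stream (VVS) proxy sufficient to account
for the observed choice behavior?** If it is, the task cannot diagnose
perceptual contributions from structures beyond the VVS (such as perirhinal
cortex); only performance *exceeding* the readout can.

The package is aimed at researchers analyzing primate (or simulated)
two-alternative "cat/dog" morph classification and three-image odd-one-out
data. It implements the complete analysis chain on synthetic data with
known ground truth, and points the same code at user-supplied stimuli and
choice tables.

## What it computes

- **Synthetic study conditions** — morph sequences of parametric
  cat-like/dog-like shapes with controllable within-sequence pixel
  colinearity (`generate_morph_stimuli()`); simulated observers with a
  logistic psychometric curve plus reliable per-image idiosyncrasies
  (`simulate_observer()`); simulated electrodes as noisy linear mixtures of
  a known encoder layer (`simulate_electrodes()`); odd-one-out pools
  (`generate_oddity_pool()`, `synthetic_object_features()`).
- **Encoders** — ImageNet-style preprocessing (224×224, channel
  normalization), a seeded ten-layer random-weight convolutional encoder,
  a flattened-pixel baseline, and a pluggable `image_encoder()` contract.
- **Neural fits** — cross-validated ridge maps from each encoder layer to
  electrode responses (`fit_electrode_map()`, `fit_layers()`), split-half
  noise ceilings with Spearman–Brown correction
  (`estimate_reliability()`, `noise_correct()`), early-vs-late layer
  contrasts and peak-layer selection. For electrodes generated from layer
  *k*, the pipeline recovers *k* as the peak layer with median
  noise-corrected fit ≈ 1.
- **Category readout** — L2 logistic regression on layer features
  (`C` chosen by inner 5-fold CV over `10^-5..10^5`), evaluated over 100
  random stratified 4/5–1/5 splits (`evaluate_random_splits()`) and under
  the conservative leave-one-morph-sequence-out control
  (`evaluate_sequence_holdout()`), with morph-level aggregation
  (`aggregate_morph_level()`).
- **Pseudo-oddity performance** — leave-one-out pseudo experiments: for
  each held-out three-image trial, 52 training trials are built from the
  remaining views of the same two objects, a multinomial ridge classifier
  predicts the odd slot, and outcomes are averaged over 100 draws and
  aggregated to object level (`estimate_trial_outcome()`,
  `aggregate_objects()`, `compare_performance_vectors()`).
- **Consistency** — within-subject split-half reliability and
  equally-powered between-subject consistency as distributions of squared
  Pearson fits over 100 random splits (`split_half_reliability()`,
  `between_subject_consistency()`), model-to-behavior regressions
  (`fit_model_to_behavior()`), group comparison (`compare_groups()`), and
  the empirical-percentile "subject-likeness" test
  (`empirical_percentile()`).
- **Pipeline** — `run_synthetic_study()` runs everything end-to-end into a
  run directory (PNG/CSV/YAML/JSON artifacts, per-stage seeds, byte-stable
  `summary.json`); `replicate_study()` runs the stages on local copies of
  downloaded stimuli/behavior and degrades gracefully when only part of
  the data is present. A thin CLI lives at `inst/cli/vvsreadout.R`.

## Worked example

```r
library(vvsreadout)

stimuli <- generate_morph_stimuli(n_sequences = 7, n_levels = 11,
                                  image_size = 64, colinearity = 0.9, seed = 1)
encoder <- random_cnn_encoder(seed = 7)
features <- extract_features(encoder, stimuli, "fc7")

readout <- evaluate_random_splits(features, stimuli,
                                  readout_config(n_iterations = 20, seed = 3))
readout
#> <readout_result [random]> 20 iterations, held-out accuracy 0.960 (extreme levels 1.000)
head(readout$curve, 3)
#>   morph_level_pct prop_dog sd
#> 1               0        0  0
#> 2              10        0  0
#> 3              20        0  0
```

Held-out accuracy at the unambiguous extreme morph levels is 1.0, and the
proportion of "dog" predictions rises monotonically along the morph
continuum — the encoder readout behaves like a psychometric observer. The
pixel baseline shows the colinearity control: under random splits it
reaches extreme-level accuracy ≈ 0.99, but when whole morph sequences are
held out it collapses to ≈ 0.57, while the encoder readout is unaffected:

```r
pixels <- flatten_pixels(stimuli, resize_to = 32)
evaluate_sequence_holdout(pixels, stimuli)$summary$accuracy_extreme_levels
#> [1] 0.5714286
evaluate_sequence_holdout(features, stimuli)$summary$accuracy_extreme_levels
#> [1] 1
```

A full synthetic study (stimuli → features → observers → readouts →
consistency → summary) is one call:

```r
run_synthetic_study(default_run_config(master_seed = 1), "runs/demo")
```

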