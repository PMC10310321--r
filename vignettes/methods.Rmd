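---
title: "Methods: linear readouts of a VVS proxy versus choice behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear readouts of a VVS proxy versus choice behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package operationalizes

A recurring problem in the lesion literature on medial temporal lobe
function is deciding whether a visual discrimination task *requires*
processing beyond the ventral visual stream (VVS). The operational test
implemented here is: estimate the performance attainable by a **linear
readout of a layer-indexed image encoder** (a stimulus-computable proxy for
high-level visual cortex) and compare it with observed choice behavior. If
a linear readout of the proxy reproduces subjects' performance, the task is
not diagnostic of extra-VVS (e.g. perirhinal) involvement; only
supra-readout performance can be.

`vvsreadout` implements the full analysis chain on synthetic data with
known ground truth: stimulus and observer simulation, encoder feature
extraction, electrode-to-layer encoding fits with noise correction,
category readouts under two split regimes, pseudo-oddity performance
estimation, and split-half consistency statistics. Every stage also
accepts user-supplied (downloaded) stimuli and choice tables through
`replicate_study()`; nothing is downloaded by the package itself.

## Synthetic morph stimuli

`generate_morph_stimuli()` renders discrete "cat"-to-"dog" morph sequences
as star-blob contours on textured backgrounds:

* The **cat family** is a large, smooth, mostly 3-lobed blob with an
  unstructured interior; the **dog family** is a spiky 7-lobed star with a
  striped interior. Morph level `p` (an integer percentage, 0–100)
  linearly blends the boundary amplitudes and the stripe contrast with
  weight `p/100`.
* Per-sequence parameters (lobe phases, stripe orientation and phase,
  position, size, background texture) are drawn once per sequence, so each
  sequence is one specific interpolation path, as in a morphed stimulus
  set with several source exemplars.
* Foreground **area is analytically matched** across the morph continuum
  (the base radius is scaled by `1/sqrt(1 + (a3^2 + a7^2)/2)`), and the
  foreground base intensity (0.58) is chosen so the strongest stripes
  never clip at the display range. Both choices remove global luminance
  cues: without them a linear pixel readout could classify across
  sequences from mean intensity alone, which would defeat the purpose of
  the pixel-baseline control.
* `colinearity` in [0, 1] sets the fraction of background texture and
  position shared across levels *within* a sequence. At the default 0.9,
  images within a sequence are strongly linearly related in pixel space
  (measured within-sequence pixel correlation ≈ 0.84 versus ≈ 0.28
  between sequences at the default rendering), which is the property that
  lets a flattened-pixel readout succeed under random train/test splits
  while failing under a morph-sequence holdout.

The category rule is label 1 ("dog") iff `morph_level_pct > 50`, 0 below;
exactly-50 images get an explicit label alternating across sequences,
because no reward rule at the midpoint is defined — the alternation keeps
the 50% images from biasing either class.

Defaults (7 sequences A–G, 11 levels 0–100, 64 px) give 77 images per
experiment and support the conservative holdout in which six sequences
train the readout and the seventh tests it. What the generator does *not* emulate: photorealistic animal
morphs, 3-D pose, or learned category structure. Passing tests on these
stimuli show that the *pipeline* behaves correctly (recovers known signal,
respects chance levels, exposes colinearity), not that any particular
encoder matches biology.

## Simulated observers

`simulate_observer()` draws Bernoulli responses with

    P(dog) = lapse/2 + (1 - lapse) * plogis(slope * (level - bias) + offset_image)

where `offset_image ~ N(0, image_effect_sd)` is drawn once per image per
observer on the logit scale. The offsets create *reliable image-level
idiosyncrasy* — the quantity the split-half analyses measure — while
binomial trial noise limits it. Reliability-recovery checks use slope-0
observers: a psychometric slope injects morph-level signal that is common
to all `image_effect_sd` conditions and masks the image-specific variance
the estimator is supposed to recover, so the slope is silenced where that
variance is the object of study. Offsets are resampled per observer, so
between-subject image-level consistency arises only through the shared
stimulus, matching the logic of a between-subject analysis.

Defaults: slope 0.12 per morph point, bias 50, lapse 0.02,
`image_effect_sd` 1, 10 repetitions per image (the repetition count of the
experiment with the richest data; image-level consistency analyses refuse
fewer than 8 repetitions by default, mirroring the exclusion of
experiments with insufficient repetitions). The two simulated groups
("intact", "lesioned") share identical parameters by default, emulating a
scenario in which the lesion leaves choice behavior unchanged.

## Encoders

`preprocess_image()` bilinearly resizes to 224×224 and normalizes channels
by the canonical ImageNet mean/SD. `random_cnn_encoder()` is a ten-layer
fixed-random-weight network (three conv + ReLU + max-pool blocks, seven
fully connected ReLU layers, He-scaled weights). Random-weight networks
keep the architectural priors — local rectified filtering and pooling —
that make convolutional features sensitive to contour and texture
*energy*, which is exactly the family-level signal in the synthetic
stimuli; they ship with the package, need no downloads, and behave
identically in the pipeline to any encoder satisfying the
`image_encoder()` contract (a pretrained adapter can be plugged in where
available). Convolutional maps are average-pooled to at most 7×7 before
flattening, keeping layer feature dimensions in the hundreds.

"First half of layers" for early/late contrasts means the first
`floor(L/2)` layers of the declared order; with the ten bundled layers the
contrast has 8 degrees of freedom.

The pixel baseline (`flatten_pixels()`) optionally resizes (default
analysis: 32 px → 3072-d) before flattening; resizing controls the
dimensionality of an otherwise 12k-dimensional logistic problem without
affecting the colinearity phenomenon, because the sequence-identity cues
are low-frequency.

## Neural fits and noise correction

`fit_electrode_map()` learns ridge maps from a layer's features to
repetition-averaged electrode responses under 5-fold cross-validation with
the penalty chosen per electrode by an inner 5-fold search
(`lambda` grid `10^(-4..4)`, correlation of concatenated inner held-out
predictions; ties to the stronger penalty). The solution is computed from
one SVD of the training design per fold, shared across electrodes and
penalties — this is what makes 10-layer × 16-electrode × 20-run sweeps
cheap — and the evaluation is the Pearson correlation of concatenated
out-of-fold predictions (fewer degenerate small-fold correlations than
per-fold averaging).

The noise ceiling is the Spearman–Brown-corrected mean split-half
correlation over 100 random repetition splits (`estimate_reliability()`),
and `noise_correct()` divides raw correlations by its square root.
Electrodes with reliability at or below 0.1 are excluded rather than
corrected (dividing by a vanishing ceiling explodes the estimate);
corrected values above 1 are flagged, never clipped.

`simulate_electrodes()` draws mixing weights isotropically in the
generating layer's *whitened top-8 principal subspace* rather than i.i.d.
over raw features. Raw i.i.d. mixtures load almost entirely on the few
top principal components, which neighboring layers share, making the
generating layer unidentifiable; fully whitened mixtures put equal weight
on near-null-variance directions no regression could learn from a few
hundred images. The top-8 compromise yields electrodes that are both
learnable and layer-identifying. Signals are z-scored across images so
`noise_sd` is a noise-to-signal ratio with a closed-form reliability
`1 / (1 + noise_sd^2 / n_reps)` for the `n_reps`-repetition mean.

The layer-recovery fixture uses a *diverse object pool*
(`generate_oddity_pool(24, 8)`, 192 images) rather than morph stimuli:
morph sets are too low-dimensional to discriminate layers (measured
cross-layer fits all ≈ 0.9), and encoding-model fits are conventionally
estimated on rich stimulus sets separate from the behavioral task. At
`noise_sd = sqrt(8 * (1/0.7 - 1))` (reliability 0.70 for the 8-repetition
mean) the fc5-generated electrode sets are assigned peak layer fc5 in
20/20 calibration runs with median noise-corrected fits ≈ 0.91–0.95.

## Category readout

`train_readout()` is an L2-penalized logistic regression (glmnet ridge,
unstandardized features, matching the sklearn-style parameterization
`lambda = 1/(n * C)`), with `C` chosen from nine log-spaced values
`10^-5..10^5` (symmetric decades around 1, the standard search range) by
stratified inner 5-fold cross-validation (misclassification loss) on
training data only. Ties at predicted probability exactly 0.5 go to
"dog".

`evaluate_random_splits()` repeats 100 stratified-by-morph-level 4/5–1/5
splits (randomized rounding keeps the expected train fraction exact for
stratum sizes not divisible by 5; whether the original splits were
stratified is unstated, so unstratified splits are available via
`stratify = FALSE`). Held-out predictions only are recorded; if an image
is never held out, extra splits are drawn with a logged message.
`evaluate_sequence_holdout()` is the conservative control: leave one morph
sequence out, train on the rest — the held-out sequence shares no
background, position, or texture phase with training.

## Pseudo-oddity protocol

For a held-out sample trial (two views of object *i*, one view of object
*j*), `build_pseudo_experiments()` draws 52 training trials from the
pool's remaining views of the same two objects, excluding the sample's
three images. **Object roles are preserved** (pair = *i*, oddity = *j*)
while viewpoints, backgrounds and the oddity's slot are randomized. The
roles must be preserved for the protocol to work at all: a linear slot
score can implement "slot *k* holds object *j*" but not the role-symmetric
relation "slot *k* differs from the other two", whose discriminant flips
sign between role assignments — with balanced roles a linear classifier
stays at 1/3 chance at any feature separation (we verified this
empirically before fixing the roles).

Each trial is encoded as its three concatenated slot-feature blocks; a
multinomial ridge classifier over the three slots at fixed `C = 1`
predicts the sample's oddity slot; the prediction is binarized and
averaged over 100 pseudo-experiment draws (`n_pseudo`, reduced to 20 in
the test suite). Object-level performance averages a pair object's
outcomes over all oddity partners. The same entry point serves encoder
features, pixels, or simulated population responses — substituting the
representation changes numbers, never code paths.

## Consistency statistics

`split_half_reliability()` splits each item's trials (items = images or
morph levels) into two random halves per iteration — odd counts assign the
extra trial to a random half — and takes the squared Pearson correlation
between the two per-item half-mean vectors; 100 iterations give a
distribution of fits. `between_subject_consistency()` draws one random
half from *each* subject per iteration, so within- and between-subject
measures are equally powered and between-subject agreement is a
distribution rather than a single, optimistically-pooled point estimate.
The two subjects' splits are drawn from a shared per-iteration seed, which
is inert for distinct subjects but makes the protocol reduce *exactly* to
the within-subject one when both tables hold identical data (with
independent splits the two halves would overlap in trials and inflate the
agreement).
The squared Pearson correlation is the headline fit metric for these
distributions; model-to-behavior comparisons use an OLS regression
(`fit_model_to_behavior()`) reporting slope, t on n−2 df, and R².

`empirical_percentile()` locates a model-to-behavior fit within a
between-subject reference distribution (fraction of reference values at or
below the fit; median over model iterations when several are supplied).
Calibration holds when the reference pools split-half values across
*several* subject pairs: a single-pair reference varies only over trial
splits, while a fresh matched-process model also varies over the
subject realization, inflating the extremes. With a reference pooled over
three subject pairs and a fourth left-out subject playing the model, the
percentile is uniform on [0, 1] across simulations (KS check in the test
suite).

`compare_groups()` regresses the two groups' stacked per-(experiment,
level) proportions on a group indicator — df (1, 2n−2) — so equivalent
groups give slope ≈ 0 and R² ≈ 0, the "no group difference" signature.

## Numerical and design choices

* All randomness flows through `substream_seed()` (a string hash into
  31-bit seeds), so adding electrodes, subjects or images never perturbs
  other units' draws, and any stage can be re-run in isolation from its
  logged seed.
* Ridge features are centered and variance-scaled with training-set
  statistics (SD floor 1e-8 for constant columns); SVD components below
  `1e-10` of the largest singular value are dropped.
* Degenerate cases: constant held-out responses give `NA` fits excluded
  from medians; single-class training sets, empty electrode sets, missing
  feature rows and disjoint item sets raise classed errors
  (`vvsreadout_invalid_argument`, `vvsreadout_missing_data`).
* Peak-layer ties break toward the earlier layer; penalty ties toward the
  stronger penalty.
* Test-suite problem sizes: the canonical 7×11 morph set for readout
  properties; a 4×10 (40-image) set for reliability properties; the
  24-object × 8-view pool for layer recovery; 20 seeded runs for recovery
  and monotonicity properties; `n_pseudo = 20` for oddity checks; 200
  simulations for percentile calibration.

## Limitations

* A random-weight encoder is a proxy for the *pipeline contract*, not for
  the primate VVS; none of the published numerical results on macaque
  recordings are reproduced here, because they require the deposited
  stimuli, behavioral tables, prior electrophysiology and a pretrained
  encoder. `replicate_study()` documents the expected local layout for
  users who have downloaded them.
* The synthetic observers have no learning, sequence effects, or lapses
  correlated with difficulty; their image-level idiosyncrasy is Gaussian
  on the logit scale by construction.
* Noise-corrected fits can exceed 1 at low reliability; the reliability
  floor (0.1) bounds but does not remove this distortion.
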