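---
title: "Methods: multimodal gait-speed classification and its explanation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal gait-speed classification and its explanation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gaitxai)
```

This vignette is the package's own account of what it computes and why:
the data model the synthetic generator emulates, the classifiers and
their training protocol, the relevance-propagation and perturbation
machinery, the numerical conventions, and the design decisions taken
where several defensible options existed.

## 1. The data model

A gait trial is a synchronized multimodal recording of a short walk
(two gait cycles, one left and one right). Four modalities are carried
per trial, with fixed zero-padded shapes:

| modality | rate | frames | channels | content |
|---|---|---|---|---|
| `markers` | 100 Hz | 585 | 156 | 3D positions (mm) of 52 reflective skin markers, marker-major x/y/z |
| `grf` | 1500 Hz source, stored on the 585-frame grid | 585 | 24 | per-plate 3D force (N), moment (N·m) and centre of pressure (mm), plus both-plate sums |
| `emg` | 1500 Hz | 8985 | 8 | surface EMG envelopes (mV) from eight electrodes on the right leg |
| `fm` | 1500 Hz | 8985 | 12 | per-foot forces and moments on the plate |

Channel `3(m-1)+d` of the marker tensor is coordinate `d` (x, y, z) of
marker `m` in the 52-marker registry (`marker_registry()`); this
bijection is what lets channel-level relevance be summed back onto
anatomical landmarks. Trials end before the padded length: walking
slowly stretches the two cycles, so `true_length` shrinks as speed
grows, and all frames past it are exactly zero.

## 2. What the synthetic generator emulates — and what it does not

`generate_cohort()` exists so that every downstream stage (splits,
training, LRP, MoRF) is testable against a known ground truth without
any external download. It emulates the *statistical structure* the
analysis relies on, not biomechanical reality:

* **Speed classes.** Four classes: very slow (0–0.4 m/s), slow
  (0.4–0.8), moderate/self-selected (0.8–1.2) and fast preferred. The
  recording protocol distinguishes "moderate" and "self-selected", but
  both fall in the same band and are classified as one class, so the
  generator emits four classes. The fast band has no printed upper
  bound; the default (1.2, 1.8] m/s is configurable
  (`speed_classes(fast_range=)`).
* **Kinematics.** Each marker channel is a sinusoid at the stride
  frequency `f = 0.5 + 0.5·v` Hz (walking speed `v` drawn uniformly
  from the class band) on a fixed per-channel offset, with Gaussian
  noise (default sd 2 mm against base amplitudes of 15–25 mm). The
  linear cadence law is a deliberate simplification: it makes stride
  frequency — and hence trial length — monotone in speed, which is the
  dominant real-world cue.
* **Subject random effects.** Each subject draws once a stature scale
  (sd 0.05), an amplitude scale (sd 0.10), a global phase offset and a
  cadence offset (sd 0.08 Hz). The cadence offset makes adjacent
  classes overlap in trial length, so length alone does not separate
  the classes; the effects are what make subject-wise splitting a
  genuinely harder protocol on synthetic data, mirroring real
  subject-identity leakage.
* **Planted discriminative channels.** Trials of class `c` multiply the
  sinusoid amplitude of a class-specific marker-channel group by 2.0
  (configurable): right shoulder-girdle markers (R_SIA, R_SRS, R_SAA)
  for class 0, their left counterparts for class 1, left
  calcaneus/metatarsal markers for class 2, and the four malleoli for
  class 3 — upper-body markers for slow gait, distal leg markers for
  fast gait. Because standardization is per channel over the pooled
  training set, the boost survives preprocessing as a class-conditional
  variance signature. These groups are the recoverable ground truth
  that the explanation tests check against.
* **Kinetics and EMG.** Vertical GRF is the classic double-hump stance
  shape with peak ∝ (1 + 0.2·v); shear components and moments are
  scaled versions; the centre of pressure ramps heel-to-toe during
  stance. EMG channels are rectified-Gaussian bursts phase-locked to
  the cycle whose duty cycle decreases with speed
  (`0.45 − 0.15·v`, floored at 0.12). F&M channels are lever-arm-scaled
  transforms of the same stance shapes on the high-rate grid.

Not emulated: joint-angle coupling, inter-marker rigid-body
constraints, realistic EMG spectra, force-plate crosstalk, missing
markers, soft-tissue artefact. Consequently a passing test suite shows
that the *pipeline* is correct and that explanations recover planted
structure — it does not certify classification accuracy on real
recordings.

All draws derive from one cohort seed; per-trial sub-seeds are mixed
deterministically, so a cohort is bit-identical under the same seed.

## 3. Preprocessing and split protocols

Standardization is per channel to zero mean and unit variance, with the
statistics computed **on the training partition only** and over
**unpadded frames only**, then applied to all partitions
(`standardize_trials()`). Padding zeros are left untouched, so padding
never biases channel statistics and remains recognisable to the models.
Constant channels map to zero through an ε-guard (1e-8) on the
denominator.

Three protocols are provided. Experiment 1 is sample-wise stratified
10-fold cross-validation; fold assignment rotates the per-class deal so
fold sizes stay balanced, and a validation slice is carved from each
fold's training portion for early stopping. Its size is not fixed by
the protocol description; the default is 10%, stratified. Experiments 2
and 3 are subject-wise k-fold CV with 5 and 10 test subjects per fold.
One description of Experiment 2 calls it 10-fold while the methods text
says 5-fold; `k` is therefore a knob, defaulting to 5. Whether fold
test sets may overlap across folds is equally ambiguous; the default
draws disjoint sets (so Experiment 3 with 50 subjects partitions them
exactly), with `disjoint = FALSE` available. One seed fixes a whole
plan; per-fold shuffles are derived sub-streams.

## 4. Models and training

The network engine is written in-package (base R on BLAS matrix
primitives) because relevance propagation needs every layer's inputs,
pre-activations and pooling switches anyway; each layer's backward pass
is hand-derived and verified against central finite differences in the
test suite (tolerance 1e-6 on random configurations).

**Multi-stream CNNs.** `single_cnn`/`dual_cnn`/`quads_cnn` run one
convolutional encoder per modality — default 3 blocks of 32/64/96
filters, kernel 7 along time, stride 2, ReLU — followed by global
average pooling and a dense embedding (128) per stream. Streams are
fused at feature level by concatenating embeddings (the fusion operator
is not dictated beyond "feature level"; concatenation is the
convention, and sum/attention variants are out of scope), then an MLP
head with softmax. Streams repeating a modality share encoder weights.
`fusion_cnn` is the same topology with a deeper fusion head (256/128).
The different stream lengths (585 vs 8985) are never resampled against
each other; each encoder handles its own rate.

Two stated defaults were deliberately changed, as package design
choices. First, **no batch normalization** inside the conv blocks:
inputs are already standardized per channel, the networks are shallow
enough to train stably without it, and batch norm would have to be
folded into adjacent convolutions for LRP — complexity without benefit
at this scale. Second, **dropout 0.3** is the default but the
scaled-down reference configuration sets it to 0 (small cohorts, short
training budgets).

**Hybrid CNN+LSTM.** Each stream's convolutional features are pooled
onto a common temporal grid (adaptive average pooling to 32 steps —
needed because the streams' conv outputs have unequal lengths),
concatenated channel-wise, passed through a single LSTM (hidden 128,
last-state readout) and an MLP softmax head.

**TCN.** Four dilated causal convolution blocks with 12/24/48/96
filters (dilations 1/2/4/8, kernel 5), ReLU and dropout, flattened into
a dense layer of 100 units.

**GRU.** Three stacked bidirectional GRUs of 128/256/256 units (the
last returns the concatenated forward-last/backward-last state), then
dense layers of 512/256/128.

**Transformer.** A kernel-1 convolution projects channels to the model
width (default 64), then encoder blocks (default 2) of 4-head
self-attention and a feed-forward layer, each with residual connection
and layer normalization, then global average pooling and a dense head.

**Baselines.** LDA/QDA (MASS) and a radial SVM (e1071) on flattened
single-modality vectors. Flattened gait tensors have far more features
than trials, so the covariance estimates are singular; the documented
remedies are temporal block-averaging before flattening
(`flatten_trials(decimate=)`), an optional PCA projection in
`cross_validate()` (default 50 components, fitted on the training
fold), and a shrinkage discriminant fallback
(`fit_baseline(regularize=)`, covariance shrunk toward a scaled
identity).

**Training.** Adam (learning rate 1e-3, batch 32 — unstated in the
protocol, standard values chosen), categorical cross-entropy, at most
1000 epochs, early stopping on validation loss with patience 20 and
best-weight restoration. Weight init is Glorot-uniform under a build
seed; shuffling and dropout run under the training seed, so a (build
seed, train seed) pair reproduces a run exactly. A NaN loss aborts with
a "diverged" error rather than silently continuing.

**Temporal decimation.** Scaled-down analyses block-average the time
axis while stacking inputs (`stack_inputs(decimate=)` with
`decimated_shapes()`); the model then consumes — and its explanations
live on — the decimated grid. Defaults remain the raw shapes.

## 5. Relevance propagation

`forward_trace()` snapshots, per layer, the inputs, pre-activations
`z_k = Σ_j a_j ω_jk + b_k`, weights and pooling switches of a
single-sample forward pass (softmax removed; the trace ends at the
logits). `lrp_backward()` initializes relevance as the chosen class's
logit — all other classes excluded — and redistributes it backwards:

* **ε-rule** (default stabilizer 1e-7): `R_j = Σ_k a_j ω_jk /
  (z_k + ε·sign(z_k)) · R_k`; the **z-rule** is ε = 0 with a
  zero-denominator guard (such terms contribute nothing).
* **α/β-rule** (default α = 2, β = 1; `rule_config()` enforces
  α − β = 1): positive and negative contributions are pooled separately
  per unit and weighted α and −β. Conservation is exact on bias-free
  layers *whose units see both signed pools*; a unit with an empty
  negative pool redistributes α·R rather than R, which is a property of
  the rule itself, not of this implementation. Test fixtures therefore
  use wide layers where empty pools are practically impossible.
* **flat rule:** incoming relevance is spread uniformly over all
  contributing inputs of each unit.
* **sequential preset A flat:** the composite named after the analyzer
  configuration it reproduces: ε on dense layers, α1β0 on convolution
  layers, flat on the input layer. The name is under-specified in
  common usage; this is the conventional reading, adopted explicitly.

Pooling layers unpool as follows: max pooling routes relevance to the
recorded argmax (winner-take-all); average/adaptive pooling spreads it
uniformly within each window (conserving and numerically stable on
signed inputs); global average pooling redistributes proportionally to
the pooled activations (which are post-ReLU, hence non-negative, in
every built architecture). **Biases absorb their own relevance share**
— the propagation is silent about them otherwise — so strict
conservation `Σ R = f_c(x)` holds for bias-free networks; the
conservation tests use `bias = FALSE` fixtures and require agreement
within 1e-4 relative (measured: ~1e-16). Deep-Taylor variants are not
implemented separately: for ReLU networks they coincide with α1β0.
Attention and bidirectional-GRU models are rejected by the tracer with
an explicit unsupported-architecture error; the CNN+LSTM is traceable
but relevance cannot pass its recurrent gates.

Gradient-family baselines (`baseline_analyzer()`): raw input, the
logit gradient (checked against finite differences), guided
backpropagation (negative gradients zeroed where the forward ReLU was
inactive or the gradient negative) and deconvnet (negative gradients
zeroed regardless of forward sign).

## 6. Relevance aggregation

`explain_class()` implements the aggregation protocol for one class:
only samples *correctly classified* as that class enter; each map is
normalized by its own maximum absolute value (signs kept — "normalize
to the respective maximum" is read as max-|·|); maps are averaged
element-wise; non-finite values are clipped with a log, and a map of
zeros yields a warning rather than an error (the degenerate-input
convention). The average is smoothed along time: each pass convolves
with (¼, ½, ¼), and at the boundary the out-of-range weight is folded
onto the edge sample so each output's weights still total 1 — this
choice keeps every pass exactly mass-preserving (tested to 1e-10) and
non-expansive in the maximum. Three passes approximate a Gaussian.
Finally the profile is min-max rescaled to [0, 1], ranked (ties broken
by ascending variable index) and the top 200 variables retained.
Channel-marginal scores (|relevance| summed over time) feed
`map_to_markers()`, which collapses x/y/z channels onto their markers.

## 7. Perturbation and AOPC

`morf_order()` tiles the time×channel grid with non-overlapping 7×7
windows (the image-domain 7×7 neighbourhood adapted to time series as 7
timesteps × 7 channels; a channel span wider than a narrow modality —
EMG has 8 channels — clamps to the full width, while a time span longer
than the input is an error). Per-tile heat is summed relevance; ties
order by time then channel. `perturb_step()` replaces a tile's values
with uniform draws over each channel's observed range *in the
unperturbed sample* — bounds are unstated in the protocol; per-channel
empirical min/max keeps replacements marginally in-distribution.
`morf_curve()` applies the recursion x₀ = x, xₖ = g(xₖ₋₁, rₖ) for L
steps, recording the class logit (softmax removed), and

AOPC = 1/(L+1) · Σ_{k=0..L} (f(x₀) − f(xₖ)),

with k = 0 contributing zero (the printed summation bound is ambiguous;
k = 0…L matches the 1/(L+1) normalizer). `compare_analyzers()` shares
the replacement-noise stream across analyzers per sample, so AOPC
differences are paired; `"random"` is the random-ordering control, and
`direction = "keep_top"` gives the complementary curve that removes the
least relevant tiles first. Both the tracked logit and the
accuracy-vs-step curve are returned, since either may be the quantity
of interest.

## 8. Statistics

Macro averaging is used for precision/recall/F1 (one F1 per model/fold;
the averaging scheme is a documented choice). A never-predicted class
contributes precision 0 with a warning. MCC uses the Gorodkin
multiclass generalization; degenerate tables return NaN with a warning.
One-vs-rest AUC is computed by the rank (Mann–Whitney) formulation,
identical to trapezoidal integration, and cross-checked against pROC in
the tests. Model-to-model comparisons pair per-fold F1 values — folds
are the only replication unit with n > 1 — through the paired t-test
t = X̄_d/(s_d/√n) with the sample sd and a two-sided p from the t
distribution on n−1 df (sidedness is unstated; two-sided is assumed).
Identical vectors give t = 0, p = 1; a nonzero mean difference with
zero spread gives a flagged infinite t. No multiple-testing correction
is applied by default, matching the unadjusted protocol; Holm is
available. Under a simulated null the empirical type-I error at α=0.05
sits in the tested [0.01, 0.12] band.

## 9. Orchestration, problem sizes and reproducibility

`run_experiment()` chains simulate → split → per-model cross-validation
→ pairwise t-tests → relevance aggregation for the best model → analyzer
comparison, freezing the configuration and every intermediate table
(CSV/JSON) under the run directory. The best model for the explanation
stage is the network with the highest mean test F1, ties broken by
lower sd; classical baselines are not eligible since they cannot be
traced. The exported functions and this vignette are the package's
interface; there is no shell entry point beyond
`scripts/acceptance.R`.

The reference analysis (tests and the acceptance script) runs at a
desk scale chosen once: a 200-trial cohort (50 subjects × 4 classes ×
1 trial), inputs decimated ×8 (low-rate) and ×64 (high-rate), a
four-stream CNN with 8/16 filters, kernel 5, stride 2, embedding 16,
head 32, no dropout, trained up to 60 epochs with patience 20. These
sizes keep a full 10-fold cross-validation plus the explanation stage
in the single-digit minutes on one CPU while leaving the planted
structure clearly learnable; all of them are ordinary arguments, and
nothing in the package depends on these particular values.

Every stochastic component — cohort synthesis, fold shuffling, weight
initialisation, dropout, perturbation noise — derives from explicit
integer seeds through a deterministic mixing function, and library code
restores the caller's RNG state.

## 10. Known limitations

* The synthetic cohort's simplicity means headline classification
  scores on it say nothing quantitative about real gait datasets; only
  orderings and protocol behaviour transfer.
* LRP does not traverse attention or recurrent gates; the Transformer
  and GRU families are benchmark-only, and the CNN+LSTM is explained
  only up to its recurrent readout.
* α/β conservation degrades on units with an empty signed pool (a
  property of the rule); the z-rule is the conservation reference.
* The pure-R engine favours transparency over speed: it is comfortable
  at the reference scale but not intended for full-resolution,
  1000-epoch training runs.
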