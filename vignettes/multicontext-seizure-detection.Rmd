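---
title: "Multi-context wavelet feature fusion for EEG seizure detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-context wavelet feature fusion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctxseize)
```

# The model

Epileptic seizures show up in scalp EEG as increased amplitudes and changed
frequency content. `ctxseize` detects them at the granularity of short
fragments: every record is cut by a sliding window (3 s long, 1 s step), each
fragment channel is turned into a Morlet continuous-wavelet scalogram
`|CWT(a, τ)|²`, and three unsupervised views of those scalograms are fused
into one feature vector per fragment for an SVM classifier.

1. **Global view.** The per-channel scalogram vectors of a fragment are
   concatenated and projected onto the top-*k* principal components fitted
   over the training fold (`fit_gpca()`), which strips redundant
   inter-channel variation.
2. **Channel-wise view.** Each channel has its own 2-layer stacked denoising
   autoencoder (`train_sdae()`). A layer encodes a masked copy of its input
   through a sigmoid hidden layer and is trained to reconstruct the clean
   input under cross-entropy loss; layers are trained greedily, each on the
   clean hidden codes of the previous one, with earlier layers frozen. The
   last hidden layers of all channels are concatenated.
3. **Temporal view.** The last SDAE layer doubles as a dictionary of basic
   scalogram patterns: a fragment is *translated* to the EEG word of its
   maximally activated unit (`translate_to_word()`), a record becomes an EEG
   sentence, and word embeddings are trained with a CBOW objective — predict
   the centre word from the average of the 2k surrounding word vectors —
   under hierarchical softmax on a Huffman tree built from word frequencies
   (`train_embeddings()`). A fragment's temporal feature is its own word's
   embedding, averaged over channels.

The blocks are concatenated in fixed order (global, channel-wise, temporal),
z-scored with training-fold statistics, and classified by an RBF SVM whose
cost and gamma are chosen by a small stratified 3-fold grid search inside
the training fold. Assumptions worth stating: fragments are treated as
exchangeable by the classifier (temporal structure enters only through the
embedding features); channels share one sampling rate; and the ictal class
is rare enough that class balancing by down-sampling is appropriate.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| window / step | 3 / 1 | s | standard fragment geometry for scalp EEG seizure work; 1 s step oversamples transitions |
| Morlet ω₀ | 6 | — | the usual time/frequency localisation trade-off; pseudo-frequency `f = ω₀ / (2πa)` |
| scales | 32, log-spaced, 1 Hz–Nyquist | — | covers delta through gamma with denser low-frequency resolution |
| pooling grid | 16 × 16 | — | keeps the SDAE input at n = 256, modest but structure-preserving |
| SDAE sizes | 80, 60 | units | compresses the 256-dim input enough to force abstraction; fewer units underfit the channel patterns, many more risk the curse of dimensionality |
| corruption | 0.3 masking | prob. | standard denoising level; 0 disables denoising, 1 destroys the input |
| embedding q | 20 | dims | large enough to separate ~60 patterns per channel, small enough to train on few sentences |
| context k | 2 | fragments | ±2 s of temporal context at the default step |
| train share | 0.8 | — | 4:1 hold-out, stratified and balanced |

# The synthetic data generator

`generate_record()` emulates exactly the two seizure signatures the method
exploits: pink (1/f) background noise per channel — so the CWT stage sees a
realistic spectral slope rather than flat white noise — and ictal intervals
in which the background is multiplied by `ictal_gain` (default 3) and a
7 Hz theta-band rhythm with per-channel random phase is superimposed. Under
random placement the default seizure rate (0.7 per record, Poisson) leaves
roughly half of the records seizure-free. Everything is seeded: the same
configuration reproduces a bitwise-identical record.

What it does **not** emulate: spike-wave morphology, inter-patient and
inter-channel variability, electrode artifacts (EMG, eye blinks, movement),
montage effects, and non-stationary background rhythms. Passing the
end-to-end tests on this generator therefore demonstrates that the pipeline
is correctly wired and can recover a known amplitude/frequency signature; it
does not certify clinical-grade performance on real corpora, where the
reported numbers are expected to be lower and patient-dependent.

The default experiment size used by the tests and the acceptance script —
24 records of 60 s at 256 Hz with 4 channels, trimmed to 200 balanced
fragments (100 per class, 160 train / 40 test) — was chosen as the smallest
configuration that exercises every stage with multi-channel data while
keeping a laptop-scale runtime.

# Numerical choices

* **Window arithmetic.** Window and step lengths convert to samples with
  `floor` (with a 1e-9 guard against representation error), so
  173.61 Hz × 3 s → 520 samples, reproducibly, and a 23.6 s Bonn-style
  record yields 21 fragments.
* **CWT discretisation.** The transform is the Riemann sum of the wavelet
  integral over the sampled record, zero outside its support, evaluated by
  FFT cross-correlation with kernels covering every lag — numerically
  identical (≤ 1e-6 relative, tested) to direct quadrature, with no wavelet
  truncation inside the record. The cone of influence is not masked.
* **Scalogram normalization.** Per-fragment min–max scaling to [0, 1],
  because the DAE uses sigmoid outputs under cross-entropy, which reads
  inputs as probabilities. A constant scalogram maps to the all-zero vector
  (with a warning) instead of dividing by zero.
* **Loss clamping.** Reconstructions at exactly 0/1 are clamped to
  `[1e-12, 1 − 1e-12]` before the log.
* **Initialisation.** SDAE weights are Glorot-style uniform (×4 for
  sigmoid), biases zero; embeddings uniform in `[−0.5/q, 0.5/q]`; Huffman
  node parameters zero — so the first CBOW pass moves only node parameters,
  and context vectors start moving from the second pass.
* **Tie-breaks.** Word translation takes the lowest index among tied
  activations; Huffman merges order nodes by (weight, smallest contained
  word id) and the lower-ranked child takes bit 0; `select_k` prefers the
  smallest k on ties. With tied frequencies some maximal-frequency word (not
  necessarily all of them) attains the minimal code length.
* **Interior context positions.** The CBOW objective sums over positions
  with a full window on both sides (`t − k ≥ 1` and `t + k ≤ T`); boundary
  positions are skipped, not errors.
* **Degenerate inputs.** Records shorter than the window yield an empty
  fragment sequence plus a warning; a single-word vocabulary gets an empty
  Huffman code with probability 1; zero-denominator metrics report 0 with a
  warning.

# Open design decisions and how they were settled

* **Ictal labelling rule.** Expert marks give seizure intervals, not
  fragment labels. Any positive overlap labels a fragment ictal — the most
  sensitive convention — configurable via `min_overlap_fraction`.
  Overlapping annotation intervals are merged first, making labelling
  order-invariant.
* **Corruption process.** Masking-to-zero noise with fraction 0.3, the
  standard denoising-autoencoder choice; decoder weights are untied from the
  encoder.
* **Per-channel dictionaries.** Words are per-channel (60 per channel), with
  global ids offset by channel (`global_word_id()`), so one embedding space
  covers all channels while preserving channel identity. Word ids are
  1-based, as is idiomatic in R.
* **Sentences and folds.** Feature extractors — PCA, SDAEs, and the
  embeddings — are fitted on the training fold only (the stricter reading of
  hold-out validation; the suite verifies no test-fold parameter leaks). EEG
  sentences are therefore built from training-fold fragments ordered within
  each record; contexts may bridge small gaps where test fragments were held
  out. A test fragment can consequently translate to a word unseen in
  training: `temporal_feature()` treats that as an error by default, while
  the pipeline substitutes a zero vector with a warning.
* **Model-selection protocol for k.** Exact leave-one-out is quadratic in
  the sample count, so `select_k()` defaults to stratified 5-fold
  cross-validation with a linear-SVM probe (LOO stays available via
  `protocol = "loo"`); k defaults to 10 when selection is skipped.
* **SVM settings.** Kernel and hyperparameters are not dictated by the
  method itself; the default is an RBF kernel with cost/gamma chosen on a
  3 × 3 grid by stratified 3-fold CV inside the training fold, linear kernel
  by flag. Hard labels use the SVM's default decision boundary; the curves
  use continuous decision scores oriented so larger means ictal.
* **Package shape.** The pipeline is exposed in the classic R modelling
  idiom — one fitting function, `ctxfusion()`, returning an S3 object with
  `print`, `summary`, `predict`, and `plot` methods — while every stage
  remains an exported function for use and testing in isolation.

# Known limitations

* The EDF reader supports the plain continuous 16-bit dialect with one
  common sampling rate; EDF+ annotations and mixed-rate signals are out of
  scope (seizure marks come from a TSV sidecar: `record_id`, `start_s`,
  `end_s`).
* Only the Morlet mother wavelet is implemented; Morse and Bump are
  recognised names that raise a clear unsupported error.
* Embedding training implements the averaging integration; concatenation is
  available for context inspection but not for training.
* Fragment-level detection only: no onset localisation, no streaming
  operation, no artifact rejection beyond what the CWT implicitly provides.
* Multi-channel temporal features average the per-channel word vectors; a
  learned cross-channel integration might do better but is not attempted.

```{r example, eval = FALSE}
records <- generate_dataset(synth_config(), n_records = 24, seed = 1)
fit <- ctxfusion(records, n_per_class = 100, seed = 1)
summary(fit)
plot(fit)
```
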