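# ctxseize

Automatic epileptic seizure detection from EEG recordings by **multi-context
feature fusion over wavelet scalograms**, for researchers in biomedical signal
processing and computational neurology who need a transparent, fully seeded
reference pipeline that runs end to end on commodity hardware.

## The method

Long-term EEG is segmented with a sliding window (3 s window, 1 s step) and
each fragment channel is mapped to a time–frequency power image, the
*scalogram*, via the continuous wavelet transform with a Morlet mother
wavelet Ψ:

```
scalogram_x(a, τ) = |CWT_x(a, τ)|²
                  = | a^(-1/2) ∫ x(t) Ψ*((t − τ)/a) dt |²
```

where the dilation `a` selects oscillatory frequency and the shift `τ`
position in time. Three unsupervised feature views are then extracted from
the scalogram vectors:

* **Global** — top-*k* principal components of the concatenated all-channel
  scalogram vectors (inter-channel redundancy removal);
* **Channel-wise** — per-channel 2-layer stacked denoising autoencoders
  (hidden sizes 80 and 60), trained greedily layer by layer on masked inputs
  with sigmoid activations and cross-entropy reconstruction loss
  `−Σ_k [x_k log y_k + (1 − x_k) log(1 − y_k)]`; the last hidden layers'
  activations are concatenated across channels;
* **Temporal** — each fragment is *translated* into an EEG word (the argmax
  unit of the last SDAE layer, a dictionary of basic scalogram patterns), a
  record becomes an EEG sentence, and 20-dimensional word embeddings
  `v_w ∈ R^q` are trained with a CBOW objective under hierarchical softmax
  on a frequency-built Huffman tree,
  `p(w_t | ctx(w_t)) = Π_j p(d_j | Intg(w_t), θ_{j−1})`.

The three blocks are concatenated, `x_Fusion = [x₁ ⊕ x₂ ⊕ x₃]`, z-scored
with training-fold statistics, and fed to an RBF-kernel SVM that separates
ictal from non-ictal fragments. Evaluation reports precision, recall, F1,
accuracy, and ROC/PR curves with trapezoidal AUCs on a balanced, stratified
4:1 hold-out split. All extractors are fitted on the training fold only.

## Worked example

The package includes a seeded generator of annotated synthetic EEG (pink
1/f background; seizures add an amplitude gain and a 7 Hz rhythm), so the
full pipeline runs without any data download:

```r
library(ctxseize)

records <- generate_dataset(synth_config(), n_records = 24, seed = 1)
fit <- ctxfusion(records, n_per_class = 100, seed = 1)
print(fit)
#> Multi-context wavelet-fusion seizure detector
#>   contexts: global + channelwise + temporal
#>   fused feature: 270 dims (global=10, channelwise=240, temporal=20)
#>   train/test fragments: 160 / 40 (seed 1)
#>   test F1 1.0000 | accuracy 1.0000 | AUC-ROC 1.0000 | AUC-PR 1.0000
```

The fused vector has 270 dimensions: 10 global principal-component scores,
4 channels × 60 SDAE code units, and a 20-dimensional EEG-word embedding.
On this synthetic dataset (strong, by-construction seizure signatures) the
held-out 40 test fragments are classified perfectly; single-context
ablations (`contexts = "global"` etc.) score slightly lower. Use
`plot(fit)` for the ROC/PR curves and `predict(fit, new_record)` to score
new data fragment by fragment.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/ctxseize.R synth --n-records 24 --seed 1 --out data/
Rscript inst/cli/ctxseize.R run --data data/ --fs 256 --seed 1 --out metrics.json
```

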