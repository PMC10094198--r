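---
title: "Multi-task ECG classification: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task ECG classification: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical 12-lead electrocardiograms are read as multi-label diagnoses:
one recording may carry several findings (an infarction and a conduction
disturbance, say), and the diagnostic vocabulary is organized
hierarchically — fine classes (right bundle branch block, ST-segment
elevation, ...) nest inside coarse superclasses (QRS-morphology
abnormalities, ST-segment changes, ...). `ecgmtnet` implements a
multi-task deep network that exploits that hierarchy: the *main* task
classifies records at one level of the taxonomy, while an *auxiliary*
task — constructed automatically from the same labels — classifies them
at the other level. Both tasks share one feature extractor (hard
parameter sharing), so gradients from the auxiliary task regularize the
representation the main task uses.

Two constructions cover the common corpora. When the corpus is labelled
at the fine level (nine CPSC2018-style arrhythmia classes), the
auxiliary task *merges* similar classes into five superclasses:
`derive_aux_labels()` maps each record's label set through the parent
map of a `label_hierarchy`, deduplicating (a record with both bundle
branch blocks gets the QRS superclass once). When the corpus is
labelled at the coarse level with a finer vocabulary available
(PTB-XL-style, five superclasses over 23 subclasses), the auxiliary
task *splits*: the subclass labels are reused as the auxiliary target.
Both built-in taxonomies ship with the package (`cpsc_hierarchy()`,
`ptbxl_hierarchy()`).

## Architecture

The shared trunk is a one-dimensional SE-ResNet: a stack of residual
blocks, each two convolutions (kernel 7) with batch normalization,
ReLU, dropout 0.2, and a squeeze-and-excitation module — global mean
pooling per channel followed by a two-layer bottleneck gate that
rescales channels by learned importance — before the residual addition.
Widths, strides and depth are configurable (`mtnet_config()`); the
full-scale default is four blocks of widths 64/128/128/256 with
stride-2 downsampling per block, chosen so a 60 s record at 250 Hz
reaches a sequence length a recurrent layer can consume.

On top of the trunk sits a Contextual Transformer (CoT) attention
block. Writing `E` for the trunk's output sequence, with `Q = E` and
`K = E` and a pointwise value embedding `V = EW`:

* `K1 = conv(K)` — a kernel-3 convolution along time gives each
  position a *static* local-context representation;
* `A = Wθ(relu(Wσ([K1, Q])))` — two successive pointwise convolutions
  of the channel-concatenation of `K1` and `Q` produce an attention
  map;
* `K2 = V ∗ A` — the elementwise product forms the *dynamic* context;
* `D = proj([K1, K2])` — the concatenation is projected back to the
  input width, so the block is drop-in.

Two readings of the original formulation were left open and are
resolved here as configuration: the attention product is a plain
elementwise multiplication (no softmax normalization — the printed
equations state a product, and the package follows them), and the value
embedding is pointwise. The original image-domain CoT applies a
local-grid softmax aggregation; that variant is deliberately not
implemented. A final design point: the published figure shows CoT and
the Bi-GRU *shared* by both tasks with only the fully connected heads
task-specific, while the accompanying text calls the whole
classification module task-specific. The default follows the figure;
`per_task_branch = TRUE` gives each task its own CoT+Bi-GRU branch for
the other reading.

The sequence is summarized by a bidirectional GRU: a forward pass over
`t = 1..T` and a backward pass over `t = T..1`, with the two final
hidden states concatenated into a `2 × gru_hidden` feature vector. The
gate convention is

    r = σ(xW_r + hU_r + b_r),  z = σ(xW_z + hU_z + b_z),
    n = tanh(xW_n + r ∗ (hU_n) + b_n),  h' = (1 − z) ∗ n + z ∗ h,

and the test suite pins it against a hand-unrolled oracle. Ablation
switches `use_cot = FALSE` and `use_bigru = FALSE` (the latter replaces
the GRU with global average pooling) reproduce the reduced variants;
both are exposed on the command line as `--no-cot` / `--no-bigru`.

Everything — convolutions (im2col), batch normalization, SE gating,
CoT, GRU back-propagation through time, Adam — is implemented in base
R. Analytic gradients of every block are verified against central
finite differences to ~1e-6 relative error in the test suite.

## Loss and training protocol

Both corpora are multi-label (the PTB-XL taxonomy carries 30,560 labels
over 21,837 records), so each head uses per-class sigmoid outputs and
the task losses are mean binary cross-entropies. They combine as

    L_total = λ · L_main + (1 − λ) · L_aux.

λ is not pinned down by the published protocol; the package defaults to
the symmetric λ = 0.5, requires it in the control object, and logs it
in every run artifact. λ = 1 provably zeroes the auxiliary-head
gradient (tested).

The optimizer is Adam with initial learning rate 5e-4, decayed by a
factor of 10 every 10 epochs (`lr_at_epoch()`), batch size 32, and
early stopping when the monitored loss has not improved for 10
consecutive epochs. Whether "loss" means training or validation loss
was left unstated; the package monitors *validation* joint loss and
restores the best epoch's weights, the conservative reading. Two
partition schemes are provided, since ten-fold cross-validation and the
curated benchmark partition are both part of the protocol:
`ptbxl_recommended` (fold tags 1–8 train, 9 validation, 10 test) and a
seeded `stratified_10fold`. No class re-weighting or oversampling is
applied.

Decision thresholds for count-based metrics are 0.5; AUC uses raw
scores. The zero-denominator convention for precision, recall and F1 is
0, which matters for rare classes. Per-class accuracy is the binarized
one-vs-rest accuracy `(TP+TN)/n` (subset accuracy is not what the
benchmark tables report).

## The synthetic-data generator

Real corpora cannot ship with the package, so every pipeline stage is
exercised on synthetic records (`synth_spec()`, `make_dataset()`).
Beats are sums of Gaussian bumps for the P, Q, R, S and T waves
(ECGSYN-style simplification), tiled with jittered RR intervals,
scaled per lead by a fixed gain pattern plus record-level gain noise,
with additive Gaussian noise. The default spec mirrors the acquisition
conventions of the real corpora: 12 leads, 500 Hz, 10 s, heart rate
60–100 bpm, 0.1 mV noise against a ~1 mV R peak, and 10% of records
carrying two labels from different superclasses. Per-class
label-assignment counts follow the frequency map exactly, so
configuring the generator with the published per-class counts
reproduces the corpus totals (6,877 CPSC records; 30,560 PTB-XL label
assignments).

Crucially, the coarse group imprints a shared morphology trait — the
property that makes the hierarchy informative, which the
random-grouping control experiment manipulates:

| group position | trait |
|---|---|
| 1 (normal) | baseline morphology |
| 2 (AF-like) | irregular RR intervals, suppressed P wave |
| 3 (QRS-like) | widened QRS complex |
| 4 (premature-beat-like) | interspersed early, wide, large beats |
| 5 (ST-like) | ST-segment offset; *sign* distinguishes the two members |

Fine classes perturb secondary features within the group (PR stretch,
deep S, a secondary R' bump, T-wave changes). What the generator does
*not* emulate: vectorcardiographically consistent lead geometry,
baseline wander, electrode artifacts, pathology-accurate waveforms, or
inter-patient variability beyond gain and heart rate. Passing tests on
this data show the *mechanism* works — the hierarchy carries signal and
the multi-task model can exploit it — not that published benchmark
accuracy would be reached on real recordings.

The difficulty dial is `noise_sd`, calibrated with a deliberately
simple nearest-centroid baseline on beat-averaged waveforms
(`centroid_baseline()`): at 0.02 mV it exceeds 0.9 macro F1, and it
decays toward chance as noise grows (tested at three levels).

## Desk-scale study conditions

Two package-level experiments echo the study's control and ablation
analyses at a size a laptop CPU handles in minutes
(`desk_conditions()`): ~600 label assignments over nine classes, 12
leads at 100 Hz for 3 s, a two-block trunk (16/32 channels), 16 GRU
units, ten epochs, batch 32. One deviation from the corpus-scale
protocol is deliberate: the initial learning rate is 5e-3 rather than
5e-4. A ten-epoch run on ~540 training records makes only ~190 Adam
updates; the published schedule is sized for tens of thousands, and at
5e-4 the sigmoid outputs of *any* variant stay below the 0.5 decision
threshold, making thresholded F1 comparisons vacuous. One decade up
restores meaningful convergence while keeping the schedule shape.

`mtl_benefit_experiment()` then trains, per seed, the same main task
twice — auxiliary labels from the true hierarchy versus from
`random_hierarchy()` (same group-size multiset, seeded membership
shuffle, neutral group names) — and compares held-out main-task macro
F1 across five seeds. `run_ablation()` runs the four variants (full,
no-CoT, no-Bi-GRU, random auxiliary) under identical conditions; at
desk scale only completion and report comparability are asserted, since
the published ordering of ablation effects is a corpus-scale result.

## Numerical and degenerate-input choices

* Resampling uses zero-phase anti-aliased decimation
  (Chebyshev + `filtfilt`) for integer rate ratios, so waveforms are
  not delayed; non-integer ratios fall back to polyphase resampling.
  Upsampling is rejected — it is outside the supported protocol.
* Cropping keeps the *first* `target_seconds` of a long record
  (deterministic prefix); padding appends exact zeros.
* BCE probabilities are clamped by an additive 1e-12 inside the log.
* Batch-norm statistics use the population variance with momentum 0.1
  running updates; evaluation mode uses the running statistics, making
  eval-mode prediction a pure function of the input (tested).
* AUC is the Mann-Whitney rank statistic with ties counted 1/2;
  single-class targets yield `NA`, excluded from macro averaging with
  a warning.
* All randomness (initialisation, shuffling, dropout, generator) flows
  from explicit integer seeds through a private RNG stream that saves
  and restores the caller's `.Random.seed`.

## Known limitations

The engine is plain R: adequate for the desk-scale studies and tests,
not for corpus-scale training (a full PTB-XL run wants a GPU
framework). The WFDB reader covers format 16 single-segment records —
enough for the emulated layout, not the full format zoo. The MAT writer
emits exactly one double matrix per file. Hierarchies deeper than two
levels are out of scope.
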