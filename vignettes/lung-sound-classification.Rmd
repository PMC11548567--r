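---
title: "Classifying respiratory cycles with a 1D convolutional network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying respiratory cycles with a 1D convolutional network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulmosound)
```

## The problem

Auscultation of the lung distinguishes two families of adventitious
sounds superimposed on normal breath noise: **crackles** — brief
(roughly 5–15 ms) transient bursts with a bubbling or clicking
character, clinically associated with pneumonia and bronchitis — and
**wheezes** — sustained (hundreds of milliseconds) narrowband musical
tones associated with asthma and COPD. Automated four-class labelling
of annotated respiratory cycles (*normal*, *crackle*, *wheeze*,
*both*) is the core task this package implements, end to end: audio
ingestion in the ICBHI 2017 layout, preprocessing to fixed-width
waveforms, class balancing by synthetic minority oversampling (SMOTE),
a one-dimensional convolutional network trained on the raw waveform,
and grid-search tuning with stratified k-fold cross-validation.

Because the reference corpus (920 recordings, 128 participants, 6898
annotated cycles) must be downloaded separately, the package ships a
seedable synthetic generator that emulates the same layout and the four
acoustic classes, so the entire pipeline is runnable and testable from
a clean install.

## The synthetic generator

`synth_config()` / `synth_dataset()` produce annotated cycles built
from three ingredients:

* **Breath noise** — white noise low-passed at 500 Hz (4th-order
  Butterworth, zero-phase) and shaped by a raised-cosine
  inspiration/expiration envelope (defaults 0.40 / 0.55 of the cycle).
  This is the *normal* class: smooth, periodic, spectrally broad but
  featureless.
* **Crackles** — 5–10 exponentially damped sinusoid bursts per cycle,
  5–15 ms long, centre frequencies 200–1800 Hz, amplitude about six
  times the breath RMS. Damped transients at random positions are the
  standard morphological model for discontinuous adventitious sounds.
* **Wheezes** — an amplitude-modulated tone, 150–900 Hz with up to two
  harmonics and a few hertz of slow frequency modulation, covering
  45–80% of the cycle at about four times the breath RMS, giving the
  sustained narrowband spectrogram ridge that defines a wheeze.

The *both* class superimposes both event types. Every clip is
peak-normalised to 0.9 and bounded in $[-1, 1]$; all frequencies stay
below 2 kHz, matching a 4 kHz pipeline rate. Cycle durations are drawn
uniformly from 1–4 s (the real corpus spans 0.2–16 s with mean 2.7 s;
the narrower default range keeps every class realisable inside a single
clip). One cycle per simulated recording is the default layout —
the simplest that still exercises annotation parsing — with
multi-cycle recordings available via `cycles_per_recording`.

The paper-level acoustics are deliberately idealised: there is no
ambient noise corpus, no heart-sound contamination, no
equipment-dependent colouration, and class-defining events are always
well above the noise floor. Passing tests on these fixtures therefore
demonstrate that the pipeline's machinery is correct and that the
network can learn genuinely acoustic class distinctions from raw
waveforms — they do not certify clinical performance on real
recordings, which only corpus-scale experiments on the downloaded
database can establish.

Two unitless evidence scores (`adventitious_scores()`) quantify how
visible each event type is: spectral-ridge persistence for wheezes
(fraction of spectrogram frames in which one frequency bin exceeds six
times its local frequency-neighbourhood median, normalised by 0.3) and
maximum short-window excess kurtosis for crackles (normalised by 5).
A threshold of 1.0 on these scores is the default decision boundary of
`validity_screen()`, the automated stand-in for the manual spectrogram
review used on the real corpus; screening is off by default for real
data and used as quality control for fixtures.

## Preprocessing

`preprocess_config()` fixes the pipeline geometry:

| parameter | default | meaning |
|---|---|---|
| `target_rate` | 4000 Hz | all recordings resampled here; the band of interest is below 2 kHz |
| `cycle_truncation_s` | 2.7 s | cycles longer than this keep only their initial 2.7 s |
| `model_input_samples` | 8000 | exact network input width (2.0 s at 4 kHz) |
| `pad_mode` | `"zero"` | short cycles are zero-padded (wrap padding available) |
| `event_window_ms` | 20–25 ms | short-window grid for event statistics |
| `split_fraction` | 0.7 | stratified train share |

The truncation length (2.7 s) and the model input width (8000 samples
= 2.0 s) are deliberately independent settings: the published
preprocessing description truncates at 2.7 s while the published layer
table consumes 8000 samples. Keeping both, applied
truncation-then-crop, reproduces the layer table exactly while
honouring the stated truncation rule. Likewise the 20–25 ms event
windows are exposed (`segment_events()`) for quality control and
transient statistics, but the model consumes full fixed-width cycles —
the only reading consistent with an 8000-sample input layer.

Sample indexing uses `round(t * rate)` with half-open intervals
`[start, end)`, so adjacent cycles never share a boundary sample.
Spectrograms default to a 256-sample Hann window with 50% overlap.
Each clip is peak-normalised before modelling.

## SMOTE

`smote_balance()` implements synthetic minority oversampling from
scratch on the model's input space: for a minority-class sample
$x_i$, pick one of its $k$ nearest same-class neighbours $x_j$
(Euclidean distance on the raw fixed-width waveform vectors; $k = 5$)
and emit

$$x_\text{new} = x_i + r\,(x_j - x_i), \qquad r \sim U[0, 1],$$

until every class reaches the majority count. Base samples are visited
cyclically in row order and the neighbour is drawn uniformly among the
$k$, which gives even coverage and seeded reproducibility; distance
ties break toward the lower row index so neighbour sets are
deterministic. Every synthetic row is by construction a coordinate-wise
convex combination of two same-class originals, originals are kept
verbatim, and synthetic rows are flagged in the provenance table.
Balancing applies to training data only; inside cross-validation it is
re-run within each fold's training split, so held-out rows are never
touched. A singleton class cannot be interpolated and raises an error
rather than silently duplicating.

## The network

`default_arch()` is a sequential 1D-CNN on the raw 8000-sample
waveform: four conv/pool/dropout blocks — filters 8, 16, 32, 64 with
kernels 13, 11, 9, 7, every pool width 3 — then flatten (6080 units)
and a 256–128–64 dense funnel into a 4-way softmax. Convolutions are
valid (no padding, stride 1), pooling is non-overlapping floor
division. The kernel and pool widths are not arbitrary: they are the
unique integer solutions to the published layer-output sequence
8000 → 7988 → 2662 → 2652 → 884 → 876 → 292 → 286 → 95 under those
conventions, and `summarize_arch()` reproduces every output length and
parameter count of that table by pure arithmetic (total 1,618,724
parameters — the per-layer column's own sum).

Remaining choices the source material leaves open, and how this
package resolves them:

* **Activations**: ReLU on hidden layers, softmax output — the
  standard pairing for this table shape.
* **Dropout**: 0.3 after every block and dense layer, overridable
  per architecture (`default_arch(dropout_rate = )`).
* **Optimizer**: Adam, default learning rate 0.001, batch 32, 50
  epochs in `train_config()`; the candidate learning rates
  {0.0001, 0.001, 0.01} appear in the tuning grid.
* **Loss**: categorical cross-entropy by default, with focal loss
  $-(1-p_\text{true})^\gamma \log p_\text{true}$ available by
  configuration (`loss = "focal"`), since both balancing strategies —
  SMOTE and focal loss — are described for this model family without a
  definitive assignment.
* **Topology**: strictly sequential, as the layer table shows no skip
  connections; the prose mention of residual connections is not
  reflected in any printed shape and is not implemented.

Training runs in compiled code (Rcpp/Armadillo) with per-sample
backpropagation, inverted dropout and a private Mersenne-Twister
stream, so a fixed seed gives bit-identical histories. Non-finite loss
aborts with a diagnostic rather than continuing. `build_cnn()` counts
parameters from the allocated weight arrays themselves, which the test
suite compares against `summarize_arch()`'s arithmetic — two
independent routes to the same totals.

## Tuning and evaluation

`grid_spec()` is a 3×3×3×3×3 grid (243 combinations) over first-block
filters {32, 64, 128}, first-block kernel {3, 5, 7}, dropout
{0.2, 0.3, 0.4}, first dense width {64, 128, 256} and learning rate
{0.0001, 0.001, 0.01}. A single value per knob must describe a
four-block network, so `arch_from_grid()` applies the same progression
the default network uses: filters double block to block, kernels
shrink by 2 (floored at 1), dense widths halve. `grid_search()` scores
every combination by mean stratified k-fold validation accuracy with
SMOTE re-applied inside each fold, skips infeasible geometries with a
warning, and breaks ties by fewer parameters then grid order.

`eval_report()` builds the 4×4 confusion matrix (rows = truth) and
derives accuracy, per-class precision/recall/F1/support and
macro-averaged one-vs-rest sensitivity and specificity (the natural
multiclass extension when no binary definition is given). Metrics with
zero denominators are reported as 0 with a warning rather than NaN.
The 70/30 holdout and the k-fold protocol compose as: cross-validate
on the training partition, report finally on the untouched 30%.

## Numerical and degenerate-input choices

* Resampling is Fourier-domain (spectral truncation = ideal
  anti-aliasing low-pass); output length is pinned to
  `round(n * dst / src)`.
* Annotations marginally past the audio end are clamped with a
  warning; fully-outside annotations are skipped.
* A `crackle` request with `bursts_per_cycle = c(0, 0)` is honoured
  and documented as degenerate: the clip carries no events, matches
  normal-class statistics, and fails validity screening.
* WAV I/O is a minimal integer-PCM RIFF reader/writer (16-bit mono
  output; 8/16/24/32-bit input, multi-channel averaged to mono).
* Unpaired WAV/TXT files are skipped with a warning so partial corpora
  can still be summarised.

## Problem sizes used by the checks

The package's own verification runs at fixture scale, chosen so the
properties under test are meaningful rather than marginal: the
learnability check trains the default network on 200 synthetic cycles
per class (70/30 split) for 30 epochs at learning rate 0.0015, batch
16, and asks for at least 0.90 best validation accuracy; the
cross-validation demonstration uses 100 cycles per class and 15 epochs
per fold. The residual confusions at this scale mirror the real task's
structure — the *both* class is hardest, being a superposition of the
other two event types.

## Known limitations

* The generator's realism gap (above): clean events, no ambient noise,
  no recording-chain variability.
* Training is CPU-bound and single-threaded by design (determinism
  over speed); corpus-scale experiments are feasible but slow.
* The published corpus-scale accuracy (0.95) depends on the external
  dataset and stochastic training and is not a package-reproducible
  quantity; the package reproduces the architecture, the balancing
  contract and the evaluation arithmetic exactly, and the learnability
  property at fixture scale.
* `arch_spec()` requires a flatten and a softmax head; purely
  convolutional or headless networks are out of scope.
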