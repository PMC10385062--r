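---
title: "Frugal correction of wrist heart-rate measurements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frugal correction of wrist heart-rate measurements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frugalhr)
```

`frugalhr` corrects the heart-rate readings of a low-cost wrist wearable
(a PPG sensor) against a chest-worn ECG reference, with a model small
enough to run inside a smartwatch's real-time operating system. This
vignette explains the method, the package's modelling choices, and what
the synthetic-data tests do and do not establish.

## The data model

A session yields three streams: device heart rate (roughly every 12 s,
jittered), reference heart rate (every 15 s), and three-axis acceleration
(~4 Hz). Alignment takes the device readings as the primary series. Each
retained reading is paired with the nearest-in-time reference value
(equidistant ties resolve to the earlier reference sample, so the rule is
deterministic) and with the acceleration magnitudes recorded in the
half-open window since the previous retained reading, so windows are
disjoint and every acceleration sample belongs to at most one reading.

Readings are dropped when no reference value lies within `max_gap`
(default 15 s, one reference interval) or when the heart rate is outside
the plausibility range 20–250 BPM. Every drop starts a new *contiguity
segment*; sliding windows, the moving-average baseline and the streaming
replay never cross segment boundaries, which is the package's guard
against stale context leaking across interruptions.

Timestamps are session-relative seconds. Files carrying absolute
datetimes are rebased on read by subtracting the earliest timestamp seen
across the three streams, since the two devices do not share a clock.

## Features

Reading $h_i$ is described by

$$v = \langle h_1,\dots,h_m,\; a^{med}_1,\dots,a^{med}_k,\;
       a^{max}_1,\dots,a^{max}_k,\; a^{iqr}_1,\dots,a^{iqr}_k \rangle,$$

of length $m + 3k$, grouped by statistic with index 1 the oldest. The
three per-window statistics — median, maximum, interquartile range of the
acceleration magnitudes — are computable from one sort followed by
indexing, which is what the target microcontroller can afford:

* even-length medians are the midpoint of the two central elements (one
  multiplication by 0.5, no division);
* the IQR uses the zero-based nearest-rank positions
  $\lfloor 0.25(n-1)\rfloor$ and $\lfloor 0.75(n-1)\rfloor$ — pure
  indexing; interpolation conventions were rejected because they require
  division.

Whether the current reading belongs to its own window is ambiguous in
principle; the package defaults to including it as $h_m$
(`include_current = TRUE`), with the strictly-past variant available
behind the flag. The current inter-reading window is always summarized as
$a_k$. A window that contains no acceleration sample (two readings in
quick succession) reuses the previous window's summary, and the event is
flagged.

Features are standardized with training-set statistics stored as mean and
*pre-inverted* standard deviation, so that applying them needs only
multiplication — the same arithmetic the device uses. Zero-variance
features get `inv_std = 1` and a flag. Targets (reference BPM) are never
normalized.

## The regressor and its training

The corrector is a fully connected network: input $m + 3k$, ReLU hidden
layers, one linear output. The deployed architecture (`m = 5`, `k = 3`,
hidden 5 and 3) has $15\cdot5 + 6\cdot3 + 4\cdot1 = 97$ parameters,
honouring the ≤ 100-parameter budget. Because no deep-learning runtime is
required at this size, the forward pass, backpropagation, Adam and Glorot
initialization are implemented directly in R; this keeps the batch
pipeline and the streaming emulation arithmetically identical.

Training follows the recipe the method was developed with: Adam at
learning rate 0.001, MSE loss plus L2(0.01) on kernels (biases are not
penalized), batch size 16. Choices the recipe leaves open were fixed as
follows:

* **Epoch budget.** `max_epochs = 500` with early stopping on validation
  MAE, `patience = 50`, best-epoch weights restored. The model is tiny
  and epochs are cheap; early stopping is the main guard against
  overfitting a small dataset.
* **Initialization.** Kernels are Glorot-uniform per repeat seed. The
  output bias starts at the training-target mean rather than zero: heart
  rates live near 90 BPM while Adam steps are bounded by the learning
  rate, so a zero-started output spends tens of thousands of updates
  climbing to the right scale. In our experiments zero-bias starts
  consumed most of the epoch budget and occasionally converged to
  corrections far worse than the raw readings; mean-target starts
  converge quickly and uniformly across seeds. A constant-lr schedule is
  kept: plateau-based decay was tried and rejected because it froze this
  scale climb.
* **Split.** 70/10/20 into per-participant contiguous time blocks in the
  order train → validation → test (earliest data trains, latest tests).
  Feature rows whose windows straddle a block boundary are discarded, so
  the three sets share no underlying record. A participant too short for
  three blocks goes wholly to the training set, with a warning.
* **Repeats.** `train_repeats()` trains five models differing only in
  seed and keeps the best by validation MAE — the same repeat protocol
  used in tuning, applied to the final fit to absorb occasional bad
  initializations.
* **Divergence.** A non-finite training prediction aborts with an error
  naming the epoch; in the grid search such repeats are recorded as
  missing and aggregates are flagged.

## Architecture tuning

The grid spans heart-rate windows {1, 3, 5, 7}, acceleration windows
{1, 3, 5}, 1–6 first-layer units, 0–2 additional hidden layers and 1–4
units shared by all additional layers; collapsing the unit choice when
there is no additional layer yields $4\cdot3\cdot6\cdot(1+4+4) = 648$
unique architectures. Each is trained five times (seeds differing by
repeat) and repeat MAEs are aggregated by the arithmetic mean (a minimum
aggregate is available behind a flag). The final model is chosen among
candidates within `mae_tolerance` (default 0.1 BPM — the size/accuracy
trade-off is not quantified elsewhere, and 0.1 BPM is well below any
practically relevant difference) of the best validation MAE: fewest
parameters first, then fewer layers, then smaller $m$, then smaller $k$.
The test block is never touched during tuning; the suite verifies this by
corrupting test-only records and asserting bit-identical search results.

## Evaluation and frugality

`evaluate_methods()` scores three methods on identical evaluation points:
the raw reading, a moving average of the last five readings (partial
leading windows; segment-aware), and the model. It reports MAE and MSE,
signed-error quartiles and 1.5·IQR box-plot outliers (the standard whisker
rule; nothing else is specified for this summary).

The frugality score condenses the accuracy/footprint trade-off:

$$\mathrm{score}(w) = \mathrm{MAE}_{test} - \frac{w}{1 + \frac{1}{U_{RAM}\cdot T_{CPU}}},$$

with memory $U_{RAM}$ in bytes, per-inference time $T_{CPU}$ in
milliseconds, and $w \in [0,1]$ the importance of frugality. Lower is
better; at $w = 0$ the score is exactly the test MAE, and the penalty
approaches $w$ as the resource product grows. The typography of the
source formula admits a second, exponent reading, implemented as
`variant = "power"` for comparison; the difference reading is the default
because it matches the structure of the score it descends from (a
performance term minus a resource-use term). $U_{RAM}$ and $T_{CPU}$ are
user-supplied constants — this package does not measure hardware; the
defaults (880 B, 0.184 ms) are the published measurements for the
deployed corrector, and $U_{RAM}$ counts only method-attributable bytes.

## Streaming emulation

`stream_init()`/`stream_push_accel()`/`stream_push_hr()` mirror the
firmware implementation: acceleration magnitudes are kept insertion-sorted
(O(n) insert, no sort afterwards) in a buffer of fixed capacity (default
256 samples, ~60 s at 4 Hz; exceeding it is an error since the device
cannot grow its buffer), summarized and cleared at each reading; the $m$
readings and $k$ summary triples live in constant-size rolling buffers;
normalization multiplies by the pre-inverted standard deviations. The test
suite asserts structurally that the hot path contains no division
operator. Until the buffers fill, readings pass through raw and flagged —
a watch must always display something. Post-warm-up the replay of a
session equals the batch pipeline's predictions to floating-point
accuracy.

## The synthetic-data generator

The generator makes every stage testable without recordings. It emulates:

* an 85-minute laboratory protocol (breaks alternating with treadmill
  walks at 5 and 3 km/h and upper-lift exercises) driving first-order
  heart-rate dynamics $\dot{HR} = (HR_{target} - HR)/\tau$, integrated
  exactly per step and continuous across phases;
* phase steady-state targets rest 70 / walk-3 95 / walk-5 115 /
  lift-dynamic 120 / lift-calm 100 BPM with $\tau = 45$ s — invented,
  physiologically plausible constants, documented as fixtures;
* exact 15 s reference sampling of the true trajectory (the reference is
  treated as gold), exponential-jittered ~12 s device sampling, 4 Hz
  acceleration whose oscillatory magnitude follows the phase intensity;
* device error $\mathcal{N}(0,\, \sigma_0 + c\cdot IQR_w)$ with the
  window acceleration IQR, plus sign-symmetric uniform spikes. The
  defaults $\sigma_0 = 10$ BPM, $c = 40$ BPM/g, spike probability 0.15
  with 30–80 BPM amplitude were chosen to reproduce the documented error
  scale of the emulated device class — raw MAE in the high teens with an
  MSE several times $\mathrm{MAE}^2$ (heavy tails) and frequent sudden
  peaks — and are frozen; the per-seed output is bit-reproducible.

What the generator does *not* emulate: raw PPG waveforms, sensor-contact
and skin-tone effects, reference-device error (the synthetic reference is
exact), rhythmic-motion aliasing that correlates error *sign* with
activity, and between-participant physiology differences. Passing the
synthetic tests therefore shows that the pipeline is correct and that the
model exploits motion context as designed — not that the specific error
magnitudes transfer to any real device.

## Numerical choices and degenerate inputs

* Equidistant reference ties → earlier sample; duplicated device
  timestamps → first kept.
* Empty acceleration windows → previous summary reused (flagged); a
  segment with no summary yet yields no feature rows.
* Zero-variance features → `inv_std = 1`, flagged, normalized to 0.
* Weights are serialized to JSON with 17 significant digits, so
  export → reload → predict is bit-stable; a C-style static-array export
  of the same numbers is provided for embedding.
* Problem sizes in the test suite and acceptance script (six synthetic
  participants, five training repeats, reduced-epoch fits in unit tests)
  were chosen as the smallest sizes at which the studied effects are
  stable.

## Known limitations

* The split convention (per-participant contiguous blocks) is one of
  several defensible readings of a leakage-free 70/10/20 split; absolute
  error numbers on real data are sensitive to it.
* The protocol places the most intense activity late in the session, so
  the chronological split asks the model to extrapolate to motion levels
  it never trained on; this is faithful to the study design but is the
  main driver of residual test error on synthetic data.
* The moving-average baseline and the model see identical evaluation
  points, but the baseline needs no warm-up, which slightly favours it at
  segment starts.
* `u_ram` and `t_cpu` are constants supplied by the user; no attempt is
  made to measure the R implementation's footprint, which would be
  meaningless for the embedded target.
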