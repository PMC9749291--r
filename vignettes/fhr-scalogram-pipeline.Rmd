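---
title: "From FHR trace to distress call: methods behind ctgmorse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From FHR trace to distress call: methods behind ctgmorse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctgmorse)
```

# Overview

`ctgmorse` classifies intrapartum fetal-heart-rate (FHR) recordings as
*normal* or *distressed*. The label is objective: umbilical-artery pH
measured shortly after birth, with pH &le; 7.15 assigned to the
distressed class (the boundary value itself is distressed). Expert
visual annotation and APGAR scores are deliberately not supported as
labeling criteria — both are subjective and a major source of
inter-observer disagreement in CTG practice.

The model is a classical scalogram-classification design: clean the 4 Hz
FHR trace with rule-based artifact removal, represent the stage-specific
window as a generalized Morse wavelet scalogram image, and train a
two-class image classifier on the labeled images. This vignette records
the method, every tunable that matters, and the design decisions the
package made where more than one reasonable choice existed.

# Preprocessing

Clinical FHR is acquired by external sensors and is contaminated in three
characteristic ways: dropouts (runs where the value falls to exactly 0),
non-physiologic outliers (below 50 bpm or above 200 bpm), and spikes
(jumps of more than 25 bpm from the previous beat). The cleaning chain
runs in a fixed order — outputs are defined only for this order:

1. **Long-gap deletion** (`remove_long_gaps`). Zero-runs lasting
   *strictly* more than 15 s (60 samples at 4 Hz) are excised and the
   series concatenated. The time axis is reindexed: downstream analysis
   treats the result as contiguous, which keeps fixed-length segments
   meaningful. A run of exactly 15 s is *kept* and later interpolated
   (strict reading of "more than 15 s"). Deletion never alters a
   surviving sample.
2. **Edge trimming** (`trim_edges`). Leading and trailing zero-runs are
   removed entirely, whatever their length, so the signal starts and
   ends at a stable measurement.
3. **Linear interpolation** (`interpolate_outliers`). Remaining zeros
   (short gaps) and outliers are replaced by the two-point linear
   formula `y = (y0 (x1 - x) + y1 (x - x0)) / (x1 - x0)` between the
   nearest *valid* neighbors — valid meaning nonzero and inside
   [50, 200]. The bounds are exclusive as outlier criteria: a sample of
   exactly 50 or 200 bpm is physiologic and untouched.
4. **Spike repair** (`remove_spikes`). A left-to-right scan: a jump of
   more than 25 bpm from the last stable sample opens an unstable run,
   which closes at the first sample back within 25 bpm of that stable
   value. The run is replaced by a natural cubic spline through 4 stable
   anchor samples on each side, and the scan repeats (at most 10 passes)
   until no violation remains. The anchor count and the run-termination
   rule are package decisions, chosen for locality and spline stability;
   a run that reaches the signal end is replaced by a least-squares
   linear extension of the left anchors instead, since there is no right
   side to anchor a spline on. Repaired values are clamped to [50, 200].
5. **Segmentation** (`segment_fhr`). Stage 1 of labor uses the first
   20 min of the cleaned signal (4800 samples at 4 Hz); stage 2 the last
   15 min (3600 samples). Windows are measured on the cleaned,
   shortened signal. A signal shorter than its window is rejected with a
   warning — padding would fabricate physiology.

After the full chain the signal contains no zeros, lies in [50, 200] bpm
and has no adjacent change above 25 bpm; these three invariants are
asserted by brute-force scans in the test suite. Each signal carries a
provenance tally (`gaps_removed`, `samples_interpolated_linear`,
`samples_interpolated_spline`, `edge_samples_trimmed`) so that tests can
verify the pipeline repaired exactly the defects that were injected. The
chain is idempotent: running it on its own output changes nothing.

# Window-slicing augmentation

Distressed outcomes are much rarer than normal ones (roughly 1:4 in
intrapartum databases), and the package oversamples the minority class
rather than discarding majority data. Each distressed recording yields
`1 + n_slices` segments (default 3): the base stage window plus the same
window shifted backward in time by 5 min per slice.

One anchoring subtlety is a package decision: the stage-1 base window
starts at time zero, so a backward shift would leave the recording.
The base window is therefore taken at offset `n_slices * shift` and the
extra slices step backward toward zero — offsets {2400, 1200, 0} samples
under the defaults — which reproduces the x3 minority multiplication
without fabricating samples. For stage 2 the base is the final window
and each slice starts 5 min earlier. When a cleaned recording is too
short for some slices, the feasible ones are returned with a warning.

Augmentation happens *before* splitting, matching the cohort counts this
arithmetic is designed around (439 normal + 113 distressed records over
two stage experiments give 1556 items, 878 normal and 678 distressed).
Slices of one recording may then span train and test; this leakage risk
is inherent to that scheme and documented here — `build_dataset` keeps
`record_id` in its manifest so a caller can split by record instead.

# The generalized Morse wavelet

The scalogram uses the analytic generalized Morse family, defined in the
frequency domain as `psi(omega) = U(omega) alpha omega^beta
exp(-omega^gamma)` with `P^2 = gamma * beta` the time-bandwidth product.
Properties the implementation enforces and tests:

- **Exact analyticity.** Filter rows are identically zero at all
  non-positive frequencies (including DC), so there is no
  negative-frequency leakage.
- **gamma = 3** makes the demodulate skewness — the third standardized
  moment of the wavelet after demodulation to its peak frequency — zero:
  the maximally symmetric "Airy" members with minimal Heisenberg area.
  `morse_demodulate_skewness` computes the moment numerically from
  derivatives of the spectrum at the peak frequency
  (`omega_p = (beta/gamma)^(1/gamma)`), and the tests cross-check it
  against the independent closed form
  `-(2 - (gamma-1)(gamma-2)) / (gamma^{3/2} beta^{1/2})`.
- **Bandwidth behavior.** At fixed gamma = 3, the half-power bandwidth
  of the frequency response is strictly decreasing in `P^2` (measured
  numerically over {4, 60, 120}): higher `P^2` buys frequency resolution
  at the cost of time resolution. FHR representation uses `P^2 = 60`
  (the usual default for time-frequency analysis) with 55 as the second
  supported value; extremes in either direction are avoided.
- **Normalization.** The family's normalizing constant is not uniquely
  conventional; the package uses `alpha = 2 (e gamma / beta)^(beta/gamma)`,
  which sets the frequency-domain peak to 2 — the dominant convention in
  analytic-CWT tooling, making tone amplitudes recoverable.

## Filter bank and CWT

`morse_filterbank` builds a geometric scale grid with 12 voices per
octave. The endpoints are a stated contract: the smallest scale places
the wavelet's peak exactly at Nyquist; the largest is set so that two
time-domain standard deviations of the wavelet
(`sqrt(beta*gamma)/omega_p` at scale 1) fit in the signal. The low end
therefore depends on the transform length — 4800-sample stage-1 windows
reach about 0.002 Hz. `fhr_cwt` removes the signal mean, multiplies the
spectrum by each filter row and inverse-transforms; boundary handling is
periodic (FFT-native), so ridge tests avoid the outermost samples. Tones
localize to the correct scale row within one voice step (a factor of
2^(1/12)), verified across 0.05–1.5 Hz.

## Rendering

`render_scalogram` min–max normalizes the magnitude per image, maps it
through a 256-level jet colormap and bilinearly resizes (via EBImage) to
224 x 224 x 3 — the input contract of standard pretrained image
backbones. Rendering is deterministic and invariant to positive
rescaling of the magnitude; per-image normalization means absolute
signal amplitude is *not* encoded in the image, only relative
time-frequency structure.

# Splitting, training, evaluation

`stratified_split` holds out `round(0.10 * n)` items per class for
testing; the remainder is the training pool, from which
`train_classifier` carves a further 10% per class as the validation set
monitored during training. (A three-way 80/10/10 description of the same
scheme is arithmetically inconsistent with the worked 88-normal /
68-distressed test split that a 90/10 per-class holdout reproduces
exactly; the package implements the 90/10 + validation-from-train
reading.)

The classifier is a transfer-learning stage with two pluggable parts:

- a **backbone** — any function from a 224 x 224 x 3 array to a fixed
  feature vector. The built-in `pool_backbone(grid = 16)` mean-pools the
  image over a 16 x 16 cell lattice per channel (768 features); 16 cells
  per side is the coarsest lattice that still resolves the scalogram
  texture that separates the classes. It stands in for a frozen
  pretrained trunk so the package and its tests run without any weight
  download; an exported ResNet-style feature extractor can be plugged in
  unchanged.
- a **softmax head** trained by mini-batch Adam (`train_config`:
  learning rate 0.001, mini-batch 30, up to 15 epochs, validation every
  15 iterations), replacing the trunk's original classification layer.
  Features are standardized with training-set statistics. Training
  records per-iteration loss/accuracy and periodic validation points —
  the usual learning curves. Every stochastic step (split, validation
  draw, shuffling, initialization) takes an explicit seed.

`evaluate_classifier` counts the binary confusion matrix with distressed
as the positive class; `classification_metrics` reports
`Acc = (tp+tn)/total`, `Se = tp/(tp+fn)`, `Sp = tn/(tn+fp)` as
percentages rounded half-up to one decimal (so 66/68 reports as 97.1). A
zero denominator yields an `NA` with an `undefined` flag rather than an
error.

# The synthetic FHR generator

`simulate_fhr_record` emulates what the pipeline needs to see, not full
fetal physiology. A record is baseline + slow wander + band-limited
short-term variability (Gaussian-smoothed noise) + Gaussian-bump
accelerations and decelerations, clamped pre-defect to [55, 195] bpm.
The distressed signature scales with `class_separation`: lower baseline
(-20 bpm at separation 1), damped variability, more and deeper
decelerations — the qualitative CTG correlates of fetal compromise. At
separation 0 the classes are literally the same distribution and only
the synthesized pH differs. Defaults: 35-min records (headroom for the
stage-1 window plus two backward slices after typical long-gap loss),
140 bpm baseline, 8 bpm variability, about one dropout, one outlier and
one spike per 10 minutes.

Defects are injected at positions at least 40 samples apart and 200
samples from either edge, so each is unambiguously attributable, and
every injection is written to a ledger. Zero-run lengths are a 70/30
mixture of short (&le; 60 samples) and long (> 60) runs, so both the
interpolation and the deletion path are exercised. The tests then check
*ledger completeness*: the pipeline's provenance counts must equal the
ledger exactly — long gaps excised, short-gap samples plus outliers
linearly interpolated, spike samples spline-repaired, nothing trimmed at
the edges.

What the generator does **not** emulate: real baseline drift and
contraction-coupled deceleration timing, autonomic variability spectra,
sensor re-acquisition artifacts, or any distributional match to a
clinical database. Passing the end-to-end tests therefore shows the
pipeline machinery is correct and that a learnable class signature
survives it — not that clinical-grade accuracy has been achieved on real
recordings.

# Problem sizes and numerical choices

The test suite runs at desk scale by design: 200 ledgered 25-min records
for the preprocessing invariant suite; end-to-end cohorts of 88 normal +
22 distressed records (154 items after slicing) for the classification
sanity checks, with a 10% holdout. Skewness differentiation uses a
five-point central-difference stencil at a relative step of 1e-3, giving
|skewness| < 1e-6 at gamma = 3 against truncation error well below that.
Half-power bandwidths are found by `uniroot` bracketing on each flank of
the peak. Spline repair clamps to [50, 200] and re-scans; ties and
degenerate inputs (all-zero signals, too-short records, single-class
cohorts, zero metric denominators) raise typed errors or flags rather
than propagating nonsense.

# Known limitations

- The WFDB reader supports format-16 single-file records (the layout of
  the target intrapartum database) — not the full WFDB format zoo.
- Augment-before-split can leak slices of one recording across
  partitions; use the manifest's `record_id` to split by record when
  that matters.
- The built-in backbone is a pooling feature extractor, not a deep
  network; headline accuracies from fine-tuned ImageNet backbones on
  clinical data are out of scope here and require both the clinical
  database and pretrained weights.
- Uterine-contraction preprocessing is out of scope: the UC channel is
  read, carried, and written, but the pipeline analyzes FHR only.
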