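# brainprint

Universal, privacy-preserving EEG biometric authentication in R.

## The problem

EEG is an attractive biometric — hard to steal, implicitly liveness-tested —
but classifier-based systems only recognize the subjects they were trained
on, and storing raw enrollment EEG leaks sensitive information (health,
age, state). **brainprint** implements the deep-fingerprint alternative:

1. Train an *n*-subject convolutional **identification** model on window-
   augmented, min-max-normalized, Gram-Schmidt-orthogonalized EEG.
2. Discard the two-dense-layer classification head; the remaining
   convolutional stack is the **fingerprint function** `f`, mapping any EEG
   sample `a` (also from subjects never seen in training) to a fixed-length
   vector `s = f(a)` — an "EEG hash": constant length, non-invertible.
3. Enroll users by storing only `s`. Verify a claimed identity by the
   distance rule

   `l(a, s) = true  iff  distance(s, f(a)) <= threshold`

   with Euclidean, Manhattan or cosine distance (cosine = 1 − similarity,
   so small always means similar), the threshold calibrated at the
   **equal-error-rate** point of a DET curve (FAR vs FRR sweep).
4. Reduce the required electrodes with an **orthogonal forward search**:
   greedily add the channel whose Gram-Schmidt residual (relative to the
   channels already chosen) maximizes classification accuracy.

Augmentation follows the sliding/sampling-window scheme: sliding windows of
`T` samples, step `delta`, `eta` per input (one input spans
`Gamma = (eta − 1) · delta + T` samples), sampling window advancing by
`Delta`, so a record of `n` samples yields `floor((n − Gamma)/Delta) + 1`
inputs. At the defaults (`T = 160, delta = 4, eta = 20, Delta = 8`,
i.e. `Gamma = 236`), a 60 s record at 160 Hz yields exactly 1171 inputs.

A synthetic cohort generator (subject-specific band-limited oscillators +
channel mixing + session noise) makes the whole pipeline testable end to
end — including open-set ("Beta" subjects never seen in training)
verification — without downloading any corpus. The CNN engine itself is
implemented in RcppArmadillo; no deep-learning framework is required.

## Worked example

```r
library(brainprint)

# a 16-subject cohort, 3 channels, two 30 s sessions each
cohort <- generate_cohort(cohort_spec(n_subjects = 16, n_channels = 3,
                                      duration_s = 30, seed = 1))

# full open-set protocol: train on the 12 "Alpha" subjects' session 1,
# enroll everyone, probe with session 2, calibrate cosine threshold at the
# Alpha-trial EER (desk-scale profile: 20 epochs, batch 8, capped inputs)
res <- run_full_protocol(cohort, n_alpha = 12,
                         config = classifier_config(n_classes = 2,
                                                    batch_size = 8),
                         distances = "cosine", n_probes = 6, seed = 1,
                         epochs = 20, max_inputs = 96, max_inputs_fp = 64)
r <- res$results$cosine
round(c(threshold = r$threshold, eer = r$eer,
        accuracy = r$metrics[["accuracy"]]), 4)
#> threshold       eer  accuracy
#>    0.0271    0.0278    0.9518
r$four_case
#>         genuine  impostor
#> alpha 0.9722222 0.9583333
#> beta  0.8750000 0.9333333
```

The threshold is the calibrated cosine acceptance distance; `eer` is the
equal error rate on the Alpha calibration trials; `accuracy` is the
fraction of all 1536 genuine + impostor verification trials decided
correctly at that threshold. The four-case matrix splits accuracy by
{Alpha, Beta} × {genuine, impostor} — the `beta` row is the universality
check: those subjects contributed nothing to training, yet genuine probes
are accepted and impostors rejected at comparable rates.

Enrollment/verification as an authentication server would use it:

```r
f <- res$fingerprinter                 # the EEG-hash function
store <- enrollment_store(f, cohort[[1]]$channel_names)
store <- enroll(store, "alice", cohort[[1]], f)
policy <- auth_policy("cosine", r$threshold)
verify(store, "alice", cohort[[2]], f, policy)   # same subject, session 2
#> <auth_decision> ACCEPTED  (cosine distance 0.0006749, threshold 0.0270975)
save_store(store, "store.json")        # fingerprints only — no raw EEG
```

There is also a command line (`inst/cli/brainprint`) with subcommands
`simulate`, `train`, `select-channels`, `enroll`, `verify`, `evaluate` and
`full-protocol`; EDF files and plain numeric matrices are both accepted as
recordings.

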