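# Shared desk-scale fixtures. All fixtures are generated in code; the tiny
# window/model profiles keep single-CPU runtimes in seconds while exercising
# every code path of the full-size configuration.

tiny_params <- function() window_params(T = 32, delta = 8, eta = 4, Delta = 16)

tiny_config <- function(n_classes = 2L, ...) {
  classifier_config(n_classes = n_classes, conv_filters = c(8L, 16L),
                    dense_hidden = 32L, dropout_rate = 0.25,
                    batch_size = 16L, epochs = 3L, ...)
}

# two-subject cohort with widely separated bands: trivially separable
tiny_cohort <- function(n_subjects = 2L, n_channels = 2L, duration_s = 10,
                        seed = 1L, ...) {
  generate_cohort(cohort_spec(n_subjects = n_subjects,
                              n_channels = n_channels,
                              duration_s = duration_s, seed = seed,
                              band_width_hz = 4, noise_sd = 0.2, ...))
}

session1 <- function(cohort) Filter(function(r) identical(r$session, 1L), cohort)

# deterministic pseudo-random recording (no subject structure)
random_recording <- function(n_channels = 3L, n_samples = 1600L, seed = 1L,
                             subject_id = "X", session = 1L,
                             channel_names = NULL) {
  set.seed(seed)
  if (is.null(channel_names)) {
    channel_names <- montage_commercial()[seq_len(n_channels)]
  }
  eeg_recording(matrix(rnorm(n_channels * n_samples), n_channels),
                160, channel_names, subject_id = subject_id,
                session = session)
}

# independent least-squares projection oracle: residual of u on span(basis)
# via the normal equations, never via Gram-Schmidt
projection_residual_oracle <- function(u, basis) {
  B <- do.call(cbind, basis)
  beta <- solve(crossprod(B), crossprod(B, u))
  as.numeric(u - B %*% beta)
}
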