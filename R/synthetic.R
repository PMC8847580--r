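#' Specification of a synthetic multi-subject EEG cohort
#'
#' Subjects are modelled as stationary band-limited oscillators: each subject
#' owns a disjoint frequency band and each latent source draws a fixed center
#' frequency from that band, emulating the stable spectral individuality
#' (e.g. occipital alpha) that resting-state EEG biometrics exploit.
#' Channels are linear mixtures of the latent sources plus independent
#' Gaussian sensor noise, so inter-channel redundancy is dialled by the
#' mixing matrix. Sessions share a subject's frequencies but redraw phases,
#' phase jitter and noise, emulating session-to-session variation.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param n_channels number of channels; labelled from the commercial
#'   montage subset.
#' @param duration_s session length in seconds; must allow at least two
#'   disjoint Gamma-length segments at the default windowing.
#' @param sample_rate_hz sampling rate (Hz).
#' @param n_sessions sessions per subject (enrollment uses session 1,
#'   probes session 2).
#' @param seed mandatory master seed; the cohort is a pure function of the
#'   spec including the seed.
#' @param base_freq_hz,band_width_hz subject band `i` (after a seeded
#'   permutation of band-to-subject assignment) spans
#'   `[base + (i-1)*width, base + i*width]` Hz.
#' @param amplitude oscillator amplitude (device units).
#' @param phase_jitter_sd per-sample phase random-walk standard deviation
#'   (radians); makes windows of one session non-identical.
#' @param noise_sd sensor noise standard deviation (device units).
#' @param mixing optional `n_channels x n_channels` mixing matrix applied to
#'   the per-channel latent sources (default: identity). Duplicated or
#'   linearly dependent rows create redundant channels.
#' @param informative_channel optional 1-based index: only this channel's
#'   latent source carries the subject signature, all other sources are
#'   pure noise (used for channel-selection experiments).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 16L, n_channels = 3L, duration_s = 30,
                        sample_rate_hz = 160, n_sessions = 2L, seed,
                        base_freq_hz = 5, band_width_hz = 1.5,
                        amplitude = 1, phase_jitter_sd = 0.03,
                        noise_sd = 0.5, mixing = NULL,
                        informative_channel = NULL) {
  if (missing(seed) || !is.numeric(seed)) {
    stop("spec error: a numeric seed is mandatory", call. = FALSE)
  }
  n_subjects <- as.integer(n_subjects)
  n_channels <- as.integer(n_channels)
  if (n_subjects < 2L) stop("spec error: need at least two subjects", call. = FALSE)
  if (n_channels < 1L) stop("spec error: need at least one channel", call. = FALSE)
  if (duration_s <= 0) stop("spec error: non-positive duration", call. = FALSE)
  n <- as.integer(round(duration_s * sample_rate_hz))
  if (n < 2L * window_gamma(window_params())) {
    stop("spec error: duration too short for two disjoint Gamma-length segments",
         call. = FALSE)
  }
  nyquist <- sample_rate_hz / 2
  if (base_freq_hz + n_subjects * band_width_hz >= nyquist) {
    stop("spec error: subject bands exceed the Nyquist frequency", call. = FALSE)
  }
  if (!is.null(mixing)) {
    mixing <- as.matrix(mixing)
    if (!all(dim(mixing) == n_channels)) {
      stop("spec error: mixing must be n_channels x n_channels", call. = FALSE)
    }
  }
  if (!is.null(informative_channel)) {
    informative_channel <- as.integer(informative_channel)
    if (informative_channel < 1L || informative_channel > n_channels) {
      stop("spec error: informative_channel out of range", call. = FALSE)
    }
  }
  structure(list(n_subjects = n_subjects, n_channels = n_channels,
                 duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 n_sessions = as.integer(n_sessions), seed = as.integer(seed),
                 base_freq_hz = base_freq_hz, band_width_hz = band_width_hz,
                 amplitude = amplitude, phase_jitter_sd = phase_jitter_sd,
                 noise_sd = noise_sd, mixing = mixing,
                 informative_channel = informative_channel),
            class = "cohort_spec")
}

synthetic_channel_names <- function(n_channels) {
  pool <- c(montage_commercial(), setdiff(montage_1010(), montage_commercial()))
  if (n_channels > length(pool)) {
    stop("spec error: more channels than montage labels", call. = FALSE)
  }
  pool[seq_len(n_channels)]
}

#' Generate a synthetic cohort of EEG recordings
#'
#' Fully reproducible from `spec$seed`: the same spec yields bit-identical
#' cohorts. Returns `n_subjects * n_sessions` recordings with subject ids
#' `"S01"`, `"S02"`, ... and integer sessions.
#'
#' @param spec a [cohort_spec()].
#' @return list of [eeg_recording()]s.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ns <- spec$n_subjects; nc <- spec$n_channels
  n <- as.integer(round(spec$duration_s * spec$sample_rate_hz))
  tt <- (seq_len(n) - 1) / spec$sample_rate_hz
  ids <- sprintf("S%02d", seq_len(ns))

  with_local_seed(spec$seed, {
    # decouple spectral ordering from enumeration (and Alpha/Beta) order
    band_of <- sample.int(ns)
    freqs <- matrix(0, ns, nc)
    for (i in seq_len(ns)) {
      lo <- spec$base_freq_hz + (band_of[i] - 1) * spec$band_width_hz
      freqs[i, ] <- stats::runif(nc, lo, lo + spec$band_width_hz)
    }

    out <- list()
    for (i in seq_len(ns)) {
      for (sess in seq_len(spec$n_sessions)) {
        src <- matrix(0, nc, n)
        for (k in seq_len(nc)) {
          informative <- is.null(spec$informative_channel) ||
            k == spec$informative_channel
          if (informative) {
            phase0 <- stats::runif(1, 0, 2 * pi)
            jitter <- cumsum(stats::rnorm(n, 0, spec$phase_jitter_sd))
            src[k, ] <- spec$amplitude *
              sin(2 * pi * freqs[i, k] * tt + phase0 + jitter)
          }
          # non-informative sources stay zero; sensor noise added below
        }
        x <- if (is.null(spec$mixing)) src else spec$mixing %*% src
        x <- x + matrix(stats::rnorm(nc * n, 0, spec$noise_sd), nc, n)
        rec <- eeg_recording(
          x, spec$sample_rate_hz, synthetic_channel_names(nc),
          subject_id = ids[i], session = sess)
        lo <- spec$base_freq_hz + (band_of[i] - 1) * spec$band_width_hz
        attr(rec, "subject_band_hz") <- c(lo, lo + spec$band_width_hz)
        out[[length(out) + 1L]] <- rec
      }
    }
    out
  })
}

#' Planted-signal cohort for channel-selection experiments
#'
#' Exactly one channel (`informative_channel`) carries the subject-specific
#' oscillation; every other channel is i.i.d. sensor noise, or — when
#' `duplicate_channel` is given — an exact copy of the informative channel
#' (constructed through the mixing matrix), enabling the redundancy
#' property: the duplicate's Gram-Schmidt residual is numerically zero once
#' the informative channel is selected.
#'
#' @param n_subjects,n_channels,seed as in [cohort_spec()].
#' @param informative_channel 1-based index of the signal-bearing channel.
#' @param duplicate_channel optional 1-based index of a channel made an
#'   exact copy of the informative one.
#' @param duration_s,noise_sd,... further [cohort_spec()] arguments.
#' @return list of [eeg_recording()]s.
#' @export
planted_selection_cohort <- function(n_subjects, n_channels,
                                     informative_channel = 1L, seed,
                                     duplicate_channel = NULL,
                                     duration_s = 10, noise_sd = 0.3, ...) {
  mixing <- diag(n_channels)
  if (!is.null(duplicate_channel)) {
    if (duplicate_channel == informative_channel) {
      stop("spec error: duplicate must differ from the informative channel",
           call. = FALSE)
    }
    mixing[duplicate_channel, ] <- 0
    mixing[duplicate_channel, informative_channel] <- 1
  }
  spec <- cohort_spec(n_subjects = n_subjects, n_channels = n_channels,
                      duration_s = duration_s, seed = seed,
                      noise_sd = noise_sd, mixing = mixing,
                      informative_channel = informative_channel, ...)
  cohort <- generate_cohort(spec)
  if (!is.null(duplicate_channel)) {
    # an exact copy: remove the duplicate's independent sensor noise by
    # copying the informative channel verbatim
    cohort <- lapply(cohort, function(r) {
      r$data[duplicate_channel, ] <- r$data[informative_channel, ]
      r
    })
  }
  cohort
}
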