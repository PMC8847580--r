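#' Sliding/sampling window parameters
#'
#' The augmentation scheme draws `eta` overlapped sliding windows of length
#' `T` (step `delta`) out of every sampling window; the sampling window spans
#' `Gamma = (eta - 1) * delta + T` samples and advances by `Delta` samples
#' between consecutive model inputs. Defaults are the tuned values for
#' 160 Hz resting-state recordings: a one-second sliding window (`T = 160`),
#' `delta = 4`, `eta = 20` and `Delta = 8`, giving `Gamma = 236`.
#'
#' @param T sliding window length in samples.
#' @param delta sliding step in samples; must satisfy `0 < delta < T` so that
#'   consecutive segments overlap.
#' @param eta number of sliding windows per model input.
#' @param Delta sampling-window step in samples.
#' @return An object of class `window_params`.
#' @export
window_params <- function(T = 160L, delta = 4L, eta = 20L, Delta = 8L) {
  T <- as.integer(T); delta <- as.integer(delta)
  eta <- as.integer(eta); Delta <- as.integer(Delta)
  if (is.na(T) || T < 2L) stop("T must be an integer >= 2", call. = FALSE)
  if (is.na(delta) || delta < 1L || delta >= T) {
    stop("delta must satisfy 0 < delta < T (sliding step smaller than window)",
         call. = FALSE)
  }
  if (is.na(eta) || eta < 1L) stop("eta must be >= 1", call. = FALSE)
  if (is.na(Delta) || Delta < 1L) stop("Delta must be >= 1", call. = FALSE)
  structure(list(T = T, delta = delta, eta = eta, Delta = Delta),
            class = "window_params")
}

#' @export
print.window_params <- function(x, ...) {
  cat(sprintf("<window_params> T=%d delta=%d eta=%d Delta=%d (Gamma=%d)\n",
              x$T, x$delta, x$eta, x$Delta, window_gamma(x)))
  invisible(x)
}

#' Per-input signal span Gamma
#'
#' The number of raw samples consumed by one model input:
#' `Gamma = (eta - 1) * delta + T`.
#'
#' @param params a [window_params()].
#' @return integer number of samples.
#' @export
window_gamma <- function(params) {
  stopifnot(inherits(params, "window_params"))
  (params$eta - 1L) * params$delta + params$T
}

#' Min-max scale a channel signal to `[0, 1]`
#'
#' `u_hat = (u - min(u)) / (max(u) - min(u))`. The extrema are taken over the
#' full signal passed in (per channel, per recording), not per window. A
#' constant signal carries no information and typically indicates a broken
#' electrode, so it raises an error rather than silently mapping to a
#' constant.
#'
#' @param u numeric vector, length >= 2.
#' @return numeric vector in `[0, 1]` with minimum exactly 0 and maximum 1.
#' @export
minmax_normalize <- function(u) {
  if (!is.numeric(u) || length(u) < 2L) {
    stop("signal must be a numeric vector of length >= 2", call. = FALSE)
  }
  lo <- min(u); hi <- max(u)
  if (!is.finite(lo) || !is.finite(hi)) {
    stop("signal contains non-finite values", call. = FALSE)
  }
  if (hi <= lo) {
    stop("degenerate signal: constant channel (max == min) carries no information",
         call. = FALSE)
  }
  (u - lo) / (hi - lo)
}

#' Gram-Schmidt orthogonalization of a signal against a basis
#'
#' Removes from `u_hat` its components along each previously accepted signal:
#' `v = u_hat - sum_j ((v_j . u_hat) / (v_j . v_j)) v_j`. With an empty basis
#' the signal is returned unchanged (the first selected channel is never
#' orthogonalized). All arithmetic is double precision; the orthogonality
#' guarantee is `|v . v_j| / (||v|| ||v_j||) < 1e-8` for well-conditioned
#' inputs.
#'
#' @param u_hat numeric vector (typically a min-max normalized channel).
#' @param basis list of numeric vectors, pairwise orthogonal, same length as
#'   `u_hat`; may be empty.
#' @return numeric vector orthogonal to every basis member.
#' @export
orthogonalize <- function(u_hat, basis = list()) {
  if (!is.list(basis)) basis <- list(basis)
  v <- as.numeric(u_hat)
  for (b in basis) {
    if (length(b) != length(v)) {
      stop("shape error: basis vector length differs from signal length",
           call. = FALSE)
    }
    nb <- sum(b * b)
    if (nb == 0) {
      stop("zero vector in orthogonal basis (division by zero)", call. = FALSE)
    }
    v <- v - (sum(b * v) / nb) * b
  }
  v
}

#' Draw eta overlapped sliding windows from a signal
#'
#' Row `r` (1-based) of the result is `signal[(r-1)*delta + 1 .. (r-1)*delta + T]`;
#' consecutive rows overlap by `T - delta` samples. The signal must span at
#' least `Gamma` samples.
#'
#' @param signal numeric vector.
#' @param params a [window_params()].
#' @return an `eta x T` numeric matrix.
#' @export
sliding_segments <- function(signal, params) {
  stopifnot(inherits(params, "window_params"))
  gam <- window_gamma(params)
  if (length(signal) < gam) {
    stop(sprintf("insufficient length: signal has %d samples, Gamma = %d",
                 length(signal), gam), call. = FALSE)
  }
  starts <- (seq_len(params$eta) - 1L) * params$delta
  idx <- outer(starts, seq_len(params$T), `+`)     # eta x T of 1-based indices
  matrix(signal[idx], nrow = params$eta, ncol = params$T)
}

#' Enumerate sampling-window start offsets
#'
#' Model inputs are cut at offsets `0, Delta, 2*Delta, ...` as long as a full
#' `Gamma`-span fits in the record; the count is
#' `floor((n_samples - Gamma) / Delta) + 1`.
#'
#' @param n_samples total record length in samples.
#' @param params a [window_params()].
#' @return integer vector of 0-based start offsets.
#' @export
enumerate_input_offsets <- function(n_samples, params) {
  stopifnot(inherits(params, "window_params"))
  n_samples <- as.integer(n_samples)
  gam <- window_gamma(params)
  if (n_samples < gam) {
    stop(sprintf("insufficient length: record has %d samples, Gamma = %d",
                 n_samples, gam), call. = FALSE)
  }
  n_inputs <- (n_samples - gam) %/% params$Delta + 1L
  (seq_len(n_inputs) - 1L) * params$Delta
}

#' Build model inputs from a recording
#'
#' The full preprocessing chain: each requested channel is min-max normalized
#' over the whole recording, optionally Gram-Schmidt orthogonalized against
#' the previously listed channels (in `channels` order, within this
#' recording), and then segmented: every sampling-window offset yields one
#' `eta x T x |C|` array whose depth ordering follows `channels`.
#' Orthogonalized signals are fed onward without re-normalization unless
#' `rescale = TRUE`.
#'
#' @param rec an [eeg_recording()].
#' @param channels ordered character vector of channel labels (the selected
#'   set C).
#' @param params a [window_params()].
#' @param orthogonalize logical; apply sequential Gram-Schmidt in
#'   `channels` order. With a single channel the flag has no effect.
#' @param rescale logical; re-apply min-max scaling after orthogonalization
#'   (off by default: the pipeline specifies a single normalization).
#' @param max_inputs optional cap on the number of inputs; when fewer inputs
#'   than offsets are requested an evenly spaced subset of offsets is used.
#'   This is a compute-budget control for desk-scale runs, not part of the
#'   augmentation scheme.
#' @return list of `model_input` arrays (`eta x T x |C|`), each carrying
#'   `subject_id` and `offset` attributes.
#' @export
build_inputs <- function(rec, channels, params = window_params(),
                         orthogonalize = TRUE, rescale = FALSE,
                         max_inputs = NULL) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(params, "window_params"))
  channels <- as.character(channels)
  if (length(channels) < 1L) stop("at least one channel required", call. = FALSE)
  missing <- setdiff(channels, rec$channel_names)
  if (length(missing) > 0L) {
    stop(sprintf("lookup error: channel(s) %s not present in recording",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }

  signals <- preprocess_channels(rec, channels, orthogonalize, rescale)
  offsets <- enumerate_input_offsets(ncol(rec$data), params)
  if (!is.null(max_inputs) && is.finite(max_inputs) &&
      length(offsets) > max_inputs) {
    pick <- unique(round(seq(1L, length(offsets), length.out = max_inputs)))
    offsets <- offsets[pick]
  }

  gam <- window_gamma(params)
  lapply(offsets, function(off) {
    x <- array(0, dim = c(params$eta, params$T, length(channels)))
    for (k in seq_along(channels)) {
      seg <- signals[[k]][(off + 1L):(off + gam)]
      x[, , k] <- sliding_segments(seg, params)
    }
    attr(x, "subject_id") <- rec$subject_id
    attr(x, "offset") <- off
    class(x) <- c("model_input", class(x))
    x
  })
}

# normalize (and optionally orthogonalize in order) the named channels,
# returning a list of full-length signals
preprocess_channels <- function(rec, channels, ortho = TRUE, rescale = FALSE) {
  basis <- list()
  signals <- vector("list", length(channels))
  for (k in seq_along(channels)) {
    u_hat <- minmax_normalize(channel_signal(rec, channels[k]))
    v <- if (ortho) orthogonalize(u_hat, basis) else u_hat
    if (ortho) basis[[k]] <- v
    if (rescale && diff(range(v)) > 0) v <- minmax_normalize(v)
    signals[[k]] <- v
  }
  names(signals) <- channels
  signals
}

#' Stack a list of model inputs into a 4-D batch array
#'
#' @param inputs list of `model_input` arrays sharing a common shape.
#' @return numeric array `eta x T x n_channels x n_inputs`.
#' @export
stack_model_inputs <- function(inputs) {
  if (length(inputs) == 0L) stop("no inputs to stack", call. = FALSE)
  d <- dim(inputs[[1]])
  out <- array(0, dim = c(d, length(inputs)))
  for (i in seq_along(inputs)) {
    if (!identical(dim(inputs[[i]]), d)) {
      stop("shape error: inputs have inconsistent shapes", call. = FALSE)
    }
    out[, , , i] <- inputs[[i]]
  }
  out
}
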