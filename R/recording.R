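#' Multi-channel EEG recording container
#'
#' An `eeg_recording` is the raw authentication datum: one subject's
#' multi-channel signal together with its sampling rate and ordered channel
#' labels. Data are held as a dense double-precision matrix with one row per
#' channel, because downstream Gram-Schmidt orthogonalization is numerically
#' sensitive.
#'
#' @param data numeric matrix, `n_channels x n_samples`, in device units.
#' @param sample_rate_hz positive sampling rate in Hz.
#' @param channel_names character vector of unique montage labels (10-10
#'   system, e.g. `"Oz"`, `"T7"`, `"Cz"`), one per row of `data`.
#' @param subject_id opaque subject identifier.
#' @param session optional session identifier (integer or string); used by
#'   the evaluation protocol to keep enrollment and probe material disjoint.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sample_rate_hz, channel_names,
                          subject_id = "unknown", session = 1L) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix (channels x samples)", call. = FALSE)
  }
  storage.mode(data) <- "double"
  channel_names <- as.character(channel_names)
  if (nrow(data) != length(channel_names)) {
    stop(sprintf("shape error: %d data rows but %d channel names",
                 nrow(data), length(channel_names)), call. = FALSE)
  }
  if (anyDuplicated(channel_names)) {
    stop("channel names must be unique", call. = FALSE)
  }
  if (ncol(data) < 1L) stop("recording must contain at least one sample",
                            call. = FALSE)
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("`sample_rate_hz` must be a single positive number", call. = FALSE)
  }
  rownames(data) <- channel_names
  structure(
    list(subject_id = as.character(subject_id),
         session = session,
         sample_rate_hz = as.numeric(sample_rate_hz),
         channel_names = channel_names,
         data = data),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject=%s session=%s  %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, as.character(x$session), nrow(x$data),
              ncol(x$data), x$sample_rate_hz,
              ncol(x$data) / x$sample_rate_hz))
  cat("channels:", paste(utils::head(x$channel_names, 12), collapse = ", "),
      if (length(x$channel_names) > 12) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_samples <- function(rec) ncol(rec$data)

#' Extract one channel's signal by label
#'
#' @param rec an [eeg_recording()].
#' @param label montage label.
#' @return numeric vector of samples.
#' @export
channel_signal <- function(rec, label) {
  i <- match(label, rec$channel_names)
  if (is.na(i)) {
    stop(sprintf("lookup error: channel '%s' not present in recording", label),
         call. = FALSE)
  }
  rec$data[i, ]
}

# ---- 10-10 montage -------------------------------------------------------

# Canonical labels of the 64-electrode arrangement used by the Physionet-style
# motor/imagery montage (international 10-10 positions).
MONTAGE_64 <- c(
  "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
  "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
  "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
  "Fp1", "Fpz", "Fp2",
  "AF7", "AF3", "AFz", "AF4", "AF8",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "FT7", "FT8", "T7", "T8", "T9", "T10", "TP7", "TP8",
  "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
  "PO7", "PO3", "POz", "PO4", "PO8",
  "O1", "Oz", "O2", "Iz"
)

# A 20-label subset representative of consumer-grade headset coverage.
# The exact commercial montage is device-dependent; this stand-in extends the
# classic 14-electrode consumer layout with midline sites so that occipital,
# temporal and central positions are all searchable.
MONTAGE_COMMERCIAL_20 <- c(
  "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC6",
  "T7", "Cz", "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "Oz", "O2"
)

#' Standard 10-10 montages
#'
#' `montage_1010()` returns the canonical labels of the 64-electrode 10-10
#' arrangement; `montage_commercial()` returns a designated 20-label subset
#' emulating the coverage of commercial EEG headsets (a documented synthetic
#' stand-in; the subset is contained in the full montage).
#'
#' @return character vector of canonical channel labels.
#' @export
montage_1010 <- function() MONTAGE_64

#' @rdname montage_1010
#' @export
montage_commercial <- function() MONTAGE_COMMERCIAL_20

#' Normalize raw channel labels to canonical 10-10 form
#'
#' EDF headers frequently pad labels with periods and whitespace (`"Oz.."`)
#' and vary in case (`"FCZ"`, `"Fcz"`). Labels are stripped of periods and
#' whitespace and, when they match a 10-10 position case-insensitively,
#' rewritten in canonical case. Unrecognized labels are returned stripped but
#' otherwise untouched. The mapping is idempotent.
#'
#' @param labels character vector of raw labels.
#' @return character vector of normalized labels.
#' @export
normalize_channel_labels <- function(labels) {
  stripped <- gsub("[.[:space:]]+", "", as.character(labels))
  idx <- match(toupper(stripped), toupper(MONTAGE_64))
  out <- ifelse(is.na(idx), stripped, MONTAGE_64[idx])
  out
}
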