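#' Read an EEG recording from an EDF file
#'
#' Minimal reader for the European Data Format (EDF): 256-byte fixed ASCII
#' header, 256 bytes of per-signal header fields, then data records of
#' little-endian 16-bit integers which are rescaled to physical units via the
#' per-signal digital/physical calibration ranges. Channel labels are
#' normalized to bare 10-10 names (see [normalize_channel_labels()]).
#'
#' Only continuous signals sharing a single sampling rate are supported;
#' EDF+ annotation channels are dropped with a warning. Event channels and
#' discontinuous recordings are out of scope.
#'
#' @param path path to an EDF file.
#' @param subject_id subject identifier; default is the header's patient
#'   field (or the file name when that field is empty).
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, subject_id = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("format error: cannot read EDF file '%s' (no such file)", path),
         call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  ascii <- function(n) {
    raw <- readBin(con, "raw", n = n)
    if (length(raw) < n) stop("format error: truncated EDF header", call. = FALSE)
    trimws(rawToChar(raw))
  }
  num <- function(n) {
    s <- ascii(n)
    v <- suppressWarnings(as.numeric(s))
    if (length(v) != 1L || is.na(v)) {
      stop(sprintf("format error: non-numeric EDF header field '%s'", s),
           call. = FALSE)
    }
    v
  }

  version <- ascii(8)
  patient <- ascii(80)
  recording_field <- ascii(80)
  ascii(8); ascii(8)                      # start date / time, unused
  header_bytes <- num(8)
  reserved <- ascii(44)
  n_records <- num(8)
  record_duration_s <- num(8)
  ns <- as.integer(num(4))
  if (ns < 1L) stop("format error: EDF file declares no signals", call. = FALSE)
  if (grepl("EDF\\+D", reserved)) {
    stop("unsupported input: discontinuous EDF+ recordings are not supported",
         call. = FALSE)
  }

  labels <- vapply(seq_len(ns), function(i) ascii(16), character(1))
  vapply(seq_len(ns), function(i) ascii(80), character(1))   # transducer
  vapply(seq_len(ns), function(i) ascii(8), character(1))    # physical dim
  phys_min <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  vapply(seq_len(ns), function(i) ascii(80), character(1))   # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(num(8)), integer(1))
  vapply(seq_len(ns), function(i) ascii(32), character(1))   # reserved

  expected_header <- 256L + 256L * ns
  if (header_bytes != expected_header) {
    # tolerate but reposition to the declared offset
    seek(con, where = header_bytes, origin = "start")
  }

  is_annotation <- grepl("EDF Annotations", labels, fixed = TRUE)
  keep <- which(!is_annotation)
  if (any(is_annotation)) {
    warning("dropping EDF+ annotation channel(s); annotations are not supported")
  }
  if (length(keep) == 0L) {
    stop("format error: EDF file contains no signal channels", call. = FALSE)
  }
  if (length(unique(spr[keep])) != 1L) {
    stop("unsupported input: signals with mixed sampling rates", call. = FALSE)
  }
  if (record_duration_s <= 0) {
    stop("format error: non-positive data record duration", call. = FALSE)
  }
  fs <- spr[keep[1]] / record_duration_s

  if (n_records < 0) {
    # unknown record count: infer from remaining file size
    here <- seek(con, where = NA)
    total <- file.info(path)$size
    bytes_per_record <- 2 * sum(spr)
    n_records <- floor((total - here) / bytes_per_record)
  }
  n_records <- as.integer(n_records)
  if (n_records < 1L) stop("format error: EDF file contains no data records",
                           call. = FALSE)

  chunks <- vector("list", ns)
  for (i in seq_len(ns)) chunks[[i]] <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      x <- readBin(con, "integer", n = spr[i], size = 2,
                   signed = TRUE, endian = "little")
      if (length(x) < spr[i]) {
        stop("format error: truncated EDF data record", call. = FALSE)
      }
      chunks[[i]][[r]] <- x
    }
  }

  nkeep <- length(keep)
  total_samples <- spr[keep[1]] * n_records
  data <- matrix(0, nrow = nkeep, ncol = total_samples)
  for (j in seq_len(nkeep)) {
    i <- keep[j]
    digital <- unlist(chunks[[i]], use.names = FALSE)
    gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    data[j, ] <- phys_min[i] + (digital - dig_min[i]) * gain
  }

  if (is.null(subject_id)) {
    subject_id <- if (nzchar(patient)) patient else basename(path)
  }
  eeg_recording(data, sample_rate_hz = fs,
                channel_names = normalize_channel_labels(labels[keep]),
                subject_id = subject_id)
}

#' Write an EEG recording to an EDF file
#'
#' Companion writer used for fixtures and interoperability. Each channel is
#' scaled to the full 16-bit digital range with per-channel physical
#' calibration, so round-tripping preserves the signal to within the format's
#' quantization (about 1/65535 of the channel's amplitude range).
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @param record_duration_s duration of one data record in seconds; the
#'   recording is truncated to a whole number of records.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_duration_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sample_rate_hz
  spr <- as.integer(round(fs * record_duration_s))
  if (spr < 1L || abs(spr - fs * record_duration_s) > 1e-9) {
    stop("record_duration_s must contain a whole number of samples", call. = FALSE)
  }
  n_rec <- ncol(rec$data) %/% spr
  if (n_rec < 1L) stop("recording shorter than one data record", call. = FALSE)
  ns <- nrow(rec$data)

  pad <- function(s, n) {
    s <- substr(as.character(s), 1, n)
    paste0(s, strrep(" ", n - nchar(s)))
  }
  fmt_num <- function(x, n) pad(formatC(x, format = "g", digits = 7), n)

  phys_min <- apply(rec$data, 1, min)
  phys_max <- apply(rec$data, 1, max)
  flat <- phys_max - phys_min <= 0
  phys_max[flat] <- phys_min[flat] + 1     # degenerate channel: unit range
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar(paste0(
    pad("0", 8), pad(rec$subject_id, 80), pad("brainprint", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 + 256 * ns, 8), pad("", 44),
    pad(n_rec, 8), fmt_num(record_duration_s, 8), pad(ns, 4),
    paste(vapply(rec$channel_names, pad, character(1), n = 16), collapse = ""),
    strrep(pad("", 80), ns),
    strrep(pad("uV", 8), ns),
    paste(vapply(phys_min, fmt_num, character(1), n = 8), collapse = ""),
    paste(vapply(phys_max, fmt_num, character(1), n = 8), collapse = ""),
    strrep(pad(dig_min, 8), ns),
    strrep(pad(dig_max, 8), ns),
    strrep(pad("", 80), ns),
    strrep(pad(spr, 8), ns),
    strrep(pad("", 32), ns)
  ), con, eos = NULL)

  # header uses %g with 7 digits; quantize against the same parsed values
  pm <- as.numeric(formatC(phys_min, format = "g", digits = 7))
  px <- as.numeric(formatC(phys_max, format = "g", digits = 7))
  gain <- (px - pm) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(ns)) {
      digital <- round((rec$data[i, idx] - pm[i]) / gain[i]) + dig_min
      digital <- as.integer(pmin(pmax(digital, dig_min), dig_max))
      writeBin(digital, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read/write a plain text matrix recording
#'
#' `read_array()` loads a whitespace- or tab-separated numeric matrix (rows =
#' channels) and attaches the supplied metadata; `write_array()` writes the
#' companion format. This is the package's portable container for synthetic
#' recordings and fixtures.
#'
#' @param path file path.
#' @param sample_rate_hz sampling rate in Hz.
#' @param channel_names channel labels, one per matrix row.
#' @param subject_id,session recording metadata.
#' @return `read_array()` returns an [eeg_recording()]; `write_array()`
#'   returns `path` invisibly.
#' @export
read_array <- function(path, sample_rate_hz, channel_names,
                       subject_id = "unknown", session = 1L) {
  if (!file.exists(path)) {
    stop(sprintf("format error: cannot read '%s'", path), call. = FALSE)
  }
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != length(channel_names)) {
    stop(sprintf("shape error: matrix has %d rows but %d channel names given",
                 nrow(m), length(channel_names)), call. = FALSE)
  }
  eeg_recording(m, sample_rate_hz, channel_names,
                subject_id = subject_id, session = session)
}

#' @rdname read_array
#' @param rec an [eeg_recording()] to write.
#' @export
write_array <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  utils::write.table(rec$data, path, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  invisible(path)
}
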