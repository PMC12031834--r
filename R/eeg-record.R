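#' Standard 10-20 scalp montage labels
#'
#' The 19 electrode names of the international 10-20 system, in the order
#' used by the simulator and the EDF writer.
#' @format Character vector of length 19.
#' @export
montage_10_20 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                   "T3", "C3", "Cz", "C4", "T4",
                   "T5", "P3", "Pz", "P4", "T6", "O1", "O2")

#' Construct a multichannel EEG record
#'
#' The raw unit of analysis: a channels-by-samples signal matrix in microvolts
#' with its sampling rate, 10-20 channel labels, and study metadata (patient,
#' scheduled timepoint, day relative to infusion).
#'
#' @param signal Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector of unique channel names (10-20
#'   convention); defaults to rownames of `signal` or the first
#'   `nrow(signal)` labels of [montage_10_20].
#' @param patient_id Patient identifier.
#' @param timepoint One of `"baseline"`, `"T1"`, `"T3"`, `"T7"`, `"T14"`,
#'   `"extra"`.
#' @param record_day Day of recording relative to infusion (day 0).
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(signal, fs, channel_labels = NULL,
                       patient_id = NA_character_, timepoint = "extra",
                       record_day = NA_real_) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("signal must be a numeric channels x samples matrix")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a positive sampling rate in Hz")
  if (is.null(channel_labels)) {
    channel_labels <- rownames(signal)
    if (is.null(channel_labels)) {
      if (nrow(signal) > length(montage_10_20))
        stop("supply channel_labels for montages larger than 19 channels")
      channel_labels <- montage_10_20[seq_len(nrow(signal))]
    }
  }
  if (length(channel_labels) != nrow(signal))
    stop("channel_labels length must match the number of signal rows")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  timepoint <- match.arg(timepoint,
                         c("baseline", "T1", "T3", "T7", "T14", "extra"))
  rownames(signal) <- channel_labels
  structure(list(
    signal = signal, fs = fs, channel_labels = channel_labels,
    patient_id = patient_id, timepoint = timepoint, record_day = record_day
  ), class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("EEG record: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs))
  cat("  patient:", x$patient_id, " timepoint:", x$timepoint,
      " day:", x$record_day, "\n")
  invisible(x)
}

# ---- EDF I/O -------------------------------------------------------------
# Minimal implementation of the European Data Format (EDF): fixed-width ASCII
# header (256 bytes global + 256 bytes per signal) followed by data records
# of 16-bit little-endian integers, linearly mapped between the digital and
# physical (microvolt) ranges. One-second data records; the sampling rate
# must therefore be a whole number of Hz.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write an EEG record to an EDF file
#'
#' @param record An [eeg_record()].
#' @param path Output file path.
#' @return `path`, invisibly. Signals are quantized to 16 bits over the
#'   per-channel physical range, the usual EDF precision.
#' @export
write_edf <- function(record, path) {
  if (!inherits(record, "eeg_record")) stop("record must be an eeg_record")
  fs <- record$fs
  if (fs != round(fs))
    stop("EDF export uses 1 s data records; fs must be an integer Hz")
  sig <- record$signal
  ns <- nrow(sig)
  n_rec <- floor(ncol(sig) / fs)
  if (n_rec < 1) stop("record shorter than one 1 s data record")
  sig <- sig[, seq_len(n_rec * fs), drop = FALSE]

  # integer physical bounds keep the 8-char header fields exact
  phys_min <- floor(apply(sig, 1, min))
  phys_max <- ceiling(apply(sig, 1, max))
  flat <- phys_max - phys_min <= 0
  phys_max[flat] <- phys_min[flat] + 1  # avoid zero scale for flat channels
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(record$patient_id, 80),
    .edf_pad(paste("timepoint", record$timepoint), 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (1 + ns), 8),
    .edf_pad("", 44),
    .edf_pad(n_rec, 8),
    .edf_pad(1, 8),
    .edf_pad(ns, 4)
  )
  fields <- c(
    .edf_pad(record$channel_labels, 16),
    .edf_pad(rep("", ns), 80),
    .edf_pad(rep("uV", ns), 8),
    .edf_pad(format(phys_min, scientific = FALSE, trim = TRUE), 8),
    .edf_pad(format(phys_max, scientific = FALSE, trim = TRUE), 8),
    .edf_pad(rep(dig_min, ns), 8),
    .edf_pad(rep(dig_max, ns), 8),
    .edf_pad(rep("", ns), 80),
    .edf_pad(rep(fs, ns), 8),
    .edf_pad(rep("", ns), 32)
  )
  writeChar(paste0(hdr, paste(fields, collapse = "")), con, eos = NULL)

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((sig[ch, idx] - phys_min[ch]) * scale[ch] + dig_min)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

.edf_field <- function(raw, at, width) {
  trimws(rawToChar(raw[at:(at + width - 1)]))
}

#' Read an EDF file into an EEG record
#'
#' Parses the EDF header, checks structural integrity against the file size,
#' converts the 16-bit samples to physical units (microvolts) and normalizes
#' channel labels to plain 10-20 names (a leading "EEG " prefix and
#' reference suffixes such as "-REF" are stripped).
#'
#' @param path EDF file path.
#' @param require_channels Optional character vector of channel labels that
#'   must be present; missing ones raise an error listing the absentees.
#' @param patient_id,timepoint,record_day Metadata to attach (EDF itself
#'   stores only free-text identification).
#' @return An [eeg_record()].
#' @export
read_edf <- function(path, require_channels = NULL,
                     patient_id = NULL, timepoint = "extra",
                     record_day = NA_real_) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  size <- file.info(path)$size
  if (size < 256) stop("not a valid EDF file (truncated header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256)
  n_rec <- suppressWarnings(as.integer(.edf_field(hdr, 237, 8)))
  rec_dur <- suppressWarnings(as.numeric(.edf_field(hdr, 245, 8)))
  ns <- suppressWarnings(as.integer(.edf_field(hdr, 253, 4)))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || is.na(rec_dur) || rec_dur <= 0)
    stop("not a valid EDF file (malformed header): ", path)
  shdr <- readBin(con, "raw", 256 * ns)
  if (length(shdr) < 256 * ns)
    stop("not a valid EDF file (truncated signal header): ", path)
  fld <- function(offset, width) {
    vapply(seq_len(ns), function(i)
      .edf_field(shdr, offset * ns + (i - 1) * width + 1, width), character(1))
  }
  labels <- fld(0, 16)
  phys_min <- as.numeric(fld(16 + 80 + 8, 8))
  phys_max <- as.numeric(fld(16 + 80 + 8 + 8, 8))
  dig_min <- as.numeric(fld(16 + 80 + 8 + 8 + 8, 8))
  dig_max <- as.numeric(fld(16 + 80 + 8 + 8 + 8 + 8, 8))
  spr <- as.integer(fld(16 + 80 + 8 + 8 + 8 + 8 + 8 + 80, 8))
  if (any(is.na(spr)) || any(spr < 1))
    stop("not a valid EDF file (bad samples-per-record): ", path)
  expected <- 256 * (1 + ns) + n_rec * sum(spr) * 2
  if (size < expected)
    stop("not a valid EDF file (data shorter than header declares): ", path)

  # normalize labels: "EEG Fp1-REF" -> "Fp1"
  labels <- sub("^EEG[ _]?", "", labels, ignore.case = TRUE)
  labels <- sub("-(REF|LE|AVG|A1|A2)$", "", labels, ignore.case = TRUE)
  if (!is.null(require_channels)) {
    missing <- setdiff(require_channels, labels)
    if (length(missing))
      stop("required channels absent from EDF: ",
           paste(missing, collapse = ", "))
  }
  if (length(unique(spr)) > 1)
    stop("channels with differing sampling rates are not supported")
  fs <- spr[1] / rec_dur

  sig <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[ch], size = 2, endian = "little")
      idx <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      sig[ch, idx] <- (dig - dig_min[ch]) * scale[ch] + phys_min[ch]
    }
  }
  pid <- if (is.null(patient_id)) .edf_field(hdr, 9, 80) else patient_id
  eeg_record(sig, fs, channel_labels = labels, patient_id = pid,
             timepoint = timepoint, record_day = record_day)
}
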