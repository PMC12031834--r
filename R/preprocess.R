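# Single-pass IIR filter (direct form I via stats::filter, which runs in C)
# initialized in the steady state of a step held at x[1], so there is no
# artificial startup discontinuity.
.iir_filter <- function(b, a, x) {
  u0 <- x[1]
  nb <- length(b)
  xx <- c(rep(u0, nb - 1), x)
  v <- as.numeric(stats::filter(xx, b, method = "convolution",
                                sides = 1))[nb - 1 + seq_along(x)]
  if (length(a) > 1) {
    ar <- -a[-1]
    y_ss <- u0 * sum(b) / (1 - sum(ar))  # steady-state output for step u0
    v <- as.numeric(stats::filter(v, ar, method = "recursive",
                                  init = rep(y_ss, length(ar))))
  }
  v
}

# Zero-phase IIR filtering: mirror padding at both ends (a time-reversed
# copy keeps band content identical and adds no offset) plus steady-state
# initialization, forward then backward; residual transients decay inside
# the pad instead of corrupting the signal.
.filtfilt_pad <- function(b, a, x, padlen) {
  n <- length(x)
  padlen <- min(padlen, n - 1)
  head_pad <- x[seq(padlen + 1, 2)]
  tail_pad <- x[seq(n - 1, n - padlen)]
  y <- c(head_pad, x, tail_pad)
  y <- .iir_filter(b, a, y)
  y <- rev(.iir_filter(b, a, rev(y)))
  y[padlen + seq_len(n)]
}

# RBJ-cookbook second-order IIR notch at f0 with quality factor Q.
.notch_coef <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Filter an EEG record for quantitative analysis
#'
#' Applies, zero-phase (forward-backward), the routine-EEG conditioning
#' chain: a 0.5-40 Hz bandpass (2nd-order Butterworth high-pass cascaded
#' with a 4th-order Butterworth low-pass) and a comb of IIR notches (Q = 30)
#' at the powerline frequency and its integer multiples up to Nyquist.
#' Zero-phase filtering avoids the phase distortion that would bias
#' phase-based connectivity downstream. Output length equals input length.
#'
#' @param record An [eeg_record()].
#' @param powerline Powerline frequency in Hz (default 50).
#' @param band Bandpass edges in Hz, default `c(0.5, 40)`.
#' @param notch_q Quality factor of each notch.
#' @return The filtered [eeg_record()].
#' @export
apply_filters <- function(record, powerline = 50, band = c(0.5, 40),
                          notch_q = 30) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$fs
  if (fs <= 2 * band[2])
    stop("sampling rate too low for the requested bandpass: fs = ", fs)
  hp <- signal::butter(2, band[1] / (fs / 2), type = "high")
  lp <- signal::butter(4, band[2] / (fs / 2), type = "low")
  notch_freqs <- powerline * seq_len(floor((fs / 2 - 1e-9) / powerline))
  notches <- lapply(notch_freqs, .notch_coef, fs = fs, Q = notch_q)
  sig <- record$signal
  padlen <- round(3 * fs)  # ~3 s absorbs the 0.5 Hz high-pass transient
  for (ch in seq_len(nrow(sig))) {
    x <- sig[ch, ]
    x <- .filtfilt_pad(hp$b, hp$a, x, padlen)
    x <- .filtfilt_pad(lp$b, lp$a, x, padlen)
    for (nt in notches)
      x <- .filtfilt_pad(nt$b, nt$a, x, padlen)
    sig[ch, ] <- x
  }
  out <- record
  out$signal <- sig
  out
}

#' Assemble the artifact-free epoch of a record
#'
#' Removes every sample falling in an annotated artifact interval
#' (half-open, `[onset, onset + duration)` seconds from record start) and
#' concatenates the clean segments in temporal order, without resampling or
#' tapering. Records whose clean time falls below `min_epoch_s` are rejected
#' rather than analysed, mirroring routine practice of excluding
#' artifact-dominated recordings.
#'
#' @param record An [eeg_record()] (typically already filtered).
#' @param artifacts Data frame with `onset_s` and `duration_s` columns; may
#'   have zero rows.
#' @param min_epoch_s Minimum clean duration in seconds (default 20).
#' @return An `eeg_epoch` (signal matrix, `fs`, `total_duration`, source
#'   metadata), or an `epoch_rejection` object carrying the reason.
#' @export
assemble_epoch <- function(record, artifacts = NULL, min_epoch_s = 20) {
  stopifnot(inherits(record, "eeg_record"))
  n <- ncol(record$signal)
  dur <- n / record$fs
  keep <- rep(TRUE, n)
  if (!is.null(artifacts) && nrow(artifacts) > 0) {
    if (any(artifacts$duration_s <= 0))
      stop("artifact intervals must have positive duration")
    if (any(artifacts$onset_s < 0) ||
        any(artifacts$onset_s + artifacts$duration_s > dur + 1e-9))
      stop("artifact interval outside the record")
    a <- artifacts[order(artifacts$onset_s), , drop = FALSE]
    ends <- a$onset_s + a$duration_s
    if (nrow(a) > 1 && any(a$onset_s[-1] < ends[-nrow(a)] - 1e-9))
      stop("artifact intervals overlap")
    times <- (seq_len(n) - 1) / record$fs
    for (i in seq_len(nrow(a)))
      keep <- keep & !(times >= a$onset_s[i] & times < ends[i])
  }
  clean_s <- sum(keep) / record$fs
  if (clean_s < min_epoch_s) {
    return(structure(list(
      reason = sprintf("clean duration %.2f s below the %g s minimum",
                       clean_s, min_epoch_s),
      clean_duration = clean_s,
      patient_id = record$patient_id, timepoint = record$timepoint
    ), class = "epoch_rejection"))
  }
  structure(list(
    signal = record$signal[, keep, drop = FALSE],
    fs = record$fs,
    channel_labels = record$channel_labels,
    total_duration = clean_s,
    kept_samples = which(keep),
    patient_id = record$patient_id, timepoint = record$timepoint
  ), class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("EEG epoch: %d channels, %.2f s clean signal @ %g Hz\n",
              nrow(x$signal), x$total_duration, x$fs))
  invisible(x)
}

#' @export
print.epoch_rejection <- function(x, ...) {
  cat("EEG epoch rejected:", x$reason, "\n")
  invisible(x)
}

#' Segment an epoch into overlapping analysis windows
#'
#' Windows of duration `T_s` seconds are placed every `dt_s` seconds along
#' the assembled epoch, giving `floor((L - T_s)/dt_s) + 1` windows for an
#' epoch of length `L >= T_s`. Windows may span artifact-excision seams.
#'
#' @param epoch An `eeg_epoch` from [assemble_epoch()].
#' @param T_s Window duration in seconds (default 2.0).
#' @param dt_s Shift between consecutive windows in seconds (default 0.25).
#' @return A `window_set`: the epoch signal plus integer window start
#'   indices, window length and step, all in samples.
#' @export
make_windows <- function(epoch, T_s = 2.0, dt_s = 0.25) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  wlen <- T_s * epoch$fs
  step <- dt_s * epoch$fs
  if (abs(wlen - round(wlen)) > 1e-9 || abs(step - round(step)) > 1e-9)
    stop("T_s and dt_s must correspond to whole numbers of samples at fs = ",
         epoch$fs)
  wlen <- round(wlen); step <- round(step)
  n <- ncol(epoch$signal)
  if (n < wlen)
    stop(sprintf("epoch (%.2f s) shorter than the window duration (%g s)",
                 n / epoch$fs, T_s))
  n_win <- floor((n - wlen) / step) + 1
  starts <- (seq_len(n_win) - 1) * step + 1
  structure(list(
    signal = epoch$signal, fs = epoch$fs,
    channel_labels = epoch$channel_labels,
    starts = starts, wlen = wlen, step = step,
    T_s = T_s, dt_s = dt_s
  ), class = "window_set")
}

#' Number of windows in a window set
#' @param ws A `window_set`.
#' @export
n_windows <- function(ws) length(ws$starts)

#' Extract one window as a channels x samples matrix
#' @param ws A `window_set`.
#' @param k Window index.
#' @export
get_window <- function(ws, k) {
  stopifnot(k >= 1, k <= length(ws$starts))
  ws$signal[, ws$starts[k]:(ws$starts[k] + ws$wlen - 1), drop = FALSE]
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("Window set: %d windows of %g s every %g s (%d channels)\n",
              length(x$starts), x$T_s, x$dt_s, nrow(x$signal)))
  invisible(x)
}
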