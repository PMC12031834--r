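#' One-sided power spectral density of a single window
#'
#' Periodogram estimate via the FFT with a Hann taper and power-consistent
#' scaling: the integral of the returned PSD over `[0, fs/2]` recovers the
#' window's mean power (Parseval consistency), so band integrals are energies
#' in squared microvolts.
#'
#' @param x Numeric vector, one channel of one analysis window.
#' @param fs Sampling rate in Hz.
#' @param taper `"hann"` (default) or `"none"`.
#' @return List with `freq` (Hz, 0 to Nyquist) and `psd` (uV^2/Hz).
#' @export
window_psd <- function(x, fs, taper = c("hann", "none")) {
  taper <- match.arg(taper)
  if (any(!is.finite(x))) stop("window contains non-finite samples")
  n <- length(x)
  w <- if (taper == "hann") 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
       else rep(1, n)
  X <- stats::fft(x * w)
  raw <- Mod(X)^2 / (fs * sum(w^2))
  half <- floor(n / 2) + 1
  psd <- raw[seq_len(half)]
  # fold negative frequencies onto the positive axis (skip DC and Nyquist)
  last <- if (n %% 2 == 0) half - 1 else half
  psd[2:last] <- 2 * psd[2:last]
  list(freq = (seq_len(half) - 1) * fs / n, psd = psd)
}

# trapezoidal integral of psd over [lo, hi] using the grid points inside
.band_integral <- function(freq, psd, lo, hi) {
  idx <- which(freq >= lo - 1e-9 & freq <= hi + 1e-9)
  if (length(idx) < 2)
    stop(sprintf("frequency grid does not cover the %g-%g Hz band", lo, hi))
  f <- freq[idx]; p <- psd[idx]
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}

#' Band energies from a PSD
#'
#' Integrates the PSD over the delta `[2,4]`, theta `[4,8]`, alpha `[8,14]`
#' and beta `[14,30]` Hz bands (trapezoidal rule on the FFT grid), plus the
#' total `[0.5, 40]` Hz energy.
#'
#' @param spectrum A list with `freq` and `psd`, as from [window_psd()].
#' @return Named numeric vector: `E_delta`, `E_theta`, `E_alpha`, `E_beta`,
#'   `E_total`.
#' @export
band_energy <- function(spectrum) {
  freq <- spectrum$freq; psd <- spectrum$psd
  if (max(freq) < 40 || min(freq) > 0.5)
    stop("frequency grid must cover 0.5-40 Hz")
  e <- vapply(.eeg_bands, function(b)
    .band_integral(freq, psd, b[1], b[2]), numeric(1))
  c(E_delta = e[["delta"]], E_theta = e[["theta"]],
    E_alpha = e[["alpha"]], E_beta = e[["beta"]],
    E_total = .band_integral(freq, psd, 0.5, 40))
}

#' Amplitude-distribution entropy of a window
#'
#' Differential entropy (nats) of the sample-amplitude distribution,
#' estimated from a histogram with Freedman-Diaconis bin widths:
#' \eqn{H = -\sum_i p_i \log(p_i/h)}. Shift-invariant, and scales as
#' \eqn{H(aX) = H(X) + \log|a|} up to estimator error.
#'
#' @param x Numeric vector with at least 64 samples.
#' @return Entropy in nats; a constant (or effectively constant) signal
#'   returns `-Inf` with attribute `degenerate = TRUE`.
#' @export
signal_entropy <- function(x) {
  if (length(x) < 64) stop("entropy estimation needs at least 64 samples")
  if (any(!is.finite(x))) stop("window contains non-finite samples")
  h <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  if (h <= 0 || diff(range(x)) == 0)
    return(structure(-Inf, degenerate = TRUE))
  breaks <- seq(min(x) - h / 2, max(x) + h, by = h)
  counts <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts
  p <- counts[counts > 0] / length(x)
  -sum(p * log(p / h))
}

#' Higuchi fractal dimension of a window
#'
#' Standard Higuchi construction: for each scale `k = 1..kmax` and offset
#' `m = 1..k`, the normalized curve length
#' \eqn{L_m(k) = \frac{n-1}{\lfloor (n-m)/k \rfloor k^2}
#'      \sum_i |x_{m+ik} - x_{m+(i-1)k}|}
#' is averaged over offsets, and the dimension is the negative slope of
#' `log L(k)` against `log k` by least squares. Values range from 1 (smooth
#' curves) to 2 (noise-like signals); results outside `[1, 2]` by numerical
#' error are clipped with a warning. Invariant to amplitude scaling.
#'
#' @param x Numeric vector with at least 100 samples.
#' @param kmax Maximum scale (default 10).
#' @return The fractal dimension, a dimensionless value in `[1, 2]`.
#' @export
higuchi_fd <- function(x, kmax = 10) {
  n <- length(x)
  if (n < 100) stop("Higuchi FD needs at least 100 samples")
  if (kmax < 2) stop("kmax must be at least 2")
  if (any(!is.finite(x))) stop("window contains non-finite samples")
  Lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      i_max <- floor((n - m) / k)
      if (i_max < 1) { Lm[m] <- NA; next }
      idx <- m + (0:i_max) * k
      Lm[m] <- sum(abs(diff(x[idx]))) * (n - 1) / (i_max * k^2)
    }
    Lk[k] <- mean(Lm, na.rm = TRUE)
  }
  if (any(Lk <= 0)) return(structure(1, degenerate = TRUE))
  fit <- stats::lm.fit(cbind(1, log(seq_len(kmax))), log(Lk))
  fd <- -fit$coefficients[2]
  if (fd < 1 - 1e-6 || fd > 2 + 1e-6)
    warning(sprintf("Higuchi FD %.3f outside [1, 2]; clipped", fd))
  unname(min(max(fd, 1), 2))
}

#' Compute window-level quantitative features for an epoch
#'
#' Runs [window_psd()]/[band_energy()], [signal_entropy()] and
#' [higuchi_fd()] on every (window, channel) pair of a window set.
#'
#' @param ws A `window_set` from [make_windows()].
#' @param features Character subset of `c("energy", "entropy", "fd")`.
#' @param kmax Higuchi scale limit.
#' @return List of matrices (windows x channels), one per feature
#'   (`E_delta`, ..., `E_total`, `H`, `F`), with a `fs` attribute.
#' @export
window_features <- function(ws, features = c("energy", "entropy", "fd"),
                            kmax = 10) {
  stopifnot(inherits(ws, "window_set"))
  features <- match.arg(features, several.ok = TRUE)
  nw <- length(ws$starts); nc <- nrow(ws$signal)
  out <- list()
  if ("energy" %in% features) {
    # one FFT call for all windows x channels of this epoch
    n <- ws$wlen
    w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
    cols <- matrix(0, n, nw * nc)
    for (k in seq_len(nw)) {
      blk <- t(ws$signal[, ws$starts[k]:(ws$starts[k] + n - 1), drop = FALSE])
      cols[, (k - 1) * nc + seq_len(nc)] <- blk * w
    }
    X <- stats::mvfft(cols)
    half <- floor(n / 2) + 1
    raw <- Mod(X[seq_len(half), , drop = FALSE])^2 / (ws$fs * sum(w^2))
    last <- if (n %% 2 == 0) half - 1 else half
    raw[2:last, ] <- 2 * raw[2:last, ]
    freq <- (seq_len(half) - 1) * ws$fs / n
    bands <- c(.eeg_bands, list(total = c(0.5, 40)))
    names(bands) <- c("E_delta", "E_theta", "E_alpha", "E_beta", "E_total")
    for (bn in names(bands)) {
      b <- bands[[bn]]
      idx <- which(freq >= b[1] - 1e-9 & freq <= b[2] + 1e-9)
      df <- diff(freq[idx])
      vals <- colSums(raw[idx[-1], , drop = FALSE] * df +
                      raw[idx[-length(idx)], , drop = FALSE] * df) / 2
      out[[bn]] <- matrix(vals, nw, nc, byrow = TRUE)
    }
  }
  if ("entropy" %in% features) {
    H <- matrix(NA_real_, nw, nc)
    for (k in seq_len(nw)) {
      win <- get_window(ws, k)
      for (ch in seq_len(nc)) H[k, ch] <- as.numeric(signal_entropy(win[ch, ]))
    }
    out$H <- H
  }
  if ("fd" %in% features) {
    F_ <- matrix(NA_real_, nw, nc)
    for (k in seq_len(nw)) {
      win <- get_window(ws, k)
      for (ch in seq_len(nc)) F_[k, ch] <- higuchi_fd(win[ch, ], kmax = kmax)
    }
    out$F <- F_
  }
  attr(out, "fs") <- ws$fs
  out
}

#' Summarize window-level features into per-record medians
#'
#' Takes the median of each feature over all (window, channel) pairs jointly
#' and derives the slowing ratio DTAR = (E_delta + E_theta) / E_alpha from
#' the summarized energies. One scalar per feature per record.
#'
#' @param wf Window-level features from [window_features()], or any named
#'   list of numeric matrices/vectors.
#' @param connectivity Optional named numeric vector of connectivity
#'   summaries (e.g. from [connectivity_summary()]) appended as-is.
#' @return An object of class `record_features`: named list of medians with
#'   `DTAR` and a `normalized` flag (FALSE).
#' @export
summarize_record <- function(wf, connectivity = NULL) {
  if (length(wf) == 0 || any(!vapply(wf, length, integer(1))))
    stop("empty window-level feature set")
  meds <- lapply(wf, function(m) stats::median(as.numeric(m)))
  names(meds) <- paste0("med_", names(wf))
  out <- meds
  if (all(c("med_E_delta", "med_E_theta", "med_E_alpha") %in% names(out))) {
    if (out$med_E_alpha <= 0)
      stop("DTAR undefined: median alpha energy is not positive")
    out$DTAR <- (out$med_E_delta + out$med_E_theta) / out$med_E_alpha
  }
  if (!is.null(connectivity)) out[names(connectivity)] <- connectivity
  out$normalized <- FALSE
  structure(out, class = "record_features")
}

#' @export
print.record_features <- function(x, ...) {
  cat("Record features", if (isTRUE(x$normalized)) "(baseline-normalized)",
      "\n")
  nm <- setdiff(names(x), "normalized")
  for (n in nm) cat(sprintf("  %-14s %.4g\n", n, x[[n]]))
  invisible(x)
}

#' Normalize post-infusion record features to the patient's baseline
#'
#' Replaces every numeric feature by the post/baseline ratio, making values
#' comparable across patients. Both inputs must be unnormalized, and every
#' baseline feature entering a ratio must be strictly positive.
#'
#' @param post,baseline `record_features` objects from [summarize_record()].
#' @return A `record_features` object with `normalized = TRUE`.
#' @export
normalize_to_baseline <- function(post, baseline) {
  stopifnot(inherits(post, "record_features"),
            inherits(baseline, "record_features"))
  if (isTRUE(post$normalized) || isTRUE(baseline$normalized))
    stop("both inputs must be unnormalized record features")
  feats <- intersect(setdiff(names(post), "normalized"),
                     setdiff(names(baseline), "normalized"))
  out <- list()
  for (f in feats) {
    b <- baseline[[f]]
    if (!is.finite(b) || b <= 0)
      stop("cannot normalize: baseline feature ", f,
           " is zero, negative or degenerate")
    out[[f]] <- post[[f]] / b
  }
  out$normalized <- TRUE
  structure(out, class = "record_features")
}
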