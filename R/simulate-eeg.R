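# Frequency bands (Hz) used throughout: delta [2,4], theta [4,8],
# alpha [8,14], beta [14,30].
.eeg_bands <- list(delta = c(2, 4), theta = c(4, 8),
                   alpha = c(8, 14), beta = c(14, 30))

# Run `expr` with the RNG seeded at `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  expr
}

#' Specify a synthetic multichannel EEG
#'
#' Describes a band-structured scalp EEG: per-band sinusoidal oscillators with
#' randomized frequency and phase, 1/f (pink) background noise, optional
#' directed lagged couplings between channels, and high-amplitude artifact
#' transients covering a set fraction of the recording.
#'
#' @param n_channels Number of channels (default 19, labelled by the 10-20
#'   montage).
#' @param fs Sampling rate in Hz; must be at least 80 Hz so that content up
#'   to the 40 Hz band edge is representable.
#' @param duration Recording length in seconds.
#' @param band_amplitudes Named amplitudes (microvolts) for the delta, theta,
#'   alpha and beta oscillators. The default is a posterior-dominant-alpha
#'   normal background.
#' @param pink_noise_amp RMS amplitude (microvolts) of the 1/f noise floor.
#' @param couplings List of couplings, each `list(from =, to =, lag =, gain =)`
#'   with channel indices, a lag in samples, and a gain: the target channel
#'   receives a lagged scaled copy of the source's oscillatory content.
#' @param artifact_fraction Fraction of the duration (in `[0, 1)`) covered by
#'   artifact transients (0.5-3 s bursts at ten times the signal scale).
#' @param seed Integer seed; identical specs with identical seeds simulate
#'   bit-identical output.
#' @return An object of class `eeg_sim_spec`.
#' @seealso [simulate_eeg()]
#' @export
eeg_sim_spec <- function(n_channels = 19, fs = 128, duration = 60,
                         band_amplitudes = c(delta = 0, theta = 2,
                                             alpha = 20, beta = 3),
                         pink_noise_amp = 5,
                         couplings = list(),
                         artifact_fraction = 0,
                         seed = 1L) {
  stopifnot(n_channels >= 1, duration > 0)
  if (fs < 80)
    stop("fs must be >= 80 Hz to represent content up to 40 Hz")
  if (artifact_fraction < 0 || artifact_fraction >= 1)
    stop("artifact_fraction must lie in [0, 1)")
  amps <- c(delta = 0, theta = 0, alpha = 0, beta = 0)
  amps[names(band_amplitudes)] <- band_amplitudes
  if (any(amps < 0)) stop("band amplitudes must be non-negative")
  for (cp in couplings) {
    if (!all(c("from", "to", "lag", "gain") %in% names(cp)))
      stop("each coupling needs from, to, lag and gain")
    if (cp$from < 1 || cp$from > n_channels ||
        cp$to < 1 || cp$to > n_channels || cp$from == cp$to)
      stop("coupling references an invalid channel pair: ",
           cp$from, " -> ", cp$to)
    if (cp$lag < 0 || cp$lag >= duration * fs)
      stop("coupling lag outside the record")
  }
  structure(list(
    n_channels = n_channels, fs = fs, duration = duration,
    band_amplitudes = amps, pink_noise_amp = pink_noise_amp,
    couplings = couplings, artifact_fraction = artifact_fraction,
    seed = seed
  ), class = "eeg_sim_spec")
}

# 1/f amplitude spectrum noise by spectral shaping of white noise,
# rescaled to the requested RMS.
.pink_noise <- function(n, rms) {
  if (rms <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)           # symmetric frequency index
  scale <- ifelse(f == 0, 0, 1 / sqrt(f))
  x <- Re(stats::fft(spec * scale, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

#' Simulate a multichannel EEG record with artifact annotations
#'
#' Each channel is a sum of band-limited sinusoidal oscillators (one per band
#' with non-zero amplitude, frequency drawn uniformly within the band,
#' random phase) plus pink noise. Coupled target channels additionally
#' receive a lagged, scaled copy of the source channel's oscillatory
#' content. Artifact intervals are 0.5-3 s bursts of ten-fold-amplitude
#' noise, returned as annotations rather than removed.
#'
#' @param spec An [eeg_sim_spec()].
#' @param patient_id,timepoint,record_day Metadata passed to [eeg_record()].
#' @return List with `record` (an [eeg_record()]) and `artifacts` (data frame
#'   with `onset_s`, `duration_s`, `label`).
#' @export
simulate_eeg <- function(spec, patient_id = "sim", timepoint = "extra",
                         record_day = NA_real_) {
  stopifnot(inherits(spec, "eeg_sim_spec"))
  with_seed(spec$seed, {
    n <- round(spec$duration * spec$fs)
    t <- (seq_len(n) - 1) / spec$fs
    osc <- matrix(0, spec$n_channels, n)   # oscillatory (band) content
    for (ch in seq_len(spec$n_channels)) {
      for (b in names(.eeg_bands)) {
        a <- spec$band_amplitudes[[b]]
        if (a > 0) {
          lim <- .eeg_bands[[b]]
          margin <- 0.1 * diff(lim)
          f <- stats::runif(1, lim[1] + margin, lim[2] - margin)
          phi <- stats::runif(1, 0, 2 * pi)
          osc[ch, ] <- osc[ch, ] + a * sin(2 * pi * f * t + phi)
        }
      }
    }
    sig <- osc
    for (cp in spec$couplings) {
      lagged <- c(numeric(cp$lag), osc[cp$from, seq_len(n - cp$lag)])
      sig[cp$to, ] <- sig[cp$to, ] + cp$gain * lagged
    }
    if (spec$pink_noise_amp > 0)
      for (ch in seq_len(spec$n_channels))
        sig[ch, ] <- sig[ch, ] + .pink_noise(n, spec$pink_noise_amp)

    artifacts <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                            label = character(0))
    if (spec$artifact_fraction > 0) {
      target <- spec$artifact_fraction * spec$duration
      amp <- 10 * max(spec$band_amplitudes, spec$pink_noise_amp, 1)
      covered <- 0
      tries <- 0
      while (covered < target && tries < 1000) {
        tries <- tries + 1
        dur <- stats::runif(1, 0.5, min(3, max(0.5, target - covered + 0.5)))
        onset <- stats::runif(1, 0, spec$duration - dur)
        overlaps <- nrow(artifacts) > 0 &&
          any(onset < artifacts$onset_s + artifacts$duration_s &
              artifacts$onset_s < onset + dur)
        if (!overlaps) {
          artifacts <- rbind(artifacts,
                             data.frame(onset_s = onset, duration_s = dur,
                                        label = "artifact"))
          i0 <- floor(onset * spec$fs) + 1
          i1 <- min(n, floor((onset + dur) * spec$fs))
          burst <- matrix(stats::rnorm(spec$n_channels * (i1 - i0 + 1),
                                       sd = amp),
                          spec$n_channels)
          sig[, i0:i1] <- sig[, i0:i1] + burst
          covered <- covered + dur
        }
      }
      artifacts <- artifacts[order(artifacts$onset_s), , drop = FALSE]
      rownames(artifacts) <- NULL
    }
    labels <- if (spec$n_channels <= 19) montage_10_20[seq_len(spec$n_channels)]
              else paste0("Ch", seq_len(spec$n_channels))
    rec <- eeg_record(sig, spec$fs, channel_labels = labels,
                      patient_id = patient_id, timepoint = timepoint,
                      record_day = record_day)
    list(record = rec, artifacts = artifacts)
  })
}

#' Write artifact annotations to CSV
#'
#' @param artifacts Data frame with `onset_s`, `duration_s`, `label`.
#' @param path Output CSV path.
#' @export
write_artifacts_csv <- function(artifacts, path) {
  utils::write.csv(artifacts, path, row.names = FALSE)
  invisible(path)
}

#' Read artifact annotations from CSV
#' @param path CSV with columns `onset_s`, `duration_s` and optionally `label`.
#' @export
read_artifacts_csv <- function(path) {
  a <- utils::read.csv(path)
  if (!all(c("onset_s", "duration_s") %in% names(a)))
    stop("annotation CSV must have onset_s and duration_s columns")
  a
}
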