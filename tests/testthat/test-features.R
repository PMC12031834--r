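tone <- function(f, fs = 256, n = 2 * fs, A = 1) {
  A * sin(2 * pi * f * (seq_len(n) - 1) / fs)
}

test_that("PSD of a tone is Parseval-consistent and concentrated", {
  fs <- 256
  x <- tone(10, fs, A = 3)
  sp <- window_psd(x, fs)
  total <- sum(diff(sp$freq) * (sp$psd[-1] + sp$psd[-length(sp$psd)]) / 2)
  expect_lt(abs(total - 3^2 / 2) / (3^2 / 2), 0.01)
  # spectral mass concentrated near 10 Hz
  near <- sp$freq >= 9 & sp$freq <= 11
  expect_gt(sum(sp$psd[near]) / sum(sp$psd), 0.99)
})

test_that("PSD of the zero signal is zero and NaNs are refused", {
  sp <- window_psd(numeric(512), 256)
  expect_true(all(sp$psd == 0))
  expect_error(window_psd(c(rnorm(100), NA), 256), "non-finite")
})

test_that("mean white-noise PSD is flat at sigma^2/Nyquist", {
  set.seed(1)
  fs <- 256
  acc <- numeric(fs + 1)
  for (i in 1:1000) acc <- acc + window_psd(rnorm(2 * fs), fs)$psd
  m <- acc / 1000
  mid <- m[10:120 * 2]   # away from DC and Nyquist
  expect_lt(abs(mean(mid) - 1 / 128) / (1 / 128), 0.05)
})

test_that("band energies integrate the right intervals", {
  fs <- 256
  be6 <- band_energy(window_psd(tone(6, fs), fs))
  expect_gt(be6[["E_theta"]] /
              sum(be6[c("E_delta", "E_theta", "E_alpha", "E_beta")]), 0.95)
  # DTAR direction: 6 Hz tone slows, 10 Hz tone does not
  be10 <- band_energy(window_psd(tone(10, fs), fs))
  dtar6 <- (be6[["E_delta"]] + be6[["E_theta"]]) / be6[["E_alpha"]]
  dtar10 <- (be10[["E_delta"]] + be10[["E_theta"]]) / be10[["E_alpha"]]
  expect_gt(dtar6, 100)
  expect_lt(dtar10, 0.01)
  # coverage guard
  expect_error(band_energy(list(freq = seq(0, 20, 0.5),
                                psd = rep(1, 41))), "cover")
})

test_that("white-noise beta/delta energy ratio equals the bandwidth ratio", {
  set.seed(2)
  fs <- 256
  eb <- 0; ed <- 0
  for (i in 1:1000) {
    be <- band_energy(window_psd(rnorm(2 * fs), fs))
    eb <- eb + be[["E_beta"]]; ed <- ed + be[["E_delta"]]
  }
  expect_lt(abs(eb / ed - 8) / 8, 0.1)
})

test_that("band energies never exceed the total in-band energy", {
  set.seed(3)
  fs <- 128
  for (i in 1:20) {
    be <- band_energy(window_psd(rnorm(2 * fs), fs))
    expect_true(all(be >= 0))
    expect_lte(be[["E_delta"]] + be[["E_theta"]] + be[["E_alpha"]] +
                 be[["E_beta"]], be[["E_total"]] + 1e-12)
  }
})

test_that("amplitude entropy matches the Gaussian closed form and scaling", {
  set.seed(4)
  hs <- replicate(1000, signal_entropy(rnorm(512)))
  expect_lt(abs(mean(hs) - 0.5 * log(2 * pi * exp(1))), 0.1)

  set.seed(5)
  dh <- replicate(300, {
    x <- rnorm(512)
    signal_entropy(2 * x) - signal_entropy(x)
  })
  expect_lt(abs(mean(dh) - log(2)), 0.05)

  # shift invariance is exact up to binning
  set.seed(6)
  x <- rnorm(512)
  expect_lt(abs(signal_entropy(x + 100) - signal_entropy(x)), 1e-9)

  h0 <- signal_entropy(rep(1, 512))
  expect_identical(as.numeric(h0), -Inf)
  expect_true(attr(h0, "degenerate"))
  expect_error(signal_entropy(rnorm(32)), "64")
})

test_that("Higuchi FD separates smooth tones from white noise", {
  fs <- 256
  expect_lt(abs(higuchi_fd(tone(2, fs, n = 512)) - 1), 0.1)
  set.seed(7)
  fds <- replicate(200, suppressWarnings(higuchi_fd(rnorm(512))))
  expect_lt(abs(mean(fds) - 2), 0.1)
  expect_true(all(fds >= 1 & fds <= 2))
})

test_that("Higuchi FD equals an independent transcription of the sums", {
  set.seed(8)
  for (i in 1:10) {
    x <- cumsum(rnorm(300))
    expect_equal(higuchi_fd(x, kmax = 8), oracle_higuchi(x, kmax = 8),
                 tolerance = 1e-10)
  }
})

test_that("Higuchi FD is exactly invariant under amplitude scaling", {
  set.seed(9)
  x <- rnorm(256)
  expect_equal(suppressWarnings(higuchi_fd(5 * x)),
               suppressWarnings(higuchi_fd(x)))
  expect_error(higuchi_fd(rnorm(50)), "100")
})

test_that("record summaries are joint medians with derived DTAR", {
  wf <- list(E_delta = matrix(c(1, 2, 3, 4, 5, 6), 3, 2),
             E_theta = matrix(rep(2, 6), 3, 2),
             E_alpha = matrix(rep(4, 6), 3, 2))
  rf <- summarize_record(wf)
  expect_equal(rf$med_E_delta, 3.5)           # median of 1..6
  expect_equal(rf$med_E_theta, 2)
  expect_equal(rf$DTAR, (3.5 + 2) / 4)
  expect_false(rf$normalized)

  # odd count: middle order statistic
  wf2 <- list(H = matrix(c(9, 1, 5), 1, 3))
  expect_equal(summarize_record(wf2)$med_H, 5)

  expect_error(summarize_record(list()), "empty")
  expect_error(summarize_record(list(E_delta = 1, E_theta = 1,
                                     E_alpha = 0)), "alpha")
})

test_that("features are invariant to channel ordering", {
  sp <- eeg_sim_spec(n_channels = 3, fs = 128, duration = 21, seed = 10)
  rec <- simulate_eeg(sp)$record
  ep <- assemble_epoch(rec, NULL)
  rf1 <- summarize_record(window_features(make_windows(ep),
                                          features = "energy"))
  ep2 <- ep
  perm <- c(3, 1, 2)
  ep2$signal <- ep$signal[perm, ]
  ep2$channel_labels <- ep$channel_labels[perm]
  rf2 <- summarize_record(window_features(make_windows(ep2),
                                          features = "energy"))
  expect_equal(rf1$med_E_theta, rf2$med_E_theta)
  expect_equal(rf1$DTAR, rf2$DTAR)
})

test_that("baseline normalization is a guarded per-feature ratio", {
  wf <- list(E_delta = 2, E_theta = 4, E_alpha = 8)
  base <- summarize_record(wf)
  post <- summarize_record(list(E_delta = 2, E_theta = 8, E_alpha = 8))
  norm <- normalize_to_baseline(post, base)
  expect_true(norm$normalized)
  expect_equal(norm$med_E_theta, 2)
  expect_equal(norm$med_E_delta, 1)

  ident <- normalize_to_baseline(base, base)
  expect_true(all(vapply(setdiff(names(ident), "normalized"),
                         function(f) ident[[f]] == 1, logical(1))))

  zero <- summarize_record(list(E_delta = 0, E_theta = 4, E_alpha = 8))
  expect_error(normalize_to_baseline(post, zero), "med_E_delta")
  expect_error(normalize_to_baseline(norm, base), "unnormalized")
})

test_that("simulated slowing raises theta energy and DTAR monotonically", {
  # raise only the theta oscillator amplitude, everything else fixed
  vals <- lapply(c(4, 10, 16, 22), function(theta_amp) {
    amps <- c(delta = 2, theta = theta_amp, alpha = 20, beta = 3)
    sp <- eeg_sim_spec(n_channels = 2, fs = 128, duration = 21,
                       band_amplitudes = amps, pink_noise_amp = 5,
                       seed = 20)
    f <- features_from_sim(sp)
    c(theta = f$med_E_theta, dtar = f$DTAR, beta_frac = f$med_E_beta /
        f$med_E_total)
  })
  theta <- vapply(vals, `[[`, numeric(1), "theta")
  dtar <- vapply(vals, `[[`, numeric(1), "dtar")
  beta_frac <- vapply(vals, `[[`, numeric(1), "beta_frac")
  expect_true(all(diff(theta) > 0))
  expect_true(all(diff(dtar) > 0))
  expect_true(all(diff(beta_frac) < 0))
})
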