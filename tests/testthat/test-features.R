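test_that("the Welch PSD localizes tones and satisfies Parseval", {
  x <- sinusoid(10, duration = 3)
  psd <- power_spectrum(x, fs_default)
  expect_equal(psd$freq[which.max(psd$power)], 10)
  # Parseval within 10% on band-limited noise
  set.seed(4)
  y <- eareeg:::fft_band_noise(3 * fs_default, fs_default, 2, 40)
  psd_y <- power_spectrum(y, fs_default)
  df <- psd_y$freq[2] - psd_y$freq[1]
  expect_lt(abs(sum(psd_y$power) * df / var(y) - 1), 0.10)
  # white noise: spectrum roughly flat (smoothed decile ratio < 3)
  set.seed(5)
  w <- rnorm(60 * fs_default)
  psd_w <- power_spectrum(w, fs_default)
  dec <- quantile(psd_w$power[psd_w$freq > 0], c(0.1, 0.9))
  expect_lt(dec[2] / dec[1], 3)
  expect_true(all(power_spectrum(rep(0, 1500), fs_default)$power == 0))
  expect_error(power_spectrum(rnorm(100), fs_default), "1 s")
})

test_that("Hjorth parameters match analytic values for tones and noise", {
  x <- sinusoid(10, duration = 3)
  hj <- hjorth_parameters(x, fs_default)
  expect_equal(unname(hj["mobility"]), 2 * pi * 10, tolerance = 0.02)
  expect_equal(unname(hj["complexity"]), 1, tolerance = 0.02)
  set.seed(6)
  g <- rnorm(60 * fs_default, sd = 5)
  expect_equal(unname(hjorth_parameters(g, fs_default)["activity"]), 25,
               tolerance = 0.10)
  expect_warning(h0 <- hjorth_parameters(rep(3, 100), fs_default), "constant")
  expect_true(is.nan(h0[["complexity"]]))
})

test_that("band metrics normalize, localize, and satisfy Parseval per band", {
  x <- sinusoid(10, duration = 3, amplitude = 2)
  bm <- band_metrics(power_spectrum(x, fs_default), x, fs_default)
  expect_equal(sum(bm$relative_power), 1, tolerance = 1e-9)
  expect_gte(bm$relative_power[bm$band == "alpha"], 0.9)
  # band RMS^2 ~ band power for Gaussian signals
  set.seed(7)
  prof <- subject_profile("s")
  g <- synthesize_recording(prof, condition_spec("eyes_open"),
                            duration = 60, seed = 8)$signal[[1]]
  bmg <- band_metrics(power_spectrum(g, fs_default, window_sec = 4), g, fs_default)
  expect_true(all(abs(bmg$rms^2 / bmg$power - 1) < 0.15))
  expect_error(band_metrics(tibble::tibble(freq = 0:100, power = rep(0, 101)),
                            rep(0, 1500), fs_default), "zero total power")
})

test_that("spectral edge matches the analytic quantile of known spectra", {
  flat <- tibble::tibble(freq = seq(1, 49, by = 0.1), power = 1)
  expect_equal(spectral_edge(flat, 95), 1 + 0.95 * 48, tolerance = 0.11)
  expect_equal(spectral_edge(flat, 100), 49)
  tone <- power_spectrum(sinusoid(10, duration = 3), fs_default)
  expect_equal(spectral_edge(tone, 95, range = c(0.1, 45)), 10, tolerance = 1)
  # monotone in percent
  edges <- vapply(c(25, 50, 75, 95), function(p) spectral_edge(flat, p), 1)
  expect_true(all(diff(edges) >= 0))
  expect_error(spectral_edge(flat, 0), "percent")
  expect_error(spectral_edge(tibble::tibble(freq = 1:10, power = rep(0, 10)), 50),
               "zero total power")
})

test_that("the feature vector has the full 35-name roster and expected symmetries", {
  expect_equal(nrow(feature_roster()), 35)
  x <- sinusoid(10, duration = 3, amplitude = 3)
  f <- extract_features(x, fs_default)
  expect_length(f, 35)
  expect_identical(names(f), feature_roster()$name)
  expect_true(all(c("Root-mean-square value, gamma band",
                    "Relative power, theta band",
                    "Mobility, overall signal",
                    "Root-mean-square value, non-gamma bands",
                    "Sum of absolute derivative, overall signal",
                    "Weighted average power, overall signal") %in% names(f)))
  expect_equal(f[["Skewness"]], 0, tolerance = 1e-6)
})

test_that("feature scale behaviour: invariants stay put, amplitudes scale", {
  set.seed(9)
  x <- sinusoid(10, duration = 3, amplitude = 4) + rnorm(1500, sd = 0.5)
  f1 <- extract_features(x, fs_default)
  f2 <- extract_features(3.7 * x, fs_default)
  invariant <- c("Skewness", "Kurtosis", "Mobility, overall signal",
                 "Complexity, overall signal",
                 paste0("Relative power, ", eeg_bands()$band, " band"),
                 "Spectral edge frequency, 50%", "Spectral edge frequency, 95%",
                 "Weighted average power, overall signal",
                 "Alpha/beta power ratio")
  for (nm in invariant) {
    expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-6, label = nm)
  }
  for (nm in c("Standard deviation", "Root-mean-square value, overall signal",
               "Root-mean-square value, alpha band")) {
    expect_equal(f2[[nm]] / f1[[nm]], 3.7, tolerance = 1e-6, label = nm)
  }
  for (nm in c("Activity, overall signal", "Absolute power, alpha band",
               "Total power")) {
    expect_equal(f2[[nm]] / f1[[nm]], 3.7^2, tolerance = 1e-6, label = nm)
  }
})

test_that("feature extraction is finite on 10,000 synthetic pass-QC segments", {
  study <- generate_stress_study(84, seed = 13,
                                 artifact_rates = c(motion = 0, muscle = 0))
  segs <- qc_segments(segment_recordings(apply_filters(study)))
  segs <- head(segs[segs$qc_status == "pass", ], 10000)
  feats <- suppressMessages(compute_features(segs))
  X <- as.matrix(feats[, feature_roster()$key])
  expect_gte(nrow(X), 9900)
  expect_true(all(is.finite(X)))
})

test_that("Welch band power agrees with a direct periodogram oracle", {
  set.seed(14)
  deviations <- vapply(1:10, function(i) {
    x <- rnorm(3 * fs_default)
    psd_w <- power_spectrum(x, fs_default)
    # periodogram oracle: single rectangular window
    n <- length(x)
    spec <- Mod(fft(x - mean(x)))^2 / (n * fs_default)
    k <- floor(n / 2) + 1
    per <- tibble::tibble(freq = (seq_len(k) - 1) * fs_default / n,
                          power = spec[seq_len(k)] * c(1, rep(2, k - 2), 1))
    a <- eareeg:::integrate_psd(psd_w, 4, 32)
    b <- eareeg:::integrate_psd(per, 4, 32)
    abs(a / b - 1)
  }, numeric(1))
  expect_lt(max(deviations), 0.20)
})

test_that("failed-QC segments are refused by the feature stage", {
  segs <- qc_segments(toy_qc_segments())
  expect_message(f <- compute_features(segs), "dropping 30")
  expect_equal(nrow(f), 70)
  all_bad <- segs[segs$qc_status == "flat", ]
  expect_error(suppressMessages(compute_features(all_bad)), "no QC-passed")
})
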