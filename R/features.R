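# The 35-feature bank: statistical, Hjorth, and frequency-domain features.

#' The 35-feature roster
#'
#' Fixed-order listing of all features computed by [extract_features()]:
#' a column key used in feature tables, the display name used in reports
#' (matching the field's naming, e.g. "Root-mean-square value, alpha band"),
#' and the feature group.
#'
#' @return A 35-row tibble with columns `key`, `name`, `group`.
#' @export
feature_roster <- function() {
  bands <- eeg_bands()$band
  cap <- function(b) b # band names stay lowercase in display names
  tibble(
    key = c(
      "mean_uv", "std_uv", "skewness", "kurtosis", "peak_to_peak", "rms_overall",
      "line_length", "zero_crossing_rate",
      "activity", "mobility", "complexity",
      paste0("power_", bands),
      paste0("relpower_", bands),
      paste0("rms_", bands),
      "rms_nongamma", "total_power",
      "sef50", "sef90", "sef95",
      "weighted_avg_power",
      "ratio_alpha_beta", "ratio_theta_alpha", "ratio_beta_alphatheta"
    ),
    name = c(
      "Mean", "Standard deviation", "Skewness", "Kurtosis",
      "Peak-to-peak amplitude", "Root-mean-square value, overall signal",
      "Sum of absolute derivative, overall signal", "Zero-crossing rate",
      "Activity, overall signal", "Mobility, overall signal",
      "Complexity, overall signal",
      paste0("Absolute power, ", cap(bands), " band"),
      paste0("Relative power, ", cap(bands), " band"),
      paste0("Root-mean-square value, ", cap(bands), " band"),
      "Root-mean-square value, non-gamma bands", "Total power",
      "Spectral edge frequency, 50%", "Spectral edge frequency, 90%",
      "Spectral edge frequency, 95%",
      "Weighted average power, overall signal",
      "Alpha/beta power ratio", "Theta/alpha power ratio",
      "Beta/(alpha+theta) power ratio"
    ),
    group = c(
      rep("statistical", 8), rep("hjorth", 3),
      rep("band_power", 5), rep("relative_power", 5), rep("band_rms", 5),
      "band_rms", "band_power", rep("spectral_edge", 3), "spectral",
      rep("ratio", 3)
    )
  )
}

#' Welch power spectral density
#'
#' One-sided Welch estimate with Hann windows (`window_sec` seconds,
#' `overlap` fractional overlap, per-window mean removal), in uV^2/Hz.
#' A 3 s segment with the defaults yields 5 averaged windows at 1 Hz
#' resolution. Satisfies Parseval: the PSD integral approximates the signal
#' variance.
#'
#' @param x Numeric signal in uV.
#' @param fs Sampling rate in Hz.
#' @param window_sec Window length in seconds (default 1).
#' @param overlap Fractional window overlap (default 0.5).
#' @return A tibble with columns `freq` (Hz) and `power` (uV^2/Hz).
#' @export
power_spectrum <- function(x, fs, window_sec = 1, overlap = 0.5) {
  check_number(fs, "fs", lower = 1e-9)
  n <- length(x)
  if (n < fs * 1) abort("segment must be at least 1 s long.")
  nw <- round(window_sec * fs)
  nw <- min(nw, n)
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, n - nw + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1)) # Hann
  scale <- 1 / (fs * sum(w^2))
  n_freq <- floor(nw / 2) + 1L
  acc <- numeric(n_freq)
  for (s in starts) {
    seg <- x[s:(s + nw - 1L)]
    seg <- (seg - mean(seg)) * w
    spec <- fft(seg)[seq_len(n_freq)]
    acc <- acc + Mod(spec)^2 * scale
  }
  pxx <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nw is even)
  dbl <- rep(2, n_freq)
  dbl[1] <- 1
  if (nw %% 2 == 0) dbl[n_freq] <- 1
  tibble(freq = (seq_len(n_freq) - 1) * fs / nw, power = pxx * dbl)
}

#' Hjorth parameters
#'
#' Activity is the signal variance; mobility is
#' `sqrt(var(dx) / var(x))` with `dx` the first difference scaled by `fs`
#' (units rad/s in the continuous limit, so a pure sinusoid at `f` Hz has
#' mobility ~ `2*pi*f`); complexity is the mobility of the derivative over
#' the mobility of the signal (1 for a pure sinusoid).
#'
#' @inheritParams power_spectrum
#' @return A named numeric vector `c(activity, mobility, complexity)`.
#' @export
hjorth_parameters <- function(x, fs) {
  act <- var(x)
  if (act == 0) {
    warn("constant segment: Hjorth mobility/complexity undefined.")
    return(c(activity = 0, mobility = NaN, complexity = NaN))
  }
  dx <- diff(x) * fs
  d2x <- diff(dx) * fs
  mob <- sqrt(var(dx) / act)
  mob_d <- sqrt(var(d2x) / var(dx))
  c(activity = act, mobility = mob, complexity = mob_d / mob)
}

# RMS of the band-limited component of x over [lo, hi), via an ideal
# frequency-domain mask (a bandpass realization with brickwall edges).
band_rms_vector <- function(x, fs, lo, hi) {
  n <- length(x)
  freq <- seq(0, n - 1) * fs / n
  freq <- pmin(freq, fs - freq)
  spec <- fft(x - mean(x))
  spec[!(freq >= lo & freq < hi)] <- 0
  y <- Re(fft(spec, inverse = TRUE)) / n
  sqrt(mean(y^2))
}

integrate_psd <- function(psd, lo, hi) {
  df <- psd$freq[2] - psd$freq[1]
  sum(psd$power[psd$freq >= lo & psd$freq < hi]) * df
}

#' Per-band spectral metrics
#'
#' Absolute band power (PSD integral over `[lo, hi)`), relative power
#' (band power over the total power in 0.1-45 Hz; the five bands tile that
#' range so relative powers sum to one), and band RMS (RMS of the
#' band-limited time signal).
#'
#' @param psd A PSD tibble from [power_spectrum()].
#' @param x The segment samples the PSD was computed from (for band RMS).
#' @param fs Sampling rate in Hz.
#' @param bands Band definition tibble, default [eeg_bands()].
#' @return A tibble with columns `band`, `power`, `relative_power`, `rms`.
#' @export
band_metrics <- function(psd, x, fs, bands = eeg_bands()) {
  total <- integrate_psd(psd, min(bands$lo), max(bands$hi))
  if (total <= 0) abort("zero total power: relative band powers undefined.")
  pow <- map_dbl(seq_len(nrow(bands)),
                 function(i) integrate_psd(psd, bands$lo[i], bands$hi[i]))
  rms <- map_dbl(seq_len(nrow(bands)),
                 function(i) band_rms_vector(x, fs, bands$lo[i], bands$hi[i]))
  tibble(band = bands$band, power = pow, relative_power = pow / total, rms = rms)
}

#' Spectral edge frequency
#'
#' The smallest grid frequency below which at least `percent`% of the total
#' spectral power lies. With `range = NULL` the whole PSD grid is used;
#' the feature bank restricts to the 0.1-45 Hz analysis range.
#'
#' @param psd A PSD tibble (`freq`, `power`).
#' @param percent Percentage of total power, in (0, 100].
#' @param range Optional `c(lo, hi)` frequency range restriction (half-open).
#' @return The edge frequency in Hz.
#' @export
spectral_edge <- function(psd, percent, range = NULL) {
  check_number(percent, "percent", lower = 1e-9, upper = 100)
  if (!is.null(range)) {
    psd <- psd[psd$freq >= range[1] & psd$freq < range[2], , drop = FALSE]
  }
  total <- sum(psd$power)
  if (total <= 0) abort("zero total power: spectral edge undefined.")
  cum <- cumsum(psd$power) / total
  psd$freq[which(cum >= percent / 100 - 1e-12)[1]]
}

skewness_ <- function(x) e1071::skewness(x, type = 2)
kurtosis_ <- function(x) e1071::kurtosis(x, type = 2) # excess kurtosis

#' Extract the 35-feature vector from one segment
#'
#' Computes the full feature bank of [feature_roster()]: statistical moments
#' and amplitude descriptors, Hjorth activity/mobility/complexity, absolute
#' and relative band powers, band RMS values, non-gamma RMS (0.1-32 Hz),
#' total power, spectral edge frequencies (50/90/95% over 0.1-45 Hz), the
#' power-weighted mean frequency, and three band-power ratios.
#'
#' @inheritParams power_spectrum
#' @param bands Band definition tibble, default [eeg_bands()].
#' @return A named numeric vector of length 35; names are the roster's
#'   display names.
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 3, by = 1 / 500))[-1]
#' f <- extract_features(x, fs = 500)
#' f[["Relative power, alpha band"]]
extract_features <- function(x, fs, bands = eeg_bands()) {
  roster <- feature_roster()
  n <- length(x)
  if (n < fs) abort("segment must be at least 1 s long.")
  psd <- power_spectrum(x, fs)
  hj <- hjorth_parameters(x, fs)
  bm <- band_metrics(psd, x, fs, bands)
  lo_all <- min(bands$lo); hi_all <- max(bands$hi)
  in_range <- psd$freq >= lo_all & psd$freq < hi_all
  total_power <- integrate_psd(psd, lo_all, hi_all)
  centroid <- sum(psd$freq[in_range] * psd$power[in_range]) /
    sum(psd$power[in_range])
  dur <- n / fs
  vals <- c(
    mean(x), sd(x), skewness_(x), kurtosis_(x),
    max(x) - min(x), sqrt(mean(x^2)),
    sum(abs(diff(x))), sum(x[-1] * x[-n] < 0) / dur,
    hj[["activity"]], hj[["mobility"]], hj[["complexity"]],
    bm$power, bm$relative_power, bm$rms,
    band_rms_vector(x, fs, 0.1, 32), total_power,
    spectral_edge(psd, 50, c(lo_all, hi_all)),
    spectral_edge(psd, 90, c(lo_all, hi_all)),
    spectral_edge(psd, 95, c(lo_all, hi_all)),
    centroid,
    bm$power[bm$band == "alpha"] / bm$power[bm$band == "beta"],
    bm$power[bm$band == "theta"] / bm$power[bm$band == "alpha"],
    bm$power[bm$band == "beta"] /
      (bm$power[bm$band == "alpha"] + bm$power[bm$band == "theta"])
  )
  setNames(vals, roster$name)
}

#' Compute the feature table for QC-passed segments
#'
#' Applies [extract_features()] to every segment with `qc_status == "pass"`
#' and returns provenance columns plus the 35 feature columns (named by the
#' roster keys; see [feature_roster()] for the display-name mapping).
#' Segments that failed QC are refused (dropped with a message), mirroring
#' the rule that features are only defined on clean segments.
#'
#' @param segments A QC-annotated segments tibble from [qc_segments()].
#' @param bands Band definition tibble.
#' @return A feature table tibble.
#' @export
compute_features <- function(segments, bands = eeg_bands()) {
  if (!"qc_status" %in% names(segments)) {
    abort("`segments` must carry `qc_status`; run qc_segments() first.")
  }
  n_fail <- sum(segments$qc_status != "pass")
  if (n_fail > 0) {
    message(sprintf("dropping %d segment(s) that failed QC.", n_fail))
    segments <- segments[segments$qc_status == "pass", , drop = FALSE]
  }
  if (!nrow(segments)) abort("no QC-passed segments to featurize.")
  roster <- feature_roster()
  feats <- map(seq_len(nrow(segments)), function(i) {
    v <- extract_features(segments$samples[[i]], segments$fs[i], bands)
    setNames(as.list(unname(v)), roster$key)
  })
  meta <- segments |> select(-"samples", -"qc_status")
  bind_cols(meta, list_rbind(map(feats, as_tibble)))
}

#' Write a feature table as TSV using display feature names
#'
#' @param table A feature table from [compute_features()] (optionally
#'   labelled).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  roster <- feature_roster()
  idx <- match(roster$key, names(table))
  names(table)[idx[!is.na(idx)]] <- roster$name[!is.na(idx)]
  readr::write_tsv(table, path)
  invisible(path)
}
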