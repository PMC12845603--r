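# Filtering, segmentation, segment-level QC, and class balancing.

#' Filter specification
#'
#' High-pass, low-pass and notch cutoffs applied by [apply_filters()].
#' Realized as 4th-order Butterworth high/low-pass sections and a Q = 30
#' biquad notch, all run forward-backward for zero phase.
#'
#' @param highpass_cutoff High-pass cutoff in Hz (default 1).
#' @param lowpass_cutoff Low-pass cutoff in Hz (default 49).
#' @param notch_freq Notch centre frequency in Hz (default 50).
#' @param notch_q Notch quality factor (default 30).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(highpass_cutoff = 1, lowpass_cutoff = 49,
                        notch_freq = 50, notch_q = 30) {
  check_number(highpass_cutoff, "highpass_cutoff", lower = 1e-9)
  check_number(lowpass_cutoff, "lowpass_cutoff", lower = 1e-9)
  check_number(notch_freq, "notch_freq", lower = 1e-9)
  check_number(notch_q, "notch_q", lower = 1e-9)
  if (highpass_cutoff >= lowpass_cutoff) {
    abort("`highpass_cutoff` must be below `lowpass_cutoff`.")
  }
  if (notch_freq <= highpass_cutoff || notch_freq > lowpass_cutoff * 1.5) {
    abort("`notch_freq` must lie within the analysis band.")
  }
  structure(list(highpass_cutoff = highpass_cutoff,
                 lowpass_cutoff = lowpass_cutoff,
                 notch_freq = notch_freq, notch_q = notch_q),
            class = "filter_spec")
}

#' Quality-control configuration
#'
#' Thresholds for segment-level QC and segmentation: segments whose
#' peak-to-peak range exceeds `saturation_range` are saturated, ranges below
#' `flat_range` are flat, and any sample beyond `artifact_abs` (post-filter)
#' marks the segment as artifact-contaminated. All comparisons are strict,
#' so samples exactly at a bound are retained.
#'
#' @param saturation_range Saturation range threshold in uV (default 80).
#' @param flat_range Flat-signal range threshold in uV (default 1).
#' @param artifact_abs Absolute amplitude threshold in uV (default 20).
#' @param segment_length Fixed-window segment length in seconds (default 3).
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(saturation_range = 80, flat_range = 1,
                      artifact_abs = 20, segment_length = 3) {
  check_number(saturation_range, "saturation_range", lower = 1e-9)
  check_number(flat_range, "flat_range", lower = 0)
  check_number(artifact_abs, "artifact_abs", lower = 1e-9)
  check_number(segment_length, "segment_length", lower = 1e-9)
  if (!(flat_range < artifact_abs && artifact_abs < saturation_range)) {
    abort("need flat_range < artifact_abs < saturation_range.")
  }
  structure(list(saturation_range = saturation_range, flat_range = flat_range,
                 artifact_abs = artifact_abs, segment_length = segment_length),
            class = "qc_config")
}

# -- IIR plumbing -----------------------------------------------------------

# RBJ cookbook biquad notch.
design_notch <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

# Squared magnitude of a digital IIR section on a frequency grid (Hz).
iir_mag2 <- function(b, a, freq, fs) {
  z <- exp(-1i * 2 * pi * freq / fs)
  num <- Reduce(`+`, lapply(seq_along(b), function(k) b[k] * z^(k - 1)))
  den <- Reduce(`+`, lapply(seq_along(a), function(k) a[k] * z^(k - 1)))
  Mod(num / den)^2
}

# Zero-phase filtering: the Butterworth/notch chain's squared-magnitude
# response (the steady-state response a forward-backward pass realizes) is
# applied in the frequency domain. This keeps exact linear-phase-free
# behaviour with no warm-up transient, which a padded forward-backward IIR
# pass cannot achieve at the notch's bandwidth on finite recordings.
filter_signal_vector <- function(x, fs, spec) {
  if (fs <= 2 * spec$lowpass_cutoff) {
    abort("`fs` must exceed twice the low-pass cutoff.")
  }
  n <- length(x)
  if (n < 64L) {
    abort("signal shorter than the filter warm-up; cannot filter.")
  }
  hp <- signal::butter(4, spec$highpass_cutoff / (fs / 2), type = "high")
  lp <- signal::butter(4, spec$lowpass_cutoff / (fs / 2), type = "low")
  nt <- design_notch(spec$notch_freq, fs, spec$notch_q)
  freq <- seq(0, n - 1) * fs / n
  freq <- pmin(freq, fs - freq) # fold to two-sided magnitude grid
  gain <- iir_mag2(hp$b, hp$a, freq, fs) *
    iir_mag2(lp$b, lp$a, freq, fs) *
    iir_mag2(nt$b, nt$a, freq, fs)
  Re(fft(fft(x) * gain, inverse = TRUE)) / n
}

#' Apply the zero-phase filter chain to recordings
#'
#' Runs the 1 Hz high-pass, 49 Hz low-pass and 50 Hz notch (Q = 30) filters
#' forward-backward over every recording's signal. Output length equals input
#' length; DC is removed and the notch frequency attenuated by >= 40 dB.
#'
#' @param data A recordings tibble with list-column `signal` and column `fs`
#'   (as produced by [generate_stress_study()], [generate_workload_study()] or
#'   [read_recording()]).
#' @param spec A [filter_spec()].
#' @return `data` with `signal` replaced by the filtered samples.
#' @export
apply_filters <- function(data, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (!all(c("signal", "fs") %in% names(data))) {
    abort("`data` must have `signal` and `fs` columns.")
  }
  data$signal <- map2(data$signal, data$fs,
                      function(x, fs) filter_signal_vector(x, fs, spec))
  data
}

#' Split recordings into analysis segments
#'
#' `mode = "fixed"` divides each recording into contiguous non-overlapping
#' windows of `cfg$segment_length` seconds, discarding any trailing
#' remainder. `mode = "trial"` treats each recording row (one trial) as a
#' single segment.
#'
#' @inheritParams apply_filters
#' @param cfg A [qc_config()].
#' @param mode `"fixed"` (stress protocol) or `"trial"` (workload protocol).
#' @return A tibble with one row per segment: the provenance columns of
#'   `data` (signal dropped) plus `segment` index and list-column `samples`.
#' @export
segment_recordings <- function(data, cfg = qc_config(), mode = c("fixed", "trial")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "qc_config"))
  if (!nrow(data)) abort("empty recording set.")
  meta <- data |> select(-"signal")
  if (mode == "trial") {
    out <- meta |> mutate(segment = 1L, samples = data$signal)
    return(out)
  }
  rows <- pmap(list(seq_len(nrow(data))), function(i) {
    x <- data$signal[[i]]
    n_seg <- floor(length(x) / (cfg$segment_length * data$fs[i]))
    if (n_seg < 1) abort("recording shorter than one segment.")
    len <- round(cfg$segment_length * data$fs[i])
    segs <- map(seq_len(n_seg), function(k) x[((k - 1) * len + 1):(k * len)])
    meta[rep(i, n_seg), ] |> mutate(segment = seq_len(n_seg), samples = segs)
  })
  list_rbind(rows)
}

qc_status_vector <- function(x, cfg) {
  rng <- max(x) - min(x)
  if (rng > cfg$saturation_range) return("saturated")
  if (rng < cfg$flat_range) return("flat")
  if (any(abs(x) > cfg$artifact_abs)) return("artifact")
  "pass"
}

#' Segment-level quality control
#'
#' Assigns each segment exactly one status with precedence
#' saturated > flat > artifact > pass (strict-inequality thresholds, see
#' [qc_config()]).
#'
#' @param segments A segments tibble from [segment_recordings()].
#' @param cfg A [qc_config()].
#' @return `segments` with a `qc_status` factor column.
#' @export
qc_segments <- function(segments, cfg = qc_config()) {
  stopifnot(inherits(cfg, "qc_config"))
  if (!nrow(segments)) abort("empty segment set.")
  segments$qc_status <- factor(
    map_chr(segments$samples, qc_status_vector, cfg = cfg),
    levels = c("pass", "saturated", "flat", "artifact")
  )
  segments
}

#' Balance classes by downsampling
#'
#' Randomly subsamples every class (without replacement) down to the minimum
#' class count. Only classification labels are ever balanced; regression
#' targets are left untouched by the pipeline.
#'
#' @param table A labelled feature table with a `label` column.
#' @param seed Integer seed for the subsampling.
#' @return The balanced table (a subset of the input rows).
#' @export
#' @examples
#' tbl <- tibble::tibble(label = rep(c("a", "b"), c(5, 3)), x = 1:8)
#' table(balance_classes(tbl, seed = 1)$label)
balance_classes <- function(table, seed = 1) {
  if (!"label" %in% names(table)) abort("`table` must have a `label` column.")
  counts <- table(as.character(table$label))
  if (length(counts) < 2L) abort("class balancing needs at least two classes.")
  n_min <- min(counts)
  with_seed(as.integer(seed) %% 2147483647L, {
    keep <- unlist(lapply(names(counts), function(cl) {
      idx <- which(as.character(table$label) == cl)
      if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
    }))
  })
  table[sort(keep), , drop = FALSE]
}

#' Write a QC report
#'
#' @param segments A QC-annotated segments tibble from [qc_segments()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(segments, path) {
  out <- segments |> select(-"samples")
  readr::write_tsv(out, path)
  invisible(path)
}
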