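# Shared fixtures, built in code.

fs_default <- 500

sinusoid <- function(f, duration = 3, fs = fs_default, amplitude = 1, phase = 0) {
  amplitude * sin(2 * pi * f * seq_len(round(duration * fs)) / fs + phase)
}

# A 100-segment toy set with known QC memberships: 70 clean, 10 saturated,
# 10 flat, 10 artifact-contaminated.
toy_qc_segments <- function() {
  n <- round(3 * fs_default)
  clean <- lapply(1:70, function(i) sinusoid(10, amplitude = 5, phase = i))
  saturated <- lapply(1:10, function(i) sinusoid(2, amplitude = 55, phase = i))  # range 110
  flat <- lapply(1:10, function(i) rep(0.2 * i, n))                               # range 0
  artifact <- lapply(1:10, function(i) {
    x <- sinusoid(10, amplitude = 5, phase = i)
    x[100 + i] <- 25  # single excursion beyond +/-20, range < 80
    x
  })
  tibble::tibble(
    subject_id = "toy",
    truth = rep(c("pass", "saturated", "flat", "artifact"), c(70, 10, 10, 10)),
    fs = fs_default,
    segment = 1:100,
    samples = c(clean, saturated, flat, artifact)
  )
}

# Random feature table keyed like the real one, for model plumbing tests.
random_feature_table <- function(n_subjects, rows_per_subject, seed = 1) {
  withr::with_seed(seed, {
    purrr::list_rbind(lapply(seq_len(n_subjects), function(i) {
      X <- matrix(rnorm(rows_per_subject * 35), rows_per_subject, 35)
      colnames(X) <- feature_roster()$key
      tibble::as_tibble(X) |>
        dplyr::mutate(
          subject_id = sprintf("s%02d", i),
          label = factor(sample(c("low", "high"), rows_per_subject, TRUE),
                         levels = c("low", "high"))
        )
    }))
  })
}

# Two-condition study with an injected alpha-RMS / beta-relative-power
# effect, used for recovery and attribution tests.
injected_effect_study <- function(n_subjects, seed = 11, block_duration = 120) {
  profs <- eareeg:::draw_subject_profiles(n_subjects, seed = seed)
  cond_lo <- condition_spec("low_load",
                            band_multipliers = c(alpha = 1.4, beta = 0.8),
                            stress_index = 0.2, duration = block_duration)
  cond_hi <- condition_spec("high_load",
                            band_multipliers = c(alpha = 0.7, beta = 1.3),
                            stress_index = 0.8, duration = block_duration)
  rows <- list()
  for (i in seq_along(profs)) {
    rows[[2 * i - 1]] <- synthesize_recording(profs[[i]], cond_lo,
                                              seed = 1000 + i, block = 1)
    rows[[2 * i]] <- synthesize_recording(profs[[i]], cond_hi,
                                          seed = 2000 + i, block = 2)
  }
  purrr::list_rbind(rows)
}

featurize_study <- function(study, mode = "fixed") {
  segs <- qc_segments(segment_recordings(apply_filters(study), mode = mode))
  suppressMessages(compute_features(segs))
}
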