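test_that("synthesis is deterministic and amplitude-calibrated", {
  prof <- subject_profile("s01")
  cond <- condition_spec("eyes_open")
  a <- synthesize_recording(prof, cond, duration = 10, seed = 3)
  b <- synthesize_recording(prof, cond, duration = 10, seed = 3)
  expect_identical(a$signal[[1]], b$signal[[1]])
  c <- synthesize_recording(prof, cond, duration = 10, seed = 4)
  expect_false(identical(a$signal[[1]], c$signal[[1]]))
  expect_equal(a$n_samples, 5000)
  # typical artifact-free amplitude well inside +/-20 uV
  expect_lt(max(abs(a$signal[[1]])), 20)
  expect_error(synthesize_recording(prof, cond, duration = -1, seed = 1),
               "duration")
  expect_error(synthesize_recording(prof, cond, duration = 10, fs = 50, seed = 1),
               "fs")
})

test_that("realized band powers track the specified variances (Welch, 20 seeds)", {
  prof <- subject_profile("s01")
  cond <- condition_spec("eyes_open")
  target <- prof$baseline_band_power
  est <- vapply(1:20, function(s) {
    x <- synthesize_recording(prof, cond, duration = 60, seed = 100 + s)$signal[[1]]
    band_metrics(power_spectrum(x, 500, window_sec = 4), x, 500)$power
  }, numeric(5))
  rel_err <- abs(rowMeans(est) - target) / target
  expect_lt(max(rel_err), 0.15)
})

test_that("an alpha multiplier raises downstream alpha relative power", {
  prof <- subject_profile("s01")
  c1 <- condition_spec("alpha_hi", band_multipliers = c(alpha = 2))
  c2 <- condition_spec("alpha_lo", band_multipliers = c(alpha = 1))
  rel <- function(cond, s) {
    x <- synthesize_recording(prof, cond, duration = 30, seed = s)$signal[[1]]
    bm <- band_metrics(power_spectrum(x, 500), x, 500)
    bm$relative_power[bm$band == "alpha"]
  }
  diffs <- vapply(1:20, function(s) rel(c1, s) - rel(c2, s), numeric(1))
  expect_true(all(diffs > 0))
})

test_that("line-noise artifacts peak at 50 Hz and the filter chain removes them", {
  prof <- subject_profile("s01")
  rec <- synthesize_recording(
    prof, condition_spec("eyes_open"), duration = 30, seed = 5,
    artifacts = list(artifact_spec("line_noise", amplitude = 10)))
  psd_raw <- power_spectrum(rec$signal[[1]], 500)
  expect_equal(psd_raw$freq[which.max(psd_raw$power)], 50)
  filt <- apply_filters(rec)
  psd_f <- power_spectrum(filt$signal[[1]], 500)
  expect_lt(psd_f$power[psd_f$freq == 50], psd_raw$power[psd_raw$freq == 50] * 1e-4)
})

test_that("the stress study has the protocol block structure and ratings", {
  study <- generate_stress_study(8, seed = 1)
  expect_equal(nrow(study), 24)
  expect_equal(unname(table(study$subject_id)), rep(3L, 8), ignore_attr = TRUE)
  expect_true(all(study$n_samples == 120 * 500))
  expect_true(all(study$rating %in% 1:9))
  expect_identical(generate_stress_study(3, seed = 9), generate_stress_study(3, seed = 9))
  expect_error(generate_stress_study(1, seed = 1), "n_subjects")
})

test_that("mean ratings increase across meditation, eyes-open, cold pressor", {
  profs <- eareeg:::draw_subject_profiles(50, seed = 21)
  conds <- stress_conditions()
  m <- vapply(conds, function(cond) {
    mean(vapply(seq_along(profs), function(i) {
      rate_block(profs[[i]], cond, seed = 100 * i + cond$stress_index * 1000)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(m[["meditation"]], m[["eyes_open"]])
  expect_lt(m[["eyes_open"]], m[["cold_pressor"]])
})

test_that("rate_block follows the clipped rating formula", {
  prof0 <- subject_profile("a", rating_bias = 0)
  lo <- condition_spec("lo", stress_index = 0)
  hi <- condition_spec("hi", stress_index = 1)
  expect_equal(rate_block(prof0, lo, seed = 1, noise_sd = 0), 1L)
  expect_equal(rate_block(prof0, hi, seed = 1, noise_sd = 0), 9L)
  prof_bias <- subject_profile("b", rating_bias = 10)
  expect_equal(rate_block(prof_bias, lo, seed = 1, noise_sd = 0), 9L)
})

test_that("the workload study has the trial hierarchy and 2.5 s trials", {
  wl <- generate_workload_study(2, seed = 4)
  expect_equal(nrow(wl), 2 * 4 * 3 * 5 * 10)
  one <- wl[wl$subject_id == "s01", ]
  expect_equal(nrow(one), 600)
  expect_true(all(wl$n_samples == 1250))
  counts <- dplyr::count(wl, task, level)
  expect_true(all(counts$n == 2 * 5 * 10))
})

test_that("mental rotation has a weaker alpha-RMS difficulty effect than arithmetic", {
  wl <- generate_workload_study(20, seed = 8,
                                tasks = c("arithmetic", "mental_rotation"),
                                artifact_rates = c(motion = 0, muscle = 0))
  wl <- wl[wl$level != "medium", ]
  wl$alpha_rms <- purrr::map2_dbl(wl$signal, wl$fs,
                                  ~eareeg:::band_rms_vector(.x, .y, 8, 12))
  es <- wl |>
    dplyr::group_by(task, subject_id, level) |>
    dplyr::summarise(m = mean(alpha_rms), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "level", values_from = "m") |>
    dplyr::group_by(task) |>
    dplyr::summarise(d = abs(mean(low - high)) / sd(low - high))
  expect_lt(es$d[es$task == "mental_rotation"], es$d[es$task == "arithmetic"])
})
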