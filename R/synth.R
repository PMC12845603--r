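# Synthetic in-ear EEG: protocol-structured recordings with controllable
# band-power structure, subject random effects, artifacts, and ratings.

#' Canonical EEG frequency bands
#'
#' The five analysis bands used throughout the package, in the half-open
#' convention `[lo, hi)`: delta (0.1-4 Hz), theta (4-8 Hz), alpha (8-12 Hz),
#' beta (12-32 Hz) and gamma (32-45 Hz).
#'
#' @return A tibble with columns `band`, `lo`, `hi` (Hz).
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function() {
  tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    lo   = c(0.1, 4, 8, 12, 32),
    hi   = c(4, 8, 12, 32, 45)
  )
}

# Default per-band baseline variances (uV^2). Chosen so the artifact-free
# post-filter signal has sd ~ 4 uV, i.e. a typical amplitude envelope within
# +/-20 uV, and a >= 95% pass rate under the +/-20 uV segment criterion.
default_band_power <- function() {
  c(delta = 5, theta = 3, alpha = 4, beta = 2.5, gamma = 1)
}

#' Subject profile for the synthetic generator
#'
#' Encapsulates the subject-level random effects: per-band baseline power
#' (multiplicative log-normal deviation from the population default), an
#' additive bias on the 1-9 subjective rating scale, and artifact event rates.
#'
#' @param subject_id Subject identifier string.
#' @param baseline_band_power Named numeric vector of per-band signal variance
#'   (uV^2) for the five bands of [eeg_bands()]. All entries must be positive.
#' @param rating_bias Additive shift applied to the subject's ratings before
#'   rounding and clipping to 1-9.
#' @param artifact_rates Named numeric vector of event rates (events/minute)
#'   for artifact kinds among `motion`, `muscle`, `flatline`, `saturation`.
#'
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id,
                            baseline_band_power = default_band_power(),
                            rating_bias = 0,
                            artifact_rates = c(motion = 0, muscle = 0)) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  bands <- eeg_bands()$band
  if (!all(bands %in% names(baseline_band_power))) {
    abort("`baseline_band_power` must name all five bands.")
  }
  if (any(!is.finite(baseline_band_power)) || any(baseline_band_power <= 0)) {
    abort("baseline band powers must be strictly positive and finite.")
  }
  check_number(rating_bias, "rating_bias")
  if (length(artifact_rates) && any(artifact_rates < 0)) {
    abort("artifact rates must be non-negative.")
  }
  structure(
    list(
      subject_id = subject_id,
      baseline_band_power = baseline_band_power[bands],
      rating_bias = rating_bias,
      artifact_rates = artifact_rates
    ),
    class = "subject_profile"
  )
}

#' Experimental condition specification
#'
#' A condition scales the subject's baseline band powers by `band_multipliers`
#' and sits at a latent `stress_index` in \[0, 1\] that drives the subjective
#' rating model. The default stress protocol orders the index
#' meditation < eyes-open < cold pressor.
#'
#' @param condition_id Condition identifier (e.g. `"meditation"` or
#'   `"arithmetic:high"`).
#' @param band_multipliers Named positive multipliers for any subset of the
#'   five bands; unnamed bands default to 1.
#' @param stress_index Latent stress level in \[0, 1\].
#' @param duration Block duration in seconds (single-block conditions).
#' @param gamma_burst_depth Depth in \[0, 1\] of slow amplitude modulation
#'   applied to the gamma component (an EMG-like burst structure; total gamma
#'   power is preserved).
#'
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(condition_id,
                           band_multipliers = NULL,
                           stress_index = 0.5,
                           duration = 120,
                           gamma_burst_depth = 0) {
  stopifnot(is.character(condition_id), length(condition_id) == 1L)
  bands <- eeg_bands()$band
  mult <- setNames(rep(1, 5), bands)
  if (!is.null(band_multipliers)) {
    if (is.null(names(band_multipliers)) ||
        !all(names(band_multipliers) %in% bands)) {
      abort("`band_multipliers` must be named by bands.")
    }
    if (any(band_multipliers <= 0)) abort("band multipliers must be > 0.")
    mult[names(band_multipliers)] <- band_multipliers
  }
  check_number(stress_index, "stress_index", 0, 1)
  check_number(duration, "duration", lower = 1e-9)
  check_number(gamma_burst_depth, "gamma_burst_depth", 0, 1)
  structure(
    list(
      condition_id = condition_id,
      band_multipliers = mult,
      stress_index = stress_index,
      duration = duration,
      gamma_burst_depth = gamma_burst_depth
    ),
    class = "condition_spec"
  )
}

#' Artifact specification
#'
#' @param kind One of `"motion"`, `"muscle"`, `"flatline"`, `"saturation"`,
#'   `"line_noise"`.
#' @param amplitude Peak amplitude in uV (>= 0).
#' @param duration Event duration in seconds (> 0); ignored for `line_noise`,
#'   which contaminates the whole recording.
#' @param rate Event rate in events/minute; ignored for `line_noise`.
#'
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(kind, amplitude, duration = 0.5, rate = 1) {
  kind <- match.arg(kind, c("motion", "muscle", "flatline", "saturation", "line_noise"))
  check_number(amplitude, "amplitude", lower = 0)
  check_number(duration, "duration", lower = 1e-9)
  check_number(rate, "rate", lower = 0)
  structure(list(kind = kind, amplitude = amplitude, duration = duration, rate = rate),
            class = "artifact_spec")
}

default_artifact_specs <- function(rates = c(motion = 0, muscle = 0)) {
  specs <- list(
    motion     = artifact_spec("motion", amplitude = 60, duration = 0.5),
    muscle     = artifact_spec("muscle", amplitude = 30, duration = 0.3),
    flatline   = artifact_spec("flatline", amplitude = 0, duration = 1),
    saturation = artifact_spec("saturation", amplitude = 100, duration = 0.5)
  )
  out <- list()
  for (k in names(rates)) {
    if (!k %in% names(specs)) next
    if (rates[[k]] <= 0) next
    sp <- specs[[k]]
    sp$rate <- rates[[k]]
    out[[length(out) + 1L]] <- sp
  }
  out
}

# Band-limit white noise in the frequency domain (hard mask over [lo, hi)).
fft_band_noise <- function(n, fs, lo, hi) {
  freq <- seq(0, n - 1) * fs / n
  freq <- pmin(freq, fs - freq) # two-sided magnitude frequency
  spec <- fft(rnorm(n))
  spec[!(freq >= lo & freq < hi)] <- 0
  Re(fft(spec, inverse = TRUE)) / n
}

# 1/f^0.7 background over [0.5, 48] Hz, unit-variance realization.
fft_pink_background <- function(n, fs) {
  freq <- seq(0, n - 1) * fs / n
  freq <- pmin(freq, fs - freq)
  spec <- fft(rnorm(n))
  gain <- rep(0, n)
  sel <- freq >= 0.5 & freq < 48
  gain[sel] <- freq[sel]^(-0.35) # amplitude ~ f^-0.35 -> power ~ 1/f^0.7
  x <- Re(fft(spec * gain, inverse = TRUE)) / n
  x / sd(x)
}

scale_to_var <- function(x, v) {
  s <- sd(x)
  if (s == 0) return(x)
  x * sqrt(v) / s
}

band_component_var <- function(x, fs, lo, hi) {
  n <- length(x)
  freq <- seq(0, n - 1) * fs / n
  freq <- pmin(freq, fs - freq)
  spec <- fft(x)
  spec[!(freq >= lo & freq < hi)] <- 0
  var(Re(fft(spec, inverse = TRUE)) / n)
}

apply_artifact_events <- function(x, fs, specs) {
  n <- length(x)
  dur_s <- n / fs
  t <- seq(0, n - 1) / fs
  for (sp in specs) {
    if (sp$kind == "line_noise") {
      x <- x + sp$amplitude * sin(2 * pi * 50 * t + runif(1, 0, 2 * pi))
      next
    }
    n_events <- rpois(1, sp$rate / 60 * dur_s)
    if (n_events == 0) next
    starts <- sort(runif(n_events, 0, max(dur_s - sp$duration, 0)))
    len <- max(2L, round(sp$duration * fs))
    for (s0 in starts) {
      i0 <- floor(s0 * fs) + 1L
      i1 <- min(n, i0 + len - 1L)
      idx <- i0:i1
      m <- length(idx)
      shape <- switch(
        sp$kind,
        motion = sample(c(-1, 1), 1) * sp$amplitude * sin(pi * seq_len(m) / m),
        muscle = rnorm(m) * (sp$amplitude / 3) * (0.5 - 0.5 * cos(2 * pi * seq_len(m) / m)),
        flatline = NA, # handled below
        saturation = sp$amplitude * ifelse(seq_len(m) <= m / 2, 1, -1)
      )
      if (sp$kind == "flatline") {
        x[idx] <- 0
      } else if (sp$kind == "saturation") {
        x[idx] <- shape
      } else {
        x[idx] <- x[idx] + shape
      }
    }
  }
  x
}

#' Synthesize one protocol block of single-channel EEG
#'
#' The signal model is a sum of independent band-limited Gaussian processes
#' (white noise shaped in the frequency domain) over a `1/f^0.7` background.
#' Each band component is rescaled so that the realized in-band variance
#' (background included) equals `baseline_band_power * band_multipliers` for
#' that band, giving exact control over the spectral structure downstream
#' feature extraction estimates.
#'
#' @param profile A [subject_profile()].
#' @param cond A [condition_spec()].
#' @param duration Recording duration in seconds (defaults to the condition's).
#' @param fs Sampling rate in Hz; must exceed twice the top band edge.
#' @param seed Integer seed; identical arguments reproduce the signal exactly.
#' @param artifacts Either `NULL` (use the profile's `artifact_rates`) or a
#'   list of [artifact_spec()] objects; `list()` disables artifacts.
#' @param block Block index recorded in the provenance columns.
#'
#' @return A one-row tibble with columns `subject_id`, `condition`, `block`,
#'   `fs`, `seed`, `n_samples`, and a list-column `signal` of samples in uV.
#' @export
#' @examples
#' prof <- subject_profile("s01")
#' rec <- synthesize_recording(prof, condition_spec("eyes_open"),
#'                             duration = 10, seed = 1)
#' rec$n_samples
synthesize_recording <- function(profile, cond, duration = NULL, fs = 500,
                                 seed = 1, artifacts = NULL, block = 1L) {
  stopifnot(inherits(profile, "subject_profile"), inherits(cond, "condition_spec"))
  duration <- duration %||% cond$duration
  check_number(duration, "duration", lower = 1e-9)
  check_number(fs, "fs", lower = 1e-9)
  bands <- eeg_bands()
  if (fs < 2 * max(bands$hi)) {
    abort("`fs` must be at least twice the top band edge (90 Hz).")
  }
  n <- round(duration * fs)
  if (n < 2) abort("`duration` too short at this sampling rate.")

  with_seed(as.integer(seed) %% 2147483647L, {
    background <- scale_to_var(fft_pink_background(n, fs), 1.5)
    x <- background
    for (i in seq_len(nrow(bands))) {
      b <- bands$band[i]
      target <- profile$baseline_band_power[[b]] * cond$band_multipliers[[b]]
      bg_in_band <- band_component_var(background, fs, bands$lo[i], bands$hi[i])
      comp_var <- max(target - bg_in_band, 0.05 * target)
      comp <- fft_band_noise(n, fs, bands$lo[i], bands$hi[i])
      if (b == "gamma" && cond$gamma_burst_depth > 0) {
        slow <- fft_band_noise(n, fs, 0.2, 2)
        env <- pmax(0, 1 + cond$gamma_burst_depth * slow / sd(slow))
        comp <- comp * env
      }
      x <- x + scale_to_var(comp, comp_var)
    }
    specs <- artifacts %||% default_artifact_specs(profile$artifact_rates)
    if (length(specs)) x <- apply_artifact_events(x, fs, specs)

    tibble(
      subject_id = profile$subject_id,
      condition = cond$condition_id,
      block = as.integer(block),
      fs = fs,
      seed = as.integer(seed) %% 2147483647L,
      n_samples = n,
      signal = list(x)
    )
  })
}

#' Subjective stress rating for one block
#'
#' `rating = clip(round(1 + 8 * stress_index + rating_bias + noise), 1, 9)`
#' with Gaussian noise (`sd = noise_sd`) before rounding.
#'
#' @inheritParams synthesize_recording
#' @param noise_sd Standard deviation of the pre-rounding rating noise.
#' @return An integer rating in 1-9.
#' @export
rate_block <- function(profile, cond, seed = 1, noise_sd = 0.8) {
  stopifnot(inherits(profile, "subject_profile"), inherits(cond, "condition_spec"))
  check_number(noise_sd, "noise_sd", lower = 0)
  with_seed(as.integer(seed) %% 2147483647L, {
    raw <- 1 + 8 * cond$stress_index + profile$rating_bias +
      (if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0)
    as.integer(min(9, max(1, round(raw))))
  })
}

# Population draw of subject profiles: log-normal band-power random effects
# (sdlog 0.25), Gaussian rating bias (sd 0.7).
draw_subject_profiles <- function(n_subjects, seed,
                                  artifact_rates = c(motion = 0, muscle = 0)) {
  with_seed(derive_seed(seed, 1), {
    map(seq_len(n_subjects), function(i) {
      base <- default_band_power() * exp(rnorm(5, 0, 0.25))
      subject_profile(
        subject_id = sprintf("s%02d", i),
        baseline_band_power = setNames(base, names(default_band_power())),
        rating_bias = rnorm(1, 0, 0.7),
        artifact_rates = artifact_rates
      )
    })
  })
}

#' Stress-protocol condition set
#'
#' Meditation (alpha-enhanced, lowest stress), eyes-open rest (reference), and
#' cold pressor (alpha suppressed, beta/gamma enhanced with EMG-like gamma
#' bursts, highest stress). `effect_scale` interpolates every band multiplier
#' between 1 (no condition effect, `effect_scale = 0`) and its default.
#'
#' @param effect_scale Non-negative scaling of the condition band effects.
#' @return A named list of three [condition_spec()] objects.
#' @export
stress_conditions <- function(effect_scale = 1) {
  check_number(effect_scale, "effect_scale", lower = 0)
  sc <- function(m) 1 + (m - 1) * effect_scale
  list(
    meditation = condition_spec(
      "meditation",
      band_multipliers = c(alpha = sc(1.5), theta = sc(1.15), gamma = sc(0.8)),
      stress_index = 0.05, duration = 120
    ),
    eyes_open = condition_spec(
      "eyes_open",
      band_multipliers = NULL,
      stress_index = 0.45, duration = 120
    ),
    cold_pressor = condition_spec(
      "cold_pressor",
      band_multipliers = c(alpha = sc(0.7), beta = sc(1.3), gamma = sc(1.8),
                           theta = sc(1.1)),
      stress_index = 0.9, duration = 120,
      gamma_burst_depth = 0.6 * min(effect_scale, 1)
    )
  )
}

#' Generate a synthetic stress study
#'
#' Each subject contributes three 120 s blocks (meditation, eyes-open rest,
#' cold pressor, in protocol order) plus one integer subjective rating (1-9)
#' per block from [rate_block()].
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Master seed; all per-subject and per-block randomness derives
#'   from it deterministically.
#' @param effect_scale Condition band-effect scaling; 0 gives effect-free
#'   recordings (ratings keep their condition structure).
#' @param artifact_rates Named events/minute rates passed to every subject's
#'   profile (`motion`, `muscle`, `flatline`, `saturation`).
#'
#' @return A tibble with one row per block: `subject_id`, `condition`,
#'   `block`, `rating`, `fs`, `seed`, `n_samples`, `signal`.
#' @export
#' @examples
#' study <- generate_stress_study(2, seed = 1)
#' nrow(study) # 6 blocks
generate_stress_study <- function(n_subjects, seed = 1, effect_scale = 1,
                                  artifact_rates = c(motion = 0.3, muscle = 0.3)) {
  n_subjects <- check_count(n_subjects, "n_subjects", lower = 2L)
  conds <- stress_conditions(effect_scale)
  profiles <- draw_subject_profiles(n_subjects, seed, artifact_rates)
  rows <- list()
  for (i in seq_len(n_subjects)) {
    prof <- profiles[[i]]
    for (k in seq_along(conds)) {
      cond <- conds[[k]]
      block_seed <- derive_seed(seed, i, k)
      rec <- synthesize_recording(prof, cond, fs = 500, seed = block_seed,
                                  block = k)
      rec$rating <- rate_block(prof, cond, seed = derive_seed(seed, i, k, 7))
      rows[[length(rows) + 1L]] <- rec
    }
  }
  list_rbind(rows) |>
    mutate(condition = factor(.data$condition,
                              levels = c("meditation", "eyes_open", "cold_pressor"))) |>
    relocate("subject_id", "condition", "block", "rating")
}

#' Workload-task difficulty effects
#'
#' Default per-task band multipliers across the low/medium/high difficulty
#' levels: alpha decreases and beta increases with difficulty for arithmetic
#' and finger tapping, the effect is weak for lexical decision, and near-flat
#' for mental rotation (whose oscillatory dynamics are stable across levels).
#'
#' @param effect_scale Non-negative scaling of the level effects.
#' @return A tibble with columns `task`, `level`, `alpha`, `beta`.
#' @export
workload_effects <- function(effect_scale = 1) {
  check_number(effect_scale, "effect_scale", lower = 0)
  sc <- function(m) 1 + (m - 1) * effect_scale
  base <- tribble(
    ~task,              ~level,   ~alpha, ~beta,
    "arithmetic",       "low",    1.25,   0.82,
    "arithmetic",       "medium", 1.00,   1.00,
    "arithmetic",       "high",   0.78,   1.25,
    "finger_tapping",   "low",    1.18,   0.88,
    "finger_tapping",   "medium", 1.00,   1.00,
    "finger_tapping",   "high",   0.85,   1.15,
    "lexical_decision", "low",    1.06,   0.96,
    "lexical_decision", "medium", 1.00,   1.00,
    "lexical_decision", "high",   0.95,   1.05,
    "mental_rotation",  "low",    1.00,   1.00,
    "mental_rotation",  "medium", 1.00,   1.00,
    "mental_rotation",  "high",   1.00,   1.00
  )
  base$alpha <- sc(base$alpha)
  base$beta <- sc(base$beta)
  base
}

#' Generate a synthetic mental-workload study
#'
#' Per subject: 4 tasks x 3 difficulty levels x 5 sessions x 10 trials, each
#' trial 2.5 s at 500 Hz (1250 samples). Each session is synthesized as one
#' continuous 25 s recording and split into trial-aligned segments, so trials
#' within a session share slow signal structure.
#'
#' @inheritParams generate_stress_study
#' @param tasks Character subset of the four tasks to generate.
#' @return A tibble with one row per trial: `subject_id`, `task`, `level`,
#'   `session`, `trial`, `fs`, `n_samples`, `signal`.
#' @export
generate_workload_study <- function(n_subjects, seed = 1, effect_scale = 1,
                                    tasks = c("arithmetic", "finger_tapping",
                                              "lexical_decision", "mental_rotation"),
                                    artifact_rates = c(motion = 0.15, muscle = 0.15)) {
  n_subjects <- check_count(n_subjects, "n_subjects", lower = 2L)
  tasks <- match.arg(tasks, several.ok = TRUE)
  eff <- workload_effects(effect_scale)
  profiles <- draw_subject_profiles(n_subjects, derive_seed(seed, 2), artifact_rates)
  levels_ <- c("low", "medium", "high")
  trial_len <- 2.5
  fs <- 500
  n_trial <- round(trial_len * fs)
  rows <- list()
  for (i in seq_len(n_subjects)) {
    prof <- profiles[[i]]
    for (ti in seq_along(tasks)) {
      task <- tasks[ti]
      for (li in seq_along(levels_)) {
        lev <- levels_[li]
        e <- eff[eff$task == task & eff$level == lev, ]
        cond <- condition_spec(
          paste(task, lev, sep = ":"),
          band_multipliers = c(alpha = e$alpha, beta = e$beta),
          stress_index = (li - 1) / 2,
          duration = 10 * trial_len
        )
        for (sess in 1:5) {
          rec <- synthesize_recording(
            prof, cond, fs = fs,
            seed = derive_seed(seed, i, ti, li, sess), block = sess
          )
          sig <- rec$signal[[1]]
          for (tr in 1:10) {
            idx <- ((tr - 1) * n_trial + 1):(tr * n_trial)
            rows[[length(rows) + 1L]] <- tibble(
              subject_id = prof$subject_id,
              task = task,
              level = lev,
              session = sess,
              trial = tr,
              fs = fs,
              n_samples = n_trial,
              signal = list(sig[idx])
            )
          }
        }
      }
    }
  }
  list_rbind(rows) |>
    mutate(level = factor(.data$level, levels = levels_))
}
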