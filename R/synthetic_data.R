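# Seeded synthetic recordings with the pathological signatures the analysis
# assumes: micrographia (geometric letter-height decay), rest/action tremor
# (radial or vertical sinusoid plus a 4-6 Hz sEMG amplitude modulation),
# bradykinetic slowing, altered pen pressure.

#' Severity profile for the synthetic generator
#'
#' Parameterizes the pathological signatures injected into generated
#' recordings. The healthy preset has all pathological parameters at zero;
#' presets are ordered (mild <= moderate in every pathological parameter).
#'
#' @param micrographia_rate fractional letter-height decay per stroke (>= 0);
#'   stroke k is drawn at height `(1 - rate)^(k-1)` times stroke 1.
#' @param tremor_amp tremor amplitude in millimetres, added radially on
#'   spirals and vertically on letters.
#' @param tremor_freq tremor frequency in Hz.
#' @param speed_scale multiplicative factor on pen speed (0 < s <= 1);
#'   task duration scales as `1/speed_scale`.
#' @param pressure_mean,pressure_sd normalized pen-pressure baseline and
#'   within-task variability.
#' @param emg_tremor_gain dimensionless gain of the tremor-band amplitude
#'   modulation of the sEMG channels.
#' @param noise_sd white positional noise, millimetres.
#' @return A list of class `severity_profile`.
#' @export
severity_profile <- function(micrographia_rate = 0, tremor_amp = 0,
                             tremor_freq = 5, speed_scale = 1,
                             pressure_mean = 0.55, pressure_sd = 0.03,
                             emg_tremor_gain = 0, noise_sd = 0.05) {
  if (micrographia_rate < 0 || micrographia_rate >= 1)
    pds_error("parameter_error", "micrographia_rate must be in [0, 1)")
  if (tremor_amp < 0 || noise_sd < 0 || emg_tremor_gain < 0)
    pds_error("parameter_error", "tremor_amp, noise_sd, emg_tremor_gain must be >= 0")
  if (speed_scale <= 0 || speed_scale > 1)
    pds_error("parameter_error", "speed_scale must be in (0, 1]")
  structure(list(micrographia_rate = micrographia_rate, tremor_amp = tremor_amp,
                 tremor_freq = tremor_freq, speed_scale = speed_scale,
                 pressure_mean = pressure_mean, pressure_sd = pressure_sd,
                 emg_tremor_gain = emg_tremor_gain, noise_sd = noise_sd),
            class = "severity_profile")
}

#' Default severity presets
#'
#' Calibrated so that default cohorts are separable but not trivially so;
#' every pathological parameter is ordered healthy <= mild <= moderate.
#'
#' @return Named list of [severity_profile()]s: `healthy`, `mild`, `moderate`.
#' @export
default_profiles <- function() {
  list(
    healthy  = severity_profile(0,    0,   5, 1.00, 0.55, 0.03, 0.0, 0.05),
    mild     = severity_profile(0.03, 0.4, 5, 0.85, 0.50, 0.05, 0.5, 0.10),
    moderate = severity_profile(0.08, 0.9, 5, 0.70, 0.45, 0.07, 1.0, 0.15)
  )
}

#' Cohort specification
#'
#' @param n_healthy,n_mild,n_moderate subject counts per group (>= 0).
#' @param reps_per_task analysed repetitions per subject per writing task
#'   (>= 1; the familiarisation repetition is never generated).
#' @param seed master integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_healthy = 11, n_mild = 12, n_moderate = 9,
                        reps_per_task = 3, seed = 1) {
  if (min(n_healthy, n_mild, n_moderate) < 0 || reps_per_task < 1)
    pds_error("parameter_error", "counts must be >= 0 and reps_per_task >= 1")
  structure(list(n_healthy = n_healthy, n_mild = n_mild,
                 n_moderate = n_moderate, reps_per_task = reps_per_task,
                 seed = seed), class = "cohort_spec")
}

# slowly drifting baseline: value + low-frequency random sinusoid + noise
drift_series <- function(n, t, base, drift_amp, noise) {
  ph <- stats::runif(2, 0, 2 * pi)
  f <- stats::runif(2, 0.05, 0.25)
  base + drift_amp * (sin(2 * pi * f[1] * t + ph[1]) +
                      0.5 * sin(2 * pi * f[2] * t + ph[2])) +
    stats::rnorm(n, 0, noise)
}

# shared pen-channel tail: pressure, azimuth, altitude around typical grips
pen_aux_channels <- function(t, profile) {
  n <- length(t)
  pressure <- drift_series(n, t, profile$pressure_mean, 0.05, profile$pressure_sd)
  pressure <- pmin(pmax(pressure, 0.02), 1)  # stay pen-down throughout the task
  azimuth <- wrap_angle(drift_series(n, t, 0.7, 0.1, 0.02))
  altitude <- pmin(pmax(drift_series(n, t, 1.0, 0.08, 0.02), 0.1), pi / 2)
  list(pressure = pressure, azimuth = azimuth, altitude = altitude)
}

#' Generate a synthetic spiral recording
#'
#' Pen tip traces an Archimedean spiral of exactly five anticlockwise turns
#' (polar angle 0 to 10*pi, radius growing linearly to `max_radius`), with a
#' tremor sinusoid added along the radial direction, white positional noise,
#' and duration `base_duration / speed_scale`.
#'
#' @param profile a [severity_profile()].
#' @param seed integer seed; same profile and seed give identical recordings.
#' @param subject_id,group,repetition metadata passed to [recording()].
#' @param pen_rate,emg_rate grid rates, Hz.
#' @param base_duration healthy-speed task duration, seconds.
#' @param max_radius outer spiral radius, millimetres.
#' @param channel_gains length-8 per-channel sEMG gains (electrode
#'   placement), passed to [generate_emg()].
#' @return A [recording()] with `pattern = "spiral"`.
#' @export
generate_spiral <- function(profile, seed, subject_id = "synthetic",
                            group = "healthy", repetition = 1L,
                            pen_rate = 140, emg_rate = 200,
                            base_duration = 10, max_radius = 50,
                            channel_gains = rep(1, 8)) {
  withr::local_seed(seed)
  dur <- base_duration / profile$speed_scale
  t <- seq(0, dur, by = 1 / pen_rate)
  theta <- 10 * pi * t / dur
  r <- 2 + (max_radius - 2) * theta / (10 * pi)
  r <- r + profile$tremor_amp * sin(2 * pi * profile$tremor_freq * t + stats::runif(1, 0, 2 * pi))
  x <- r * cos(theta) + stats::rnorm(length(t), 0, profile$noise_sd)
  y <- r * sin(theta) + stats::rnorm(length(t), 0, profile$noise_sd)
  aux <- pen_aux_channels(t, profile)
  pen <- pen_stream(t, x, y, aux$pressure, aux$azimuth, aux$altitude)
  emg <- generate_emg(profile, dur, seed = seed + 1L, rate = emg_rate,
                      channel_gains = channel_gains)
  recording(subject_id, group, "spiral", repetition, pen, emg, pen_rate = pen_rate)
}

#' Generate a synthetic letter-sequence recording
#'
#' Eight "l"-like strokes modelled as smooth vertical arches; stroke k has
#' height `height * (1 - micrographia_rate)^(k-1)` (micrographia as a
#' geometric decay), the baseline advances in x, and tremor/noise are added
#' as in [generate_spiral()] but along the vertical writing axis.
#'
#' @param profile a [severity_profile()].
#' @param height nominal letter height in cm, one of 2.5 or 5.0.
#' @param seed integer seed.
#' @inheritParams generate_spiral
#' @param base_stroke_duration healthy-speed duration of one stroke, seconds.
#' @return A [recording()] with `pattern = "letters_small"` (2.5 cm) or
#'   `"letters_large"` (5 cm).
#' @export
generate_letters <- function(profile, height = 2.5, seed = 1,
                             subject_id = "synthetic", group = "healthy",
                             repetition = 1L, pen_rate = 140, emg_rate = 200,
                             base_stroke_duration = 0.45,
                             channel_gains = rep(1, 8)) {
  if (!height %in% c(2.5, 5.0))
    pds_error("parameter_error", "height must be 2.5 or 5.0 cm")
  pattern <- if (height == 2.5) "letters_small" else "letters_large"
  withr::local_seed(seed)
  n_strokes <- 8L
  stroke_dur <- base_stroke_duration / profile$speed_scale
  dur <- n_strokes * stroke_dur
  t <- seq(0, dur, by = 1 / pen_rate)
  s_glob <- t / stroke_dur                      # stroke coordinate, 0..8
  k <- pmin(floor(s_glob), n_strokes - 1)       # stroke index 0..7
  s <- s_glob - k                               # within-stroke phase 0..1
  h_mm <- height * 10
  hk <- h_mm * (1 - profile$micrographia_rate)^k
  y <- hk * sin(pi * s)^2
  stroke_width <- 6
  x <- stroke_width * (k + s) + 1.5 * sin(pi * s)^2   # slight rightward bow
  y <- y + profile$tremor_amp * sin(2 * pi * profile$tremor_freq * t + stats::runif(1, 0, 2 * pi))
  x <- x + stats::rnorm(length(t), 0, profile$noise_sd)
  y <- y + stats::rnorm(length(t), 0, profile$noise_sd)
  aux <- pen_aux_channels(t, profile)
  pen <- pen_stream(t, x, y, aux$pressure, aux$azimuth, aux$altitude)
  emg <- generate_emg(profile, dur, seed = seed + 1L, rate = emg_rate,
                      channel_gains = channel_gains)
  recording(subject_id, group, pattern, repetition, pen, emg, pen_rate = pen_rate)
}

#' Generate a synthetic 8-channel sEMG stream
#'
#' Zero-mean band-limited Gaussian noise per channel (passband 20 Hz to
#' `min(150, 0.45 * rate)` Hz), amplitude-modulated by a tremor-band
#' (4-6 Hz) envelope scaled by `emg_tremor_gain`. Per-channel gains model
#' electrode placement differences.
#'
#' @param profile a [severity_profile()].
#' @param duration seconds (> 0).
#' @param seed integer seed.
#' @param rate sampling rate, Hz.
#' @param channel_gains numeric length-8 per-channel amplitude gains.
#' @return An [emg_stream()].
#' @export
generate_emg <- function(profile, duration, seed = 1, rate = 200,
                         channel_gains = rep(1, 8)) {
  if (duration <= 0) pds_error("parameter_error", "duration must be > 0")
  withr::local_seed(seed)
  n <- max(2L, floor(duration * rate) + 1L)
  t <- (seq_len(n) - 1) / rate
  hi <- min(150, 0.45 * rate)
  bf <- signal::butter(4, c(20, hi) / (rate / 2), type = "pass")
  tremor_f <- stats::runif(1, 4, 6)
  ch <- matrix(0, n, 8)
  for (j in 1:8) {
    raw <- stats::rnorm(n)
    filt <- signal::filtfilt(bf, raw)
    env <- 1 + profile$emg_tremor_gain *
      (0.5 + 0.5 * sin(2 * pi * tremor_f * t + stats::runif(1, 0, 2 * pi)))
    ch[, j] <- channel_gains[j] * filt * env
  }
  emg_stream(t, ch, rate)
}

#' Generate a full synthetic cohort
#'
#' Subjects in three groups, each performing the three writing tasks
#' (anticlockwise five-turn spiral; 8-letter sequences at 2.5 cm and 5 cm)
#' `reps_per_task` times. Per-subject random effects (baseline speed,
#' pressure, tremor and sEMG gains; log-normal on positive parameters) are
#' drawn once per subject so repetitions within a subject correlate.
#' Deterministic per `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param profiles named list of [severity_profile()]s for `healthy`,
#'   `mild`, `moderate`; defaults to [default_profiles()].
#' @return List of [recording()]s of length
#'   `(n_healthy + n_mild + n_moderate) * 3 * reps_per_task`.
#' @export
generate_cohort <- function(spec, profiles = default_profiles()) {
  groups <- rep(GROUPS, times = c(spec$n_healthy, spec$n_mild, spec$n_moderate))
  if (length(groups) == 0) return(list())
  recs <- list()
  withr::local_seed(spec$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 10L, length(groups) * 3 * spec$reps_per_task + length(groups))
  si <- 0L
  for (i in seq_along(groups)) {
    g <- groups[i]
    base <- profiles[[g]]
    si <- si + 1L
    withr::with_seed(subject_seeds[si], {
      # log-normal subject random effects; wider on the noise-like
      # parameters (tremor, positional noise, sEMG modulation) than on the
      # tightly task-constrained ones (speed, pressure)
      lf <- exp(stats::rnorm(6, 0, c(0.12, 0.12, 0.35, 0.35, 0.35, 0.25)))
      subj <- base
      subj$speed_scale   <- min(1, base$speed_scale * lf[1])
      subj$pressure_mean <- min(0.95, max(0.05, base$pressure_mean * lf[2]))
      subj$tremor_amp    <- base$tremor_amp * lf[3]
      subj$emg_tremor_gain <- base$emg_tremor_gain * lf[4]
      subj$noise_sd      <- base$noise_sd * lf[5]
      subj$micrographia_rate <- min(0.5, base$micrographia_rate * lf[6])
      # electrode-placement variability: per-subject, per-channel sEMG gains
      gains <- exp(stats::rnorm(8, 0, 0.35))
    })
    id <- sprintf("S%02d_%s", i, g)
    for (rep_i in seq_len(spec$reps_per_task)) {
      for (task in c("spiral", "letters_small", "letters_large")) {
        si <- si + 1L
        sd_k <- subject_seeds[si]
        rec <- switch(task,
          spiral = generate_spiral(subj, sd_k, id, g, rep_i, channel_gains = gains),
          letters_small = generate_letters(subj, 2.5, sd_k, id, g, rep_i, channel_gains = gains),
          letters_large = generate_letters(subj, 5.0, sd_k, id, g, rep_i, channel_gains = gains))
        recs[[length(recs) + 1L]] <- rec
      }
    }
  }
  recs
}
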