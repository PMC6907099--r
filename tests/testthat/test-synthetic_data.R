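test_that("generated spirals wind five anticlockwise turns", {
  for (seed in c(3, 17)) {
    rec <- generate_spiral(default_profiles()$healthy, seed)
    down <- rec$pen$pressure > 0
    cx <- mean(rec$pen$x[down]); cy <- mean(rec$pen$y[down])
    ang <- pdscribe:::unwrap_phase(atan2(rec$pen$y - cy, rec$pen$x - cx))
    span <- ang[length(ang)] - ang[1]
    expect_lt(abs(span - 10 * pi) / (10 * pi), 0.02)
    # monotone after smoothing (anticlockwise: increasing angle)
    sm <- stats::filter(ang, rep(1 / 21, 21))
    expect_true(all(diff(sm[!is.na(sm)]) > 0))
  }
})

test_that("generators are deterministic per seed", {
  p <- default_profiles()$moderate
  a <- generate_spiral(p, 12); b <- generate_spiral(p, 12)
  expect_identical(a, b)
  l1 <- generate_letters(p, 5.0, 9); l2 <- generate_letters(p, 5.0, 9)
  expect_identical(l1, l2)
  e1 <- generate_emg(p, 1.5, 4); e2 <- generate_emg(p, 1.5, 4)
  expect_identical(e1, e2)
})

test_that("letter strokes decay geometrically with the micrographia rate", {
  rec <- generate_letters(clean_profile(0.1), 2.5, seed = 5)
  pen <- resample_uniform(rec$pen, 140)
  pk <- detect_peaks(pen$y)
  expect_equal(nrow(pk$upper), 8)
  expect_equal(pk$upper$value[8] / pk$upper$value[1], 0.9^7, tolerance = 0.02)

  # rate 0, no noise: all 8 peaks equal, alpha = 0
  rec0 <- generate_letters(clean_profile(0), 5.0, seed = 5)
  pen0 <- resample_uniform(rec0$pen, 140)
  pk0 <- detect_peaks(pen0$y)
  expect_equal(nrow(pk0$upper), 8)
  expect_lt(diff(range(pk0$upper$value)), 1e-6)
  expect_lt(letter_size_features(pen0)$alpha, 1e-6)

  # peak count is 8 under pathological profiles too
  recm <- generate_letters(default_profiles()$moderate, 2.5, seed = 21)
  expect_equal(nrow(detect_peaks(resample_uniform(recm$pen, 140)$y)$upper), 8)
})

test_that("synthetic sEMG is zero-mean and RMS-homogeneous in channel gains", {
  p <- default_profiles()$healthy
  e <- generate_emg(p, 3, seed = 8)
  for (j in 1:8) {
    ch <- e$channels[, j]
    expect_lt(abs(mean(ch)), 3 * sd(ch) / sqrt(length(ch)))
  }
  e2 <- generate_emg(p, 3, seed = 8, channel_gains = rep(2, 8))
  expect_equal(apply(e2$channels, 2, emg_rms),
               2 * apply(e$channels, 2, emg_rms), tolerance = 1e-12)
})

test_that("pathological presets shift sEMG RMS upward on every channel", {
  p <- default_profiles()
  rms_mean <- function(prof) rowMeans(vapply(
    1:50, function(s) emg_features(generate_emg(prof, 2, seed = s))$rms, numeric(8)))
  expect_true(all(rms_mean(p$moderate) > rms_mean(p$healthy)))
})

test_that("pathological presets raise the spiral precision index", {
  p <- default_profiles()
  idx <- function(prof) vapply(1:50, function(s)
    spiral_precision(resample_uniform(generate_spiral(prof, s)$pen, 140))$index,
    numeric(1))
  expect_gt(mean(idx(p$moderate)), mean(idx(p$healthy)))
})

test_that("mean regression-line angle increases with the micrographia rate", {
  alpha_mean <- function(rate) mean(vapply(1:50, function(s) {
    prof <- severity_profile(micrographia_rate = rate, tremor_amp = 0.2,
                             noise_sd = 0.1)
    letter_size_features(resample_uniform(generate_letters(prof, 2.5, s)$pen, 140))$alpha
  }, numeric(1)))
  a <- vapply(c(0, 0.04, 0.08), alpha_mean, numeric(1))
  expect_true(all(diff(a) > 0))
})

test_that("cohort generation honours counts, labels and determinism", {
  spec <- cohort_spec(11, 12, 9, reps_per_task = 3, seed = 20260901)
  recs <- default_cohort()
  expect_length(recs, 32 * 3 * 3)
  expect_identical(sort(unique(vapply(recs, `[[`, "", "group"))),
                   sort(c("healthy", "mild", "moderate")))
  # same spec twice -> identical cohorts (spot-check first/last recordings)
  recs2 <- generate_cohort(spec)
  expect_identical(recs2[[1]], recs[[1]])
  expect_identical(recs2[[length(recs2)]], recs[[length(recs)]])

  small <- generate_cohort(cohort_spec(0, 0, 1, reps_per_task = 1, seed = 2))
  expect_length(small, 3)
  expect_true(all(vapply(small, `[[`, "", "group") == "moderate"))
})

test_that("every generated recording satisfies the stream invariants", {
  recs <- generate_cohort(cohort_spec(1, 1, 1, reps_per_task = 1, seed = 14))
  for (rec in recs) {
    expect_true(all(diff(rec$pen$t) > 0))
    expect_true(all(rec$pen$pressure >= 0 & rec$pen$pressure <= 1))
    expect_true(all(rec$pen$altitude >= 0 & rec$pen$altitude <= pi / 2))
    expect_equal(ncol(rec$emg$channels), 8)
  }
})
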