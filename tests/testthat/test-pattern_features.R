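test_that("peak detection recovers hand-known extrema of a triangular wave", {
  # 8 teeth with heights 8,7,...,1 over a zero baseline
  heights <- 8:1
  y <- unlist(lapply(heights, function(h) c(seq(0, h, length.out = 11)[-11],
                                            seq(h, 0, length.out = 11)[-11])))
  y <- c(y, 0)
  pk <- detect_peaks(y, prominence_frac = 0.05)
  expect_equal(pk$upper$value, as.numeric(heights))
  expect_true(all(pk$lower$value == 0))
  expect_true(all(diff(pk$upper$index) > 0))

  expect_error(detect_peaks(rep(1, 100)), class = "pdscribe_insufficient_peaks")
})

test_that("peak prominence filters shallow ripples", {
  y <- sin(seq(0, 6 * pi, length.out = 400)) +
    0.05 * sin(seq(0, 120 * pi, length.out = 400))
  pk <- detect_peaks(y, prominence_frac = 0.2)
  expect_equal(nrow(pk$upper), 3)   # only the three main crests survive
})

test_that("regression line matches hand OLS and is translation invariant", {
  fit <- regression_line(c(0, 1, 2), c(0, 1, 0))
  expect_equal(fit$slope, 0)
  expect_equal(fit$intercept, 1 / 3)
  expect_equal(fit$r2, 0)

  fit2 <- regression_line(1:5, 2 * (1:5) + 3)
  expect_equal(fit2$r2, 1)
  expect_equal(fit2$slope, 2)

  y <- withr::with_seed(2, rnorm(10)); t <- 1:10
  f0 <- regression_line(t, y); f1 <- regression_line(t, y + 5)
  expect_equal(f1$slope, f0$slope)
  expect_equal(f1$r2, f0$r2)

  expect_error(regression_line(rep(1, 4), 1:4), class = "pdscribe_degenerate_abscissa")
  expect_error(regression_line(1:2, 1:2), class = "pdscribe_insufficient_data")
})

test_that("alpha equals the closed-form angle between the peak lines", {
  # arches whose apex heights follow a -0.1 mm/s line over a flat baseline
  t <- seq(0, 8, by = 1 / 140)
  k <- pmin(floor(t), 7); s <- t - k
  apex_t <- k + 0.5
  h <- 10 - 0.1 * apex_t
  pen <- make_pen(t, 6 * t, h * sin(pi * s)^2)
  ls <- letter_size_features(pen)
  expect_equal(ls$alpha, atan(0.1), tolerance = 0.02)
  expect_equal(ls$alpha_deg, 5.71, tolerance = 0.02)
  expect_gt(ls$r2_up, 0.99)   # apices are collinear
})

test_that("spiral precision index is ~0 for circles and equiangular spirals", {
  th <- seq(0, 2 * pi, length.out = 1001)
  circle <- make_pen(seq_along(th) / 100, 10 * cos(th), 10 * sin(th))
  expect_lt(spiral_precision(circle)$index, 1e-3)

  # log spiral about its pole: beta constant at atan(1/a)
  th2 <- seq(0, 6 * pi, length.out = 50001)
  r <- exp(0.1 * th2)
  spiral <- make_pen(seq_along(th2) / 1000, r * cos(th2), r * sin(th2))
  sp <- spiral_precision(spiral, center = c(0, 0))
  expect_lt(sp$index, 1e-2)
  expect_equal(mean(sp$beta_series), atan(1 / 0.1), tolerance = 1e-3)

  # point-symmetric double arm: the centroid IS the pole, default centre works
  xy <- rbind(cbind(-r * cos(th2), -r * sin(th2)), cbind(r * cos(th2), r * sin(th2)))
  double <- make_pen(seq_len(nrow(xy)) / 1000, xy[, 1], xy[, 2])
  expect_lt(spiral_precision(double)$index, 1e-2)

  # an Archimedean spiral's pitch angle varies with radius: index > 0
  th3 <- seq(0, 10 * pi, length.out = 4001)
  arch <- make_pen(seq_along(th3) / 400, (2 + th3) * cos(th3), (2 + th3) * sin(th3))
  expect_gt(spiral_precision(arch)$index, 0.01)
})

test_that("pattern features are invariant to rigid motions and scaling", {
  rec <- generate_spiral(default_profiles()$mild, 55)
  pen <- resample_uniform(rec$pen, 140)
  base <- spiral_precision(pen)$index

  rot <- 0.7; cr <- cos(rot); sr <- sin(rot)
  pen_rot <- pen
  pen_rot$x <- cr * pen$x - sr * pen$y + 12
  pen_rot$y <- sr * pen$x + cr * pen$y - 3
  expect_equal(spiral_precision(pen_rot)$index, base, tolerance = 1e-9)

  pen_scaled <- pen; pen_scaled$x <- 3 * pen$x; pen_scaled$y <- 3 * pen$y
  expect_equal(spiral_precision(pen_scaled)$index, base, tolerance = 1e-12)

  # alpha is translation invariant
  lrec <- generate_letters(default_profiles()$mild, 2.5, 56)
  lpen <- resample_uniform(lrec$pen, 140)
  a0 <- letter_size_features(lpen)$alpha
  lpen2 <- lpen; lpen2$y <- lpen$y + 25; lpen2$x <- lpen$x - 8
  expect_equal(letter_size_features(lpen2)$alpha, a0, tolerance = 1e-9)
})

test_that("radial tremor of growing amplitude inflates the spiral index", {
  idx_at <- function(amp) mean(vapply(1:50, function(s) {
    prof <- severity_profile(tremor_amp = amp, noise_sd = 0.05)
    spiral_precision(resample_uniform(generate_spiral(prof, s)$pen, 140))$index
  }, numeric(1)))
  idx <- vapply(c(0, 0.45, 0.9), idx_at, numeric(1))
  expect_true(all(diff(idx) > 0))
})
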