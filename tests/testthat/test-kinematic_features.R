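test_that("derivative chain reproduces closed-form limits", {
  t <- seq(0, 2, by = 0.01)
  # linear motion: constant velocity, zero acceleration and jerk
  kin <- derivative_chain(make_pen(t, 5 * t, 0 * t), lowpass_hz = NULL)
  expect_equal(kin$v_cart, rep(5, length(kin$v_cart)), tolerance = 1e-9)
  expect_equal(max(abs(kin$a_cart)), 0, tolerance = 1e-9)
  expect_equal(max(abs(kin$j_cart)), 0, tolerance = 1e-8)

  # cubic: third derivative 6 everywhere (central differences are exact here)
  kin3 <- derivative_chain(make_pen(t, t^3, 0 * t), lowpass_hz = NULL)
  expect_equal(kin3$jx, rep(6, length(kin3$jx)), tolerance = 1e-6)

  # sinusoid at 100x oversampling: velocity amplitude A*omega within 1%
  A <- 2; f <- 1; ts <- seq(0, 3, by = 1 / 100)
  kin_s <- derivative_chain(make_pen(ts, A * sin(2 * pi * f * ts), 0 * ts),
                            lowpass_hz = NULL)
  expect_equal(max(abs(kin_s$vx)), A * 2 * pi * f, tolerance = 0.01)
})

test_that("derivative chain enforces grid preconditions", {
  expect_error(derivative_chain(make_pen(c(0, 0.1, 0.3, 0.32), 1:4, 1:4)),
               class = "pdscribe_precondition_error")
  expect_error(derivative_chain(make_pen(0:2 / 10, 1:3, 1:3)),
               class = "pdscribe_precondition_error")
  expect_error(derivative_chain(make_pen(0:5 / 10, 1:6, 1:6)),
               class = "pdscribe_insufficient_data")
  kin <- derivative_chain(make_pen(0:6 / 10, (0:6)^2, 0:6 * 0), lowpass_hz = NULL)
  expect_length(kin$jx, 1)
  expect_length(kin$vx, 1)  # all series share the common support
})

test_that("summaries use the population convention", {
  expect_equal(summarize_series(c(2, 2, 2)), list(mean = 2, sd = 0))
  expect_equal(summarize_series(c(1, 3)), list(mean = 2, sd = 1))
  x <- withr::with_seed(4, rnorm(50))
  s0 <- summarize_series(x); s1 <- summarize_series(x + 13.5)
  expect_equal(s1$mean, s0$mean + 13.5)
  expect_equal(s1$sd, s0$sd)
  expect_error(summarize_series(1), class = "pdscribe_insufficient_data")
})

test_that("tilt and pressure summaries handle pen-down gating and circularity", {
  t <- seq(0, 1, by = 0.01); n <- length(t)
  pen <- make_pen(t, t, t, pressure = 0.5, azimuth = 0.3, altitude = pi / 2)
  tp <- tilt_pressure_features(pen)
  expect_equal(tp$pressure, list(mean = 0.5, sd = 0))
  expect_equal(tp$altitude, list(mean = pi / 2, sd = 0))

  # azimuth hopping between the two sides of the +/-pi cut: sd on the
  # unwrapped series is small, not ~pi
  az <- rep(c(pi - 0.05, -pi + 0.05), length.out = n)
  pen2 <- make_pen(t, t, t, azimuth = az)
  expect_lt(tilt_pressure_features(pen2)$azimuth$sd, 0.1)

  expect_error(tilt_pressure_features(make_pen(t, t, t, pressure = 0)),
               class = "pdscribe_empty_task")
})

test_that("kinematic features are translation invariant and speed covariant", {
  rec <- generate_spiral(clean_profile(), 77)
  pen <- resample_uniform(rec$pen, 140)
  kin <- derivative_chain(pen, lowpass_hz = NULL)
  pen_shift <- pen; pen_shift$x <- pen$x + 40; pen_shift$y <- pen$y - 17
  kin_shift <- derivative_chain(pen_shift, lowpass_hz = NULL)
  # the filtered chain is translation invariant too
  expect_equal(derivative_chain(pen_shift)$v_cart, derivative_chain(pen)$v_cart,
               tolerance = 1e-9)
  expect_equal(kin_shift[c("vx", "vy", "ax", "ay", "jx", "jy")],
               kin[c("vx", "vy", "ax", "ay", "jx", "jy")], tolerance = 1e-9)

  # drawing the same path twice as fast doubles v, quadruples a, octuples j
  s <- 2
  pen_fast <- pen_stream(pen$t / s, pen$x, pen$y, pen$pressure,
                         pen$azimuth, pen$altitude)
  kin_fast <- derivative_chain(pen_fast, lowpass_hz = NULL)
  expect_equal(mean(kin_fast$v_cart) / mean(kin$v_cart), s, tolerance = 0.01)
  expect_equal(mean(kin_fast$a_cart) / mean(kin$a_cart), s^2, tolerance = 0.02)
  expect_equal(mean(kin_fast$j_cart) / mean(kin$j_cart), s^3, tolerance = 0.05)
})
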