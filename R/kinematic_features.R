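# Pen-tip kinematics: velocity / acceleration / jerk chains (X, Y and
# Cartesian magnitude) plus pressure and tilt summaries.

central_diff <- function(v, dt) (v[-(1:2)] - v[seq_len(length(v) - 2)]) / (2 * dt)

#' Velocity, acceleration and jerk series of a pen trajectory
#'
#' First, second and third time-derivatives of the x-y position by repeated
#' interior central differences on the uniform grid, yielding nine series:
#' `vx, vy, v_cart, ax, ay, a_cart, jx, jy, j_cart` (mm/s, mm/s^2, mm/s^3),
#' all truncated to the common valid support (three samples lost at each
#' end). A zero-phase Butterworth low-pass (default 12 Hz cutoff) is applied
#' to x and y before differentiation because raw third derivatives are
#' noise-dominated; set `lowpass_hz = NULL` to disable.
#'
#' @param pen a uniform-grid [pen_stream()] (use [resample_uniform()] first).
#' @param lowpass_hz cutoff of the zero-phase pre-filter in Hz, or `NULL`.
#' @return List of the nine series plus `dt`.
#' @export
derivative_chain <- function(pen, lowpass_hz = 12) {
  n <- nrow(pen)
  if (n < 4) pds_error("precondition_error", "derivative chain needs >= 4 samples")
  dts <- diff(pen$t)
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > 1e-6 * dt + 1e-12)
    pds_error("precondition_error", "derivative chain needs a uniform time grid")
  if (n < 7) pds_error("insufficient_data", "jerk needs >= 7 samples on the grid")
  x <- pen$x; y <- pen$y
  if (!is.null(lowpass_hz)) {
    nyq <- 1 / (2 * dt)
    if (lowpass_hz < nyq) {
      bf <- signal::butter(2, lowpass_hz / nyq, type = "low")
      # detrend on the endpoint line before filtering: avoids start/end
      # transients and keeps the filter exactly transparent to translations
      # and linear motion
      lp <- function(v) {
        trend <- seq(v[1], v[n], length.out = n)
        signal::filtfilt(bf, v - trend) + trend
      }
      x <- lp(x); y <- lp(y)
    }
  }
  vx <- central_diff(x, dt);  vy <- central_diff(y, dt)
  ax <- central_diff(vx, dt); ay <- central_diff(vy, dt)
  jx <- central_diff(ax, dt); jy <- central_diff(ay, dt)
  m <- length(jx)                       # common support: interior of interior
  trim <- function(v) v[seq.int(1 + (length(v) - m) / 2, length.out = m)]
  vx <- trim(vx); vy <- trim(vy); ax <- trim(ax); ay <- trim(ay)
  list(vx = vx, vy = vy, v_cart = sqrt(vx^2 + vy^2),
       ax = ax, ay = ay, a_cart = sqrt(ax^2 + ay^2),
       jx = jx, jy = jy, j_cart = sqrt(jx^2 + jy^2), dt = dt)
}

#' Mean and population standard deviation of a series
#'
#' @param x numeric vector, length >= 2.
#' @return List with `mean` and `sd` (population, 1/n convention).
#' @export
summarize_series <- function(x) {
  if (length(x) < 2) pds_error("insufficient_data", "summary needs >= 2 samples")
  m <- mean(x)
  list(mean = m, sd = sqrt(mean((x - m)^2)))
}

#' Pressure, azimuth and altitude summaries of a pen stream
#'
#' Mean and population sd over pen-down samples (pressure > 0). Azimuth is a
#' circular quantity: its statistics are computed on the phase-unwrapped
#' series so a pen hovering around the +/-pi cut does not produce a
#' spurious sd of ~pi.
#'
#' @param pen a [pen_stream()].
#' @return Named list of `SummaryPair`s: `pressure`, `azimuth`, `altitude`.
#' @export
tilt_pressure_features <- function(pen) {
  down <- pen$pressure > 0
  if (sum(down) < 2) pds_error("empty_task", "no pen-down samples in stream")
  list(pressure = summarize_series(pen$pressure[down]),
       azimuth  = summarize_series(unwrap_phase(pen$azimuth[down])),
       altitude = summarize_series(pen$altitude[down]))
}
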