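# Domain types and on-disk format for pen-tablet / sEMG recordings.

#' @keywords internal
pds_error <- function(class, message, call. = FALSE) {
  stop(structure(
    class = c(paste0("pdscribe_", class), "pdscribe_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

GROUPS   <- c("healthy", "mild", "moderate")
PATTERNS <- c("spiral", "letters_small", "letters_large")

#' Construct a pen stream
#'
#' A pen stream is a data frame of pen-tip samples from a graphic tablet:
#' time `t` (seconds), position `x`, `y` (millimetres, x rightward, y upward,
#' origin at the tablet lower-left), normalized `pressure` in \[0, 1\], and the
#' pen orientation angles `azimuth` in \[-pi, pi) and `altitude` in \[0, pi/2\]
#' (radians; altitude pi/2 means the pen is vertical).
#'
#' @param t,x,y,pressure,azimuth,altitude numeric vectors of equal length.
#' @return A `data.frame` of class `pen_stream` with the six columns above.
#' @export
pen_stream <- function(t, x, y, pressure, azimuth, altitude) {
  df <- data.frame(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                   pressure = as.numeric(pressure),
                   azimuth = as.numeric(azimuth), altitude = as.numeric(altitude))
  validate_pen_stream(df)
  class(df) <- c("pen_stream", "data.frame")
  df
}

validate_pen_stream <- function(df) {
  if (nrow(df) == 0) pds_error("format_error", "pen stream is empty")
  if (any(diff(df$t) <= 0))
    pds_error("format_error", "pen stream field 't' is not strictly increasing")
  if (any(df$pressure < 0 | df$pressure > 1))
    pds_error("format_error", "pen stream field 'pressure' outside [0, 1]")
  if (any(df$altitude < 0 | df$altitude > pi / 2 + 1e-9))
    pds_error("format_error", "pen stream field 'altitude' outside [0, pi/2]")
  if (any(df$azimuth < -pi - 1e-9 | df$azimuth >= pi + 1e-9))
    pds_error("format_error", "pen stream field 'azimuth' outside [-pi, pi)")
  invisible(df)
}

#' Construct an 8-channel sEMG stream
#'
#' @param t numeric vector of timestamps (seconds) on a uniform grid.
#' @param channels numeric matrix with 8 columns (one per armband channel),
#'   raw dimensionless armband units, one row per sample.
#' @param rate sampling rate in Hz.
#' @return An object of class `emg_stream` with elements `t`, `channels`, `rate`.
#' @export
emg_stream <- function(t, channels, rate) {
  channels <- as.matrix(channels)
  if (ncol(channels) != 8)
    pds_error("format_error",
              sprintf("emg stream field 'channels' must have 8 channels, got %d", ncol(channels)))
  if (nrow(channels) < 2 || length(t) != nrow(channels))
    pds_error("format_error", "emg stream needs >= 2 samples with matching 't'")
  colnames(channels) <- paste0("ch", 1:8)
  structure(list(t = as.numeric(t), channels = channels, rate = rate),
            class = "emg_stream")
}

#' Construct a recording
#'
#' One analysed repetition of one writing task: the pen stream, the sEMG
#' stream and the subject metadata. Both clocks share t = 0 at the first
#' pen-down pressure sample.
#'
#' @param subject_id opaque subject identifier.
#' @param group one of `"healthy"`, `"mild"`, `"moderate"`.
#' @param pattern one of `"spiral"`, `"letters_small"`, `"letters_large"`.
#' @param repetition integer >= 1.
#' @param pen a [pen_stream()].
#' @param emg an [emg_stream()].
#' @param pen_rate pen sampling rate in Hz (grid rate used on resampling).
#' @return An object of class `recording`.
#' @export
recording <- function(subject_id, group, pattern, repetition, pen, emg,
                      pen_rate = 140) {
  group <- match.arg(group, GROUPS)
  pattern <- match.arg(pattern, PATTERNS)
  if (repetition < 1) pds_error("format_error", "repetition must be >= 1")
  validate_pen_stream(pen)
  if (!inherits(emg, "emg_stream")) pds_error("format_error", "emg must be an emg_stream")
  structure(list(subject_id = as.character(subject_id), group = group,
                 pattern = pattern, repetition = as.integer(repetition),
                 pen = pen, emg = emg, pen_rate = pen_rate),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject %s (%s), %s rep %d: %d pen samples (%.2f s), 8-ch sEMG %d samples @ %g Hz\n",
              x$subject_id, x$group, x$pattern, x$repetition,
              nrow(x$pen), diff(range(x$pen$t)), nrow(x$emg$channels), x$emg$rate))
  invisible(x)
}

# On-disk recording bundle: a directory holding meta.json plus pen.csv
# (t,x,y,pressure,azimuth,altitude) and emg.csv (t,ch1..ch8); UTF-8, '.'
# decimal separator. Numeric values are written with 15 significant digits,
# the declared round-trip precision.
fmt_num <- function(x) sprintf("%.15g", x)

#' Write a recording bundle to disk
#'
#' @param rec a [recording()].
#' @param path directory to create/overwrite with `meta.json`, `pen.csv`,
#'   `emg.csv`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(subject_id = rec$subject_id, group = rec$group,
               pattern = rec$pattern, repetition = rec$repetition,
               pen_rate_hz = rec$pen_rate, emg_rate_hz = rec$emg$rate,
               pressure_max = 1.0)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  pen <- rec$pen
  pen_chr <- vapply(pen, fmt_num, character(nrow(pen)))
  if (nrow(pen) == 1) pen_chr <- matrix(pen_chr, nrow = 1)
  writeLines(c(paste(names(pen), collapse = ","),
               apply(pen_chr, 1, paste, collapse = ",")),
             file.path(path, "pen.csv"))
  emg_mat <- cbind(t = rec$emg$t, rec$emg$channels)
  emg_chr <- apply(emg_mat, 2, fmt_num)
  writeLines(c(paste(colnames(emg_mat), collapse = ","),
               apply(emg_chr, 1, paste, collapse = ",")),
             file.path(path, "emg.csv"))
  invisible(path)
}

#' Read a recording bundle from disk
#'
#' @param path directory written by [write_recording()].
#' @return A [recording()].
#' @export
read_recording <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) pds_error("format_error", paste("no meta.json under", path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("subject_id", "group", "pattern", "repetition", "pressure_max"))
    if (is.null(meta[[f]])) pds_error("format_error", paste("meta.json missing field", f))
  pen <- utils::read.csv(file.path(path, "pen.csv"))
  need <- c("t", "x", "y", "pressure", "azimuth", "altitude")
  if (!identical(names(pen), need))
    pds_error("format_error", "pen.csv header must be t,x,y,pressure,azimuth,altitude")
  if (any(diff(pen$t) <= 0))
    pds_error("format_error", "pen.csv field 't' is not strictly increasing")
  pmax_dev <- meta$pressure_max
  if (pmax_dev <= 0) pds_error("format_error", "meta.json field pressure_max must be > 0")
  pen$pressure <- pen$pressure / pmax_dev
  emg <- utils::read.csv(file.path(path, "emg.csv"))
  if (ncol(emg) != 9)
    pds_error("format_error",
              sprintf("emg.csv must have columns t,ch1..ch8; found %d sEMG columns", ncol(emg) - 1))
  recording(meta$subject_id, meta$group, meta$pattern, meta$repetition,
            pen_stream(pen$t, pen$x, pen$y, pen$pressure, pen$azimuth, pen$altitude),
            emg_stream(emg$t, as.matrix(emg[, -1]), meta$emg_rate_hz),
            pen_rate = meta$pen_rate_hz)
}

# wrap an angle into [-pi, pi)
wrap_angle <- function(a) ((a + pi) %% (2 * pi)) - pi

#' Resample a pen stream onto a uniform time grid
#'
#' Linear interpolation of all channels onto a grid of step `1/rate` spanning
#' `[t_first, t_last]`. The angular channels (azimuth) are interpolated on the
#' shortest arc: the series is unwrapped before interpolation and re-wrapped
#' to \[-pi, pi) afterwards, so a step from -3.1 to 3.1 rad passes through
#' +/-pi, not through 0.
#'
#' @param pen a [pen_stream()].
#' @param rate target grid rate in Hz (> 0).
#' @return A `pen_stream` on the uniform grid.
#' @export
resample_uniform <- function(pen, rate) {
  if (nrow(pen) < 2) pds_error("insufficient_data", "resampling needs >= 2 pen samples")
  if (rate <= 0) pds_error("parameter_error", "rate must be > 0")
  t0 <- pen$t[1]; t1 <- pen$t[nrow(pen)]
  n <- floor((t1 - t0) * rate + 1e-9) + 1
  grid <- t0 + (seq_len(n) - 1) / rate
  lin <- function(v) stats::approx(pen$t, v, xout = grid, rule = 2)$y
  az_unwrapped <- unwrap_phase(pen$azimuth)
  alt <- lin(pen$altitude)
  pen_stream(grid, lin(pen$x), lin(pen$y),
             pmin(pmax(lin(pen$pressure), 0), 1),
             wrap_angle(stats::approx(pen$t, az_unwrapped, xout = grid, rule = 2)$y),
             pmin(pmax(alt, 0), pi / 2))
}

# classic phase unwrap: remove 2*pi jumps between consecutive samples
unwrap_phase <- function(a) {
  d <- diff(a)
  a + c(0, cumsum(-2 * pi * round(d / (2 * pi))))
}
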