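# Muscle-activity features: per-channel RMS and tolerance-gated,
# length-normalized zero-crossing rates.

#' Root mean square of a signal
#'
#' `sqrt(mean(x^2))`, the standard sEMG amplitude/activity index.
#'
#' @param x numeric vector, length >= 1.
#' @return Non-negative scalar in the signal's raw units.
#' @export
emg_rms <- function(x) {
  if (length(x) < 1) pds_error("insufficient_data", "rms needs a non-empty channel")
  sqrt(mean(x^2))
}

#' Zero-crossing tolerance of an sEMG stream
#'
#' The arithmetic mean over the 8 channels of the per-channel population
#' standard deviation (1/n convention). Used to gate zero-crossing counts
#' against noise; scales linearly with the signal amplitude.
#'
#' @param channels numeric matrix, one column per channel, >= 2 rows.
#' @return Non-negative scalar, raw signal units.
#' @export
zc_tolerance <- function(channels) {
  channels <- as.matrix(channels)
  if (nrow(channels) < 2) pds_error("insufficient_data", "zc tolerance needs >= 2 samples per channel")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  mean(apply(channels, 2, pop_sd))
}

#' Tolerance-gated zero-crossing rate
#'
#' Counts consecutive sample pairs with a strict sign change whose jump
#' magnitude `|x_k - x_{k+1}|` is at least `tol`, divided by the number of
#' samples `n`. The tolerance gate applies symmetrically to both crossing
#' directions. Samples exactly at 0 carry no sign, so a 0-touching pair is
#' never a strict sign change.
#'
#' @param x numeric vector, length >= 2.
#' @param tol non-negative gate in raw signal units.
#' @return Crossing rate in \[0, 1) (crossings per sample).
#' @export
zero_crossings <- function(x, tol) {
  n <- length(x)
  if (n < 2) pds_error("insufficient_data", "zero crossings need >= 2 samples")
  if (tol < 0) pds_error("parameter_error", "tol must be >= 0")
  a <- x[-n]; b <- x[-1]
  sum(((a > 0 & b < 0) | (a < 0 & b > 0)) & abs(a - b) >= tol) / n
}

#' All sEMG features of a recording's muscle-activity stream
#'
#' Removes the per-channel DC offset (raw armband signals are offset-prone),
#' computes the shared tolerance over this recording's 8 channels, then the
#' per-channel RMS and gated zero-crossing rate.
#'
#' @param emg an [emg_stream()].
#' @return List with `rms` (length 8), `zc` (length 8), `tol` (scalar).
#' @export
emg_features <- function(emg) {
  ch <- sweep(emg$channels, 2, colMeans(emg$channels))
  tol <- zc_tolerance(ch)
  list(rms = apply(ch, 2, emg_rms),
       zc  = apply(ch, 2, zero_crossings, tol = tol),
       tol = tol)
}
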