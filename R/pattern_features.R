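# Pattern-specific descriptors: letter-size regression features (the angle
# between the upper- and lower-peak regression lines, their R^2) and the
# spiral precision index (sd of the radius/tangent angle along the trace).

#' Detect prominent upper and lower peaks of a series
#'
#' Local maxima (upper) and minima (lower) whose topographic prominence is at
#' least `prominence_frac` of the series range, in time order. Plateau
#' extrema are reduced to their first sample.
#'
#' @param y numeric series on a uniform grid.
#' @param prominence_frac prominence threshold as a fraction of
#'   `max(y) - min(y)`; default 0.2.
#' @return List with data frames `upper` and `lower`, each with columns
#'   `index` and `value` (>= 3 rows each, else an insufficient-peaks error).
#' @export
detect_peaks <- function(y, prominence_frac = 0.2) {
  rng <- diff(range(y))
  up <- find_prominent_maxima(y, prominence_frac * rng)
  lo <- find_prominent_maxima(-y, prominence_frac * rng)
  lo$value <- -lo$value
  if (nrow(up) < 3 || nrow(lo) < 3)
    pds_error("insufficient_peaks",
              sprintf("need >= 3 upper and lower peaks, found %d upper / %d lower",
                      nrow(up), nrow(lo)))
  list(upper = up, lower = lo)
}

# local maxima of y with prominence >= min_prom (standard definition: height
# above the higher of the two key saddles toward the nearest higher terrain)
find_prominent_maxima <- function(y, min_prom) {
  n <- length(y)
  empty <- data.frame(index = integer(), value = numeric())
  if (n < 3) return(empty)
  d <- diff(y)
  idx <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L   # rising then non-rising
  if (length(idx) == 0) return(empty)
  prom <- vapply(idx, function(i) {
    left <- y[seq_len(i - 1)]
    right <- y[seq.int(i + 1, n)]
    hl <- which(left > y[i]); hr <- which(right > y[i])
    key_l <- if (length(hl)) min(left[seq.int(max(hl), i - 1)]) else min(left)
    key_r <- if (length(hr)) min(right[seq_len(min(hr))]) else min(right)
    y[i] - max(key_l, key_r)
  }, numeric(1))
  keep <- prom >= min_prom
  data.frame(index = idx[keep], value = y[idx[keep]])
}

#' Ordinary least-squares line with coefficient of determination
#'
#' `R^2 = 1 - SSE/SST` with `SST = sum((y - mean(y))^2)` and
#' `SSE = sum((y - yhat)^2)`; defined as 1 when `SST = 0` (perfectly flat
#' targets are fit perfectly by a constant line).
#'
#' @param t abscissae (not all equal).
#' @param y ordinates; both length >= 3.
#' @return List with `slope`, `intercept`, `r2`.
#' @export
regression_line <- function(t, y) {
  if (length(t) < 3 || length(t) != length(y))
    pds_error("insufficient_data", "regression needs >= 3 (t, y) points")
  if (diff(range(t)) == 0)
    pds_error("degenerate_abscissa", "all abscissae equal; cannot fit a line")
  tm <- mean(t); ym <- mean(y)
  slope <- sum((t - tm) * (y - ym)) / sum((t - tm)^2)
  intercept <- ym - slope * tm
  sst <- sum((y - ym)^2)
  sse <- sum((y - (intercept + slope * t))^2)
  list(slope = slope, intercept = intercept,
       r2 = if (sst == 0) 1 else 1 - sse / sst)
}

#' Letter-size (micrographia) features of a letter-sequence trace
#'
#' Fits a regression line through the upper peaks of the pen-tip y-series
#' and one through the lower peaks (abscissa = sample time of each peak),
#' and returns the unsigned angle `alpha` between the two lines folded into
#' \[0, pi/2\] together with the two coefficients of determination. Healthy
#' constant-height writing gives two parallel horizontal lines (alpha = 0);
#' micrographia tilts the upper line downwards and opens the angle.
#'
#' @param pen a uniform-grid [pen_stream()] of a letters recording.
#' @param prominence_frac passed to [detect_peaks()].
#' @return List with `alpha` (radians), `alpha_deg`, `r2_up`, `r2_low`,
#'   `upper_peaks`, `lower_peaks`.
#' @export
letter_size_features <- function(pen, prominence_frac = 0.2) {
  pk <- detect_peaks(pen$y, prominence_frac)
  fit_up <- regression_line(pen$t[pk$upper$index], pk$upper$value)
  fit_lo <- regression_line(pen$t[pk$lower$index], pk$lower$value)
  alpha <- abs(atan(fit_up$slope) - atan(fit_lo$slope))
  if (alpha > pi / 2) alpha <- pi - alpha      # fold: only line directions matter
  list(alpha = alpha, alpha_deg = alpha * 180 / pi,
       r2_up = fit_up$r2, r2_low = fit_lo$r2,
       upper_peaks = pk$upper, lower_peaks = pk$lower)
}

#' Spiral precision index
#'
#' For each interior pen-down point P of the trace, beta is the unsigned
#' angle between the radius vector from the trajectory centroid C to P and
#' the local direction of travel (central difference). The index is the
#' population standard deviation of the beta series: 0 for a perfect circle
#' (beta = pi/2 everywhere) or an equiangular spiral, larger for tremorous
#' or irregular traces. Invariant to translation, rotation and uniform
#' scaling of the trajectory.
#'
#' @param pen a uniform-grid [pen_stream()] of a spiral recording.
#' @param eps vectors with norm below `eps` mm (stationary pen, centre
#'   point) are skipped.
#' @param center optional `c(x, y)` measurement centre in mm; by default
#'   the arithmetic mean of the pen-down points. An explicit centre is
#'   useful when the geometric pole of a trace is known (the equiangular
#'   constant-angle property holds about the pole, which coincides with the
#'   centroid only for point-symmetric or many-turn balanced traces).
#' @return List with `index` (radians), `beta_series`, `centroid`.
#' @export
spiral_precision <- function(pen, eps = 1e-6, center = NULL) {
  down <- which(pen$pressure > 0)
  if (length(down) < 10) pds_error("insufficient_data", "spiral index needs >= 10 pen-down points")
  x <- pen$x[down]; y <- pen$y[down]
  if (is.null(center)) center <- c(mean(x), mean(y))
  cx <- center[1]; cy <- center[2]
  n <- length(x)
  i <- 2:(n - 1)
  dx <- x[i + 1] - x[i - 1]; dy <- y[i + 1] - y[i - 1]
  rx <- x[i] - cx;           ry <- y[i] - cy
  dn <- sqrt(dx^2 + dy^2);   rn <- sqrt(rx^2 + ry^2)
  ok <- dn > eps & rn > eps
  if (sum(ok) < 10) pds_error("insufficient_data", "too few moving points for spiral index")
  beta <- atan2(abs(rx[ok] * dy[ok] - ry[ok] * dx[ok]),
                rx[ok] * dx[ok] + ry[ok] * dy[ok])
  m <- mean(beta)
  list(index = sqrt(mean((beta - m)^2)), beta_series = beta,
       centroid = c(x = cx, y = cy))
}
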