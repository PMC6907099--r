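# Canonical per-recording feature vectors and the three analysis datasets
# (A: spiral, 41 features; B: 2.5 cm letters and C: 5 cm letters, 43 each).

kin_feature_names <- function() {
  base <- c("vx", "vy", "vcart", "ax", "ay", "acart", "jx", "jy", "jcart",
            "pressure", "azimuth", "altitude")
  as.vector(t(outer(base, c("mean", "sd"), paste, sep = "_")))
}

#' Canonical feature names for a writing pattern
#'
#' The fixed, documented column order of every dataset: `rms_ch1..8`,
#' `zc_ch1..8`, the 24 kinematic / pressure / tilt summaries, then the
#' pattern-specific features (`spiral_precision` for spirals — 41 total;
#' `alpha_deg`, `r2_up`, `r2_low` for letters — 43 total).
#'
#' @param pattern one of `"spiral"`, `"letters_small"`, `"letters_large"`.
#' @return Character vector of length 41 or 43.
#' @export
feature_names <- function(pattern) {
  pattern <- match.arg(pattern, PATTERNS)
  c(paste0("rms_ch", 1:8), paste0("zc_ch", 1:8), kin_feature_names(),
    if (pattern == "spiral") "spiral_precision" else c("alpha_deg", "r2_up", "r2_low"))
}

#' Extract the canonical feature vector of a recording
#'
#' Runs the sEMG (RMS, zero-crossing), kinematic (velocity / acceleration /
#' jerk chains, pressure, tilt) and pattern-specific stages and concatenates
#' them in canonical order. The pen stream is resampled to the recording's
#' uniform grid rate first.
#'
#' @param rec a [recording()].
#' @param lowpass_hz pre-differentiation low-pass cutoff, see
#'   [derivative_chain()].
#' @return Named numeric vector of length 41 (spiral) or 43 (letters).
#' @export
extract_features <- function(rec, lowpass_hz = 12) {
  out <- tryCatch({
    ef <- emg_features(rec$emg)
    pen <- resample_uniform(rec$pen, rec$pen_rate)
    kin <- derivative_chain(pen, lowpass_hz = lowpass_hz)
    tp <- tilt_pressure_features(pen)
    sp <- function(s) unlist(summarize_series(s), use.names = FALSE)
    kin_vals <- c(sp(kin$vx), sp(kin$vy), sp(kin$v_cart),
                  sp(kin$ax), sp(kin$ay), sp(kin$a_cart),
                  sp(kin$jx), sp(kin$jy), sp(kin$j_cart),
                  tp$pressure$mean, tp$pressure$sd,
                  tp$azimuth$mean, tp$azimuth$sd,
                  tp$altitude$mean, tp$altitude$sd)
    pat_vals <- if (rec$pattern == "spiral") {
      spiral_precision(pen)$index
    } else {
      ls <- letter_size_features(pen)
      c(ls$alpha_deg, ls$r2_up, ls$r2_low)
    }
    c(ef$rms, ef$zc, kin_vals, pat_vals)
  }, pdscribe_error = function(e) {
    pds_error("feature_error",
              sprintf("recording %s (%s rep %d): %s",
                      rec$subject_id, rec$pattern, rec$repetition, conditionMessage(e)))
  })
  stats::setNames(as.numeric(out), feature_names(rec$pattern))
}

#' Assemble a labeled dataset from recordings
#'
#' Selects the recordings of one writing pattern (dataset A = spiral,
#' B = 2.5 cm letters, C = 5 cm letters), extracts their feature vectors
#' (one row per repetition) and attaches binary labels: objective 1 labels
#' PD (mild + moderate) vs healthy; objective 2 labels moderate vs mild and
#' excludes healthy subjects. The positive class is PD (objective 1) or
#' moderate (objective 2). Subject ids are retained so train/validation
#' splits can be made subject-wise.
#'
#' @param recs list of [recording()]s.
#' @param dataset `"A"`, `"B"` or `"C"`.
#' @param objective 1 (PD detection) or 2 (PD rating).
#' @return A `labeled_dataset`: data frame with columns `subject_id`,
#'   `label`, then the canonical feature columns; attributes
#'   `feature_names`, `dataset`, `objective`, `positive_class`.
#' @export
build_dataset <- function(recs, dataset = c("A", "B", "C"), objective = 1) {
  dataset <- match.arg(dataset)
  pattern <- c(A = "spiral", B = "letters_small", C = "letters_large")[[dataset]]
  keep <- Filter(function(r) r$pattern == pattern, recs)
  if (objective == 2) keep <- Filter(function(r) r$group != "healthy", keep)
  if (length(keep) == 0)
    pds_error("empty_dataset", sprintf("no recordings for dataset %s, objective %d", dataset, objective))
  lab <- function(g) {
    if (objective == 2) return(g)
    if (g == "healthy") "healthy" else "PD"
  }
  feats <- t(vapply(keep, extract_features, numeric(length(feature_names(pattern)))))
  df <- data.frame(subject_id = vapply(keep, `[[`, "", "subject_id"),
                   label = vapply(keep, function(r) lab(r$group), ""),
                   feats, check.names = FALSE)
  if (anyNA(df)) pds_error("feature_error", "missing values after dataset assembly")
  labeled_dataset(df, dataset = dataset, objective = objective)
}

labeled_dataset <- function(df, dataset, objective) {
  structure(df,
            feature_names = setdiff(names(df), c("subject_id", "label")),
            dataset = dataset, objective = objective,
            positive_class = if (objective == 1) "PD" else "moderate",
            class = c("labeled_dataset", "data.frame"))
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset %s, objective %d> %d rows x %d features; labels: %s\n",
              attr(x, "dataset"), attr(x, "objective"), nrow(x),
              length(attr(x, "feature_names")),
              paste(sprintf("%s=%d", names(table(x$label)), table(x$label)), collapse = ", ")))
  invisible(x)
}

ds_features <- function(ds) as.matrix(ds[, attr(ds, "feature_names"), drop = FALSE])
ds_y <- function(ds) as.integer(ds$label == attr(ds, "positive_class"))  # 1 = positive

#' Export / import a labeled dataset as CSV
#'
#' First columns `subject_id,label`, then the canonical feature columns.
#' The dataset tag and objective ride along in a comment-free side-channel:
#' they are re-derivable from the column set and labels, so `read_dataset`
#' takes them as arguments.
#'
#' @param ds a `labeled_dataset`.
#' @param path CSV file path.
#' @return `path` (write) or the `labeled_dataset` (read).
#' @export
write_dataset <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @param dataset,objective tags for the imported dataset.
#' @export
read_dataset <- function(path, dataset, objective) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df)[1:2], c("subject_id", "label")))
    pds_error("format_error", "dataset CSV must start with subject_id,label")
  labeled_dataset(df, dataset = dataset, objective = objective)
}
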