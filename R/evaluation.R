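# Confusion-matrix metrics and the repeated-evaluation harness, plus the
# originating clinical study's published summary numbers used as a
# pure-arithmetic consistency reference.

#' Accuracy, specificity and sensitivity of a confusion matrix
#'
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`, `specificity = TN/(TN+FP)`,
#' `sensitivity = TP/(TP+FN)`. Works on counts or percentages. A metric
#' whose denominator is zero is returned as `NA` (undefined; excluded from
#' averages by the harness).
#'
#' @param cm numeric vector with named or positional elements
#'   `(tp, fp, fn, tn)`.
#' @return Named numeric vector `accuracy`, `specificity`, `sensitivity`.
#' @export
confusion_metrics <- function(cm) {
  if (!is.null(names(cm)) && all(c("tp", "fp", "fn", "tn") %in% names(cm)))
    cm <- cm[c("tp", "fp", "fn", "tn")]
  cm <- as.numeric(cm)[1:4]
  tp <- cm[1]; fp <- cm[2]; fn <- cm[3]; tn <- cm[4]
  div <- function(a, b) if (b > 0) a / b else NA_real_
  c(accuracy = div(tp + tn, tp + tn + fp + fn),
    specificity = div(tn, tn + fp),
    sensitivity = div(tp, tp + fn))
}

#' Repeated train/evaluate harness
#'
#' Runs `n_reps` independent (initialization, split) draws of
#' [train_ann()], expresses each repetition's validation confusion matrix
#' as percentages of the validation-fold size, and averages. Repetitions
#' whose split is invalid are redrawn internally (bounded). Metric means
#' and standard deviations are taken over repetitions; undefined metrics
#' (zero denominator) are excluded from their averages.
#'
#' @inheritParams train_ann
#' @param n_reps number of repetitions (>= 1).
#' @param base_seed master seed; per-repetition seeds are derived from it.
#' @param ... passed to [train_ann()] (`epochs`, `patience`, `lr`, ...).
#' @return An `eval_summary`: `mean_confusion` (percentages tp/fp/fn/tn
#'   summing to 100), `metrics` (mean and sd of accuracy / specificity /
#'   sensitivity), `n_reps`, `per_rep` (matrix of per-repetition metrics).
#' @export
repeated_eval <- function(ds, topo, n_reps = 250,
                          split_policy = c("subject", "repetition"),
                          base_seed = 1, ...) {
  split_policy <- match.arg(split_policy)
  if (n_reps < 1) pds_error("parameter_error", "n_reps must be >= 1")
  seeds <- withr::with_seed(base_seed, sample.int(.Machine$integer.max - 1L, n_reps))
  cms <- matrix(NA_real_, n_reps, 4, dimnames = list(NULL, c("tp", "fp", "fn", "tn")))
  mets <- matrix(NA_real_, n_reps, 3,
                 dimnames = list(NULL, c("accuracy", "specificity", "sensitivity")))
  for (i in seq_len(n_reps)) {
    fit <- train_ann(ds, topo, split_policy = split_policy, seed = seeds[i], ...)
    cm <- fit$val_confusion
    cms[i, ] <- 100 * cm / sum(cm)
    mets[i, ] <- confusion_metrics(cm)
  }
  msd <- function(v) {
    v <- v[!is.na(v)]
    c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0)
  }
  structure(list(mean_confusion = colMeans(cms),
                 metrics = apply(mets, 2, msd),
                 n_reps = n_reps, per_rep = mets),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("<eval_summary over %d repetitions>\n", x$n_reps))
  cat(sprintf("  mean confusion (%%): TP %.2f  FP %.2f  FN %.2f  TN %.2f\n",
              x$mean_confusion["tp"], x$mean_confusion["fp"],
              x$mean_confusion["fn"], x$mean_confusion["tn"]))
  for (m in colnames(x$metrics))
    cat(sprintf("  %-12s %.4f [%.4f]\n", m, x$metrics["mean", m], x$metrics["sd", m]))
  invisible(x)
}

#' Published reference results of the originating clinical study
#'
#' The clinical study this methodology derives from (11 healthy, 12 mild
#' and 9 moderate PD subjects; private data) reported, for each objective
#' (1: PD vs healthy, 2: moderate vs mild) and each of the six dataset
#' cases, a 250-repetition average percentage confusion matrix, the summary
#' metrics, and the genetically selected topology. These printed numbers
#' are shipped as a plain-text table; they serve as the reference for the
#' pure-arithmetic consistency check that recomputing accuracy /
#' specificity / sensitivity from each confusion matrix reproduces the
#' printed metric means.
#'
#' @return Data frame with columns `objective`, `case`, `tp`, `fp`, `fn`,
#'   `tn` (percent), `accuracy`, `specificity`, `sensitivity` (printed
#'   means), `topology`, `activations`, `moga_accuracy`, `n_features`.
#' @export
reference_results <- function() {
  path <- system.file("extdata", "reference_results.csv", package = "pdscribe",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
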