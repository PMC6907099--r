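# Orchestration of the six-case experiment: datasets A/B/C x {all features,
# selected features} for each classification objective.

CASE_MAP <- data.frame(
  case = 1:6,
  dataset = c("A", "B", "C", "A", "B", "C"),
  selection = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
)

# master seed -> named sub-seeds, documented fan-out: the master seed drives
# one RNG draw per pipeline stage so stages stay independently reproducible.
fan_out_seeds <- function(master) {
  withr::with_seed(master, {
    s <- sample.int(.Machine$integer.max - 1e7, 4)
    list(cohort = s[1], selection = s[2], moga = s[3], eval = s[4])
  })
}

#' Run one case of the six-case classification experiment
#'
#' Maps the case number to its dataset and selection flag (1-3: datasets
#' A/B/C with all features; 4-6: the same datasets reduced by decision-tree
#' feature selection), then runs the Gini-tree selection (when flagged), the
#' multi-objective topology search, and the repeated train/evaluate harness
#' on the best topology. The master seed fans out to per-stage sub-seeds, so
#' the report is bit-for-bit reproducible.
#'
#' @param recs list of [recording()]s covering the case's writing pattern.
#' @param objective 1 (PD vs healthy) or 2 (moderate vs mild).
#' @param case integer 1-6.
#' @param n_reps repetitions of the final evaluation harness (the reference
#'   protocol used 250).
#' @param seed master seed.
#' @param moga_pop,moga_gens population size and generations of the
#'   topology search.
#' @param split_policy train/validation split policy, see [train_ann()].
#' @param ... further arguments to [evolve_topology()].
#' @return A `case_report` list: `objective`, `case`, `dataset`,
#'   `selection`, `n_features`, `selected_features`, `topology` (slash
#'   notation), `moga_accuracy`, `mean_confusion` (percent), `metrics`
#'   (mean and sd), `n_reps`, `seed`.
#' @export
run_experiment <- function(recs, objective, case, n_reps = 250, seed = 1,
                           moga_pop = 30, moga_gens = 20,
                           split_policy = "subject", ...) {
  if (!case %in% 1:6) pds_error("configuration_error", "case must be in 1..6")
  row <- CASE_MAP[CASE_MAP$case == case, ]
  seeds <- fan_out_seeds(seed)
  ds <- build_dataset(recs, row$dataset, objective)
  sel <- NULL
  if (row$selection) {
    sel <- withr::with_seed(seeds$selection, select_features(ds))
    if (length(sel$selected) == 0)
      pds_error("configuration_error", "feature selection kept no features")
    ds <- subset_features(ds, sel$selected)
  }
  moga <- evolve_topology(ds, pop_size = moga_pop, generations = moga_gens,
                          seed = seeds$moga, split_policy = split_policy, ...)
  ev <- repeated_eval(ds, moga$best, n_reps = n_reps,
                      split_policy = split_policy, base_seed = seeds$eval)
  structure(list(objective = objective, case = case,
                 dataset = row$dataset, selection = row$selection,
                 n_features = length(attr(ds, "feature_names")),
                 selected_features = if (is.null(sel)) NULL else sel$selected,
                 importance = if (is.null(sel)) NULL else as.list(sel$importance),
                 topology = format_topology(moga$best),
                 moga_accuracy = moga$best_accuracy,
                 mean_confusion = as.list(ev$mean_confusion),
                 metrics = list(
                   accuracy = as.list(ev$metrics[, "accuracy"]),
                   specificity = as.list(ev$metrics[, "specificity"]),
                   sensitivity = as.list(ev$metrics[, "sensitivity"])),
                 n_reps = n_reps, seed = seed),
            class = c("case_report", "list"))
}

#' Write / render a case report
#'
#' `write_report` serializes a `case_report` to JSON (stable field order,
#' bit-for-bit reproducible under a fixed master seed); `render_report`
#' formats one or more reports as a Markdown table in the shape of the
#' reference study's summary tables.
#'
#' @param report a `case_report` (or, for `render_report`, a list of them).
#' @param path output JSON file.
#' @return `path`, invisibly; `render_report` returns a character vector of
#'   Markdown lines.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = 10,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
render_report <- function(report) {
  reports <- if (inherits(report, "case_report")) list(report) else report
  lines <- c("| Case | Dataset | Features | Topology | Accuracy | Specificity | Sensitivity |",
             "|------|---------|----------|----------|----------|-------------|-------------|")
  for (r in reports) {
    lines <- c(lines, sprintf(
      "| %d | %s%s | %d | %s | %.4f [%.4f] | %.4f [%.4f] | %.4f [%.4f] |",
      r$case, r$dataset, if (r$selection) " (selected)" else "", r$n_features,
      r$topology,
      r$metrics$accuracy$mean, r$metrics$accuracy$sd,
      r$metrics$specificity$mean, r$metrics$specificity$sd,
      r$metrics$sensitivity$mean, r$metrics$sensitivity$sd))
  }
  lines
}
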