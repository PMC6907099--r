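# Decision-tree feature selection: a single CART classification tree with
# Gini impurity; the selected features are those used by the fitted tree,
# ranked by their total (normalized) impurity decrease.

#' Select representative features with a Gini decision tree
#'
#' Fits one CART-style classification tree (Gini diversity index, binary
#' axis-aligned splits) to the dataset and scores every feature by the total
#' impurity decrease of the primary splits it provides (no surrogate or
#' competitor credit), normalized to sum 1. Features with positive
#' importance, in descending order, form the selected set. Ties between
#' equal-gain splits are broken by the tree grower toward the lowest
#' canonical feature index, so row order does not affect the result.
#'
#' @param ds a `labeled_dataset` with >= 10 rows and both classes present.
#' @param max_depth,min_leaf tree growth limits; defaults (5, 3) keep
#'   selected-set sizes in the single digits on cohort-sized datasets.
#' @return A `selection_result`: list with `selected` (character),
#'   `importance` (named numeric, sums to 1 over selected), `tree_depth`.
#' @export
select_features <- function(ds, max_depth = 5, min_leaf = 3) {
  y <- ds$label
  if (length(unique(y)) < 2)
    pds_error("degenerate_labels", "feature selection needs both classes present")
  if (nrow(ds) < 10)
    pds_error("insufficient_data", "feature selection needs >= 10 rows")
  X <- as.data.frame(ds_features(ds))
  names(X) <- make.names(names(X))   # rpart-safe aliases
  alias <- stats::setNames(attr(ds, "feature_names"), names(X))
  fit <- rpart::rpart(factor(y) ~ ., data = X, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        maxdepth = max_depth, minbucket = min_leaf,
                        minsplit = 2 * min_leaf, cp = 0, xval = 0,
                        maxcompete = 0, maxsurrogate = 0, usesurrogate = 0))
  imp <- fit$variable.importance   # primary-split improvements only
  if (is.null(imp) || length(imp) == 0)
    return(structure(list(selected = character(), importance = numeric(),
                          tree_depth = 0L), class = "selection_result"))
  names(imp) <- alias[names(imp)]
  imp <- sort(imp / sum(imp), decreasing = TRUE)
  depth <- max(floor(log2(as.integer(rownames(fit$frame)))))
  structure(list(selected = names(imp), importance = imp,
                 tree_depth = as.integer(depth)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d features (tree depth %d):\n",
              length(x$selected), x$tree_depth))
  for (f in x$selected) cat(sprintf("  %-16s %.3f\n", f, x$importance[[f]]))
  invisible(x)
}

#' Restrict a dataset to a selected feature subset
#'
#' @param ds a `labeled_dataset`.
#' @param features character vector of canonical feature names to keep.
#' @return The reduced `labeled_dataset` (canonical column order preserved).
#' @export
subset_features <- function(ds, features) {
  keep <- intersect(attr(ds, "feature_names"), features)
  if (length(keep) == 0) pds_error("empty_dataset", "no features left after selection")
  labeled_dataset(ds[, c("subject_id", "label", keep), drop = FALSE],
                  dataset = attr(ds, "dataset"), objective = attr(ds, "objective"))
}
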