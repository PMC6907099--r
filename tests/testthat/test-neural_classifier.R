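test_that("activation vocabulary matches its definitions", {
  expect_equal(activation("logsig", 0), 0.5)
  expect_equal(activation("tansig", 0), 0)
  expect_equal(activation("purelin", -2.3), -2.3)
  expect_equal(activation("satlins", 2.7), 1)
  expect_equal(activation("satlins", -0.3), -0.3)
  expect_equal(activation("satlins", -5), -1)
  x <- withr::with_seed(8, rnorm(100, 0, 3))
  expect_equal(activation("tansig", x), 2 * activation("logsig", 2 * x) - 1,
               tolerance = 1e-12)
  expect_error(activation("relu", 1), class = "pdscribe_vocabulary_error")
})

test_that("topology descriptors parse the slash notation and enforce bounds", {
  topo <- parse_topology("45/114/21/2", "satlins/tansig/logsig/softmax")
  expect_equal(topo$hidden, c(45L, 114L, 21L))
  expect_equal(topo$activations, c("satlins", "tansig", "logsig"))
  expect_match(format_topology(topo), "45/114/21/2")

  expect_error(ann_topology(integer(), character()), class = "pdscribe_topology_error")
  expect_error(ann_topology(c(1, 2, 3, 4), rep("logsig", 4)), class = "pdscribe_topology_error")
  expect_error(ann_topology(257, "logsig"), class = "pdscribe_topology_error")
  expect_error(ann_topology(c(10, 256), c("logsig", "logsig")), class = "pdscribe_topology_error")
  expect_error(ann_topology(10, "step"), class = "pdscribe_vocabulary_error")
  expect_error(parse_topology("10/2", "logsig/purelin"), class = "pdscribe_topology_error")
})

test_that("confusion metrics reproduce printed reference values", {
  m <- confusion_metrics(c(tp = 62.11, fp = 1.62, fn = 1.53, tn = 34.75))
  expect_equal(unname(m["sensitivity"]), 0.9760, tolerance = 1e-3)
  expect_equal(unname(m["specificity"]), 0.9555, tolerance = 1e-3)

  m2 <- confusion_metrics(c(tp = 41.31, fp = 2.46, fn = 1.54, tn = 54.69))
  expect_equal(unname(m2["accuracy"]), 0.9600, tolerance = 1e-3)

  expect_equal(unname(confusion_metrics(c(50, 0, 0, 50))), rep(1, 3))
  expect_true(is.na(confusion_metrics(c(0, 0, 0, 10))["sensitivity"]))
})

test_that("label swap exchanges sensitivity and specificity", {
  for (seed in 1:5) {
    cm <- withr::with_seed(seed, as.numeric(rmultinom(1, 200, c(4, 1, 1, 4))))
    names(cm) <- c("tp", "fp", "fn", "tn")
    swapped <- c(tp = cm[["tn"]], fp = cm[["fn"]], fn = cm[["fp"]], tn = cm[["tp"]])
    m <- confusion_metrics(cm); ms <- confusion_metrics(swapped)
    expect_equal(unname(ms["sensitivity"]), unname(m["specificity"]))
    expect_equal(unname(ms["specificity"]), unname(m["sensitivity"]))
    expect_equal(unname(ms["accuracy"]), unname(m["accuracy"]))
  }
})

test_that("training fits a separable problem and is deterministic per seed", {
  ds <- separable_dataset()
  topo <- ann_topology(4, "logsig")
  fit <- train_ann(ds, topo, split_policy = "repetition", seed = 3)
  expect_equal(fit$train_accuracy, 1.0)
  expect_gte(fit$val_accuracy, 0.9)

  fit2 <- train_ann(ds, topo, split_policy = "repetition", seed = 3)
  expect_identical(fit2$val_confusion, fit$val_confusion)
  expect_identical(fit2$net$W, fit$net$W)

  # different seed draws a different initialization/split
  fit3 <- train_ann(ds, topo, split_policy = "repetition", seed = 4)
  expect_false(identical(fit3$train_idx, fit$train_idx) &&
               identical(fit3$net$W, fit$net$W))
})

test_that("subject-wise splits keep a subject's repetitions on one side", {
  ds <- default_dataset("C", 1)
  fit <- train_ann(ds, ann_topology(8, "tansig"), split_policy = "subject", seed = 5)
  tr_subj <- unique(ds$subject_id[fit$train_idx])
  va_subj <- unique(ds$subject_id[-fit$train_idx])
  expect_length(intersect(tr_subj, va_subj), 0)
  one_class <- pdscribe:::labeled_dataset(as.data.frame(ds)[ds$label == "PD", ],
                                          dataset = "C", objective = 1)
  expect_error(train_ann(one_class, ann_topology(4, "logsig")),
               class = "pdscribe_resample_split")
})

test_that("the repeated harness averages percentage confusions coherently", {
  ds <- separable_dataset()
  topo <- ann_topology(4, "logsig")
  ev1 <- repeated_eval(ds, topo, n_reps = 1, split_policy = "repetition", base_seed = 2)
  expect_equal(unname(ev1$metrics["sd", ]), c(0, 0, 0))
  expect_equal(sum(ev1$mean_confusion), 100, tolerance = 1e-6)

  ev <- repeated_eval(ds, topo, n_reps = 5, split_policy = "repetition", base_seed = 2)
  expect_equal(sum(ev$mean_confusion), 100, tolerance = 1e-6)
  expect_true(all(ev$metrics["mean", ] >= 0 & ev$metrics["mean", ] <= 1))
  # determinism of the whole summary under the master seed
  ev_again <- repeated_eval(ds, topo, n_reps = 5, split_policy = "repetition", base_seed = 2)
  expect_identical(ev_again$mean_confusion, ev$mean_confusion)
})
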