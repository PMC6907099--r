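# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# the full default cohort (11 healthy / 12 mild / 9 moderate, 3 reps x 3 tasks)
default_cohort <- function() {
  cached("cohort", function() generate_cohort(cohort_spec(seed = 20260901)))
}

default_dataset <- function(dataset = "C", objective = 1) {
  cached(paste0("ds_", dataset, "_", objective),
         function() build_dataset(default_cohort(), dataset, objective))
}

# clean profile for analytic letter checks: no tremor, no noise
clean_profile <- function(micrographia_rate = 0) {
  severity_profile(micrographia_rate = micrographia_rate, tremor_amp = 0,
                   noise_sd = 0, pressure_sd = 0)
}

# analytic pen stream helper
make_pen <- function(t, x, y, pressure = 0.5, azimuth = 0, altitude = 1) {
  n <- length(t)
  rep_n <- function(v) if (length(v) == 1) rep(v, n) else v
  pen_stream(t, x, y, rep_n(pressure), rep_n(azimuth), rep_n(altitude))
}

# small linearly separable two-feature dataset (wide margin)
separable_dataset <- function(n_per_class = 30, seed = 99, margin = 4) {
  withr::with_seed(seed, {
    x1 <- cbind(rnorm(n_per_class), rnorm(n_per_class))
    x2 <- cbind(rnorm(n_per_class) + margin, rnorm(n_per_class) + margin)
    df <- data.frame(
      subject_id = sprintf("P%03d", seq_len(2 * n_per_class)),
      label = rep(c("healthy", "PD"), each = n_per_class),
      f1 = c(x1[, 1], x2[, 1]), f2 = c(x1[, 2], x2[, 2]),
      check.names = FALSE)
    pdscribe:::labeled_dataset(df, dataset = "A", objective = 1)
  })
}

# balanced pure-noise dataset: no feature carries label information
noise_dataset <- function(n_per_class = 30, n_features = 10, seed = 7) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    feats <- matrix(rnorm(n * n_features), n, n_features,
                    dimnames = list(NULL, paste0("f", seq_len(n_features))))
    df <- data.frame(subject_id = sprintf("N%03d", seq_len(n)),
                     label = rep(c("healthy", "PD"), each = n_per_class),
                     feats, check.names = FALSE)
    pdscribe:::labeled_dataset(df, dataset = "A", objective = 1)
  })
}

# one informative feature planted among pure-noise features
planted_dataset <- function(seed, n = 60, n_noise = 40) {
  withr::with_seed(seed, {
    y <- rep(c(0, 1), each = n / 2)
    feats <- cbind(planted = y + rnorm(n, 0, 0.1),
                   matrix(rnorm(n * n_noise), n, n_noise,
                          dimnames = list(NULL, paste0("noise", seq_len(n_noise)))))
    df <- data.frame(subject_id = sprintf("P%03d", 1:n),
                     label = ifelse(y == 1, "PD", "healthy"),
                     feats, check.names = FALSE)
    pdscribe:::labeled_dataset(df, dataset = "A", objective = 1)
  })
}
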