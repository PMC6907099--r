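# Feed-forward two-class neural classifier: 1-3 hidden layers drawn from the
# activation vocabulary {logsig, tansig, purelin, satlins}, fixed 2-neuron
# softmax output, cross-entropy training with early stopping.

ACTIVATIONS <- c("logsig", "tansig", "purelin", "satlins")

#' Activation functions of the network vocabulary
#'
#' `logsig(x) = 1/(1+exp(-x))`; `tansig(x) = tanh(x)`; `purelin(x) = x`;
#' `satlins(x) = clamp(x, -1, 1)`.
#'
#' @param name one of `"logsig"`, `"tansig"`, `"purelin"`, `"satlins"`.
#' @param x numeric input.
#' @return The activation value, vectorized over `x`.
#' @export
activation <- function(name, x) {
  switch(name,
         logsig = 1 / (1 + exp(-x)),
         tansig = tanh(x),
         purelin = x,
         satlins = pmin(pmax(x, -1), 1),
         pds_error("vocabulary_error", paste("unknown activation:", name)))
}

act_deriv <- function(name, a, z) {
  switch(name,
         logsig = a * (1 - a),
         tansig = 1 - a^2,
         purelin = rep(1, length(z)),
         satlins = as.numeric(z > -1 & z < 1))
}

#' Network topology descriptor
#'
#' Hidden-layer sizes and activations; the output layer is fixed at two
#' neurons with softmax. Valid topologies have 1-3 hidden layers, the first
#' of size 1-256 and later ones of size 1-255.
#'
#' @param sizes integer vector of hidden-layer sizes (length 1-3).
#' @param activations character vector of activation names, same length.
#' @return An object of class `ann_topology`.
#' @export
ann_topology <- function(sizes, activations) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 1 || length(sizes) > 3)
    pds_error("topology_error", "1 to 3 hidden layers required")
  if (length(activations) != length(sizes))
    pds_error("topology_error", "one activation per hidden layer required")
  if (sizes[1] < 1 || sizes[1] > 256 || any(sizes[-1] < 1) || any(sizes[-1] > 255))
    pds_error("topology_error", "layer sizes must be 1-256 (first) / 1-255 (later)")
  if (!all(activations %in% ACTIVATIONS))
    pds_error("vocabulary_error",
              paste("unknown activation:", setdiff(activations, ACTIVATIONS)[1]))
  structure(list(hidden = sizes, activations = activations),
            class = "ann_topology")
}

#' Parse / format a topology in slash notation
#'
#' The reporting notation lists hidden sizes then the fixed 2-neuron output
#' ("45/114/21/2") and the activation chain ending in softmax
#' ("satlins/tansig/logsig/softmax").
#'
#' @param sizes_str e.g. `"45/114/21/2"`.
#' @param act_str e.g. `"satlins/tansig/logsig/softmax"`.
#' @return An `ann_topology` (parse) or a single string (format).
#' @export
parse_topology <- function(sizes_str, act_str) {
  sz <- as.integer(strsplit(sizes_str, "/", fixed = TRUE)[[1]])
  ac <- strsplit(act_str, "/", fixed = TRUE)[[1]]
  if (sz[length(sz)] != 2 || ac[length(ac)] != "softmax")
    pds_error("topology_error", "output layer must be 2/softmax")
  ann_topology(sz[-length(sz)], ac[-length(ac)])
}

#' @rdname parse_topology
#' @param topo an `ann_topology`.
#' @export
format_topology <- function(topo) {
  sprintf("%s/2, %s/softmax",
          paste(topo$hidden, collapse = "/"),
          paste(topo$activations, collapse = "/"))
}

#' @export
print.ann_topology <- function(x, ...) {
  cat("<ann_topology>", format_topology(x), "\n"); invisible(x)
}

# ---- forward / backward ----------------------------------------------------

init_net <- function(topo, n_in) {
  dims <- c(n_in, topo$hidden, 2L)
  W <- vector("list", length(dims) - 1); b <- W
  for (l in seq_along(W)) {
    W[[l]] <- matrix(stats::rnorm(dims[l + 1] * dims[l], 0, sqrt(2 / (dims[l] + dims[l + 1]))),
                     dims[l + 1], dims[l])
    b[[l]] <- numeric(dims[l + 1])
  }
  list(W = W, b = b, acts = topo$activations)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# X: n x p (already standardized). Returns per-layer pre-activations and
# activations; P: n x 2 softmax probabilities, column 2 = positive class.
forward_net <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L); Z <- vector("list", L)
  H <- X
  for (l in seq_len(L - 1)) {
    Z[[l]] <- H %*% t(net$W[[l]]) + matrix(net$b[[l]], nrow(H), length(net$b[[l]]), byrow = TRUE)
    A[[l]] <- activation(net$acts[l], Z[[l]])
    H <- A[[l]]
  }
  Z[[L]] <- H %*% t(net$W[[L]]) + matrix(net$b[[L]], nrow(H), 2, byrow = TRUE)
  P <- softmax_rows(Z[[L]])
  list(Z = Z, A = A, P = P)
}

# gradient of mean cross-entropy wrt all weights; Y: n x 2 one-hot
backward_net <- function(net, X, Y, fw) {
  L <- length(net$W); n <- nrow(X)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- (fw$P - Y) / n                    # n x 2
  for (l in L:1) {
    H_prev <- if (l == 1) X else fw$A[[l - 1]]
    gW[[l]] <- t(delta) %*% H_prev
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% net$W[[l]]) *
        act_deriv_mat(net$acts[l - 1], fw$A[[l - 1]], fw$Z[[l - 1]])
    }
  }
  list(W = gW, b = gb)
}

act_deriv_mat <- function(name, a, z) {
  d <- act_deriv(name, a, z)
  matrix(d, nrow(a), ncol(a))
}

ce_loss <- function(P, Y) -mean(rowSums(Y * log(pmax(P, 1e-12))))

#' Train the neural classifier on a labeled dataset
#'
#' Draws a train/validation split by `split_policy`, z-scores the inputs
#' with training-fold statistics, initializes the weights from `seed` and
#' minimizes the softmax cross-entropy with full-batch Adam, early-stopping
#' on validation loss (best weights restored). Deterministic given
#' `(ds, topo, split_policy, seed)`.
#'
#' @param ds a `labeled_dataset`.
#' @param topo an [ann_topology()].
#' @param split_policy `"subject"` (default; 70/30 stratified split over
#'   subjects, preventing repetition leakage) or `"repetition"` (stratified
#'   over rows).
#' @param seed integer seed for split and initialization.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param lr Adam learning rate.
#' @param train_frac training fraction of the split.
#' @return List of class `ann_fit`: trained `net`, standardization
#'   (`center`, `scale`), `train_idx`, `val_confusion` (counts: tp, fp, fn,
#'   tn), `val_accuracy`, `train_accuracy`, `epochs_run`.
#' @export
train_ann <- function(ds, topo, split_policy = c("subject", "repetition"),
                      seed = 1, epochs = 500, patience = 20, lr = 0.02,
                      train_frac = 0.7) {
  split_policy <- match.arg(split_policy)
  X_all <- ds_features(ds); y_all <- ds_y(ds)
  train_idx <- draw_split(ds, split_policy, seed, train_frac)
  y_tr <- y_all[train_idx]
  if (length(unique(y_tr)) < 2)
    pds_error("resample_split", "training fold contains a single class")
  ctr <- colMeans(X_all[train_idx, , drop = FALSE])
  scl <- apply(X_all[train_idx, , drop = FALSE], 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  std <- function(M) sweep(sweep(M, 2, ctr), 2, scl, "/")
  X_tr <- std(X_all[train_idx, , drop = FALSE])
  X_va <- std(X_all[-train_idx, , drop = FALSE])
  y_va <- y_all[-train_idx]
  Y_tr <- cbind(1 - y_tr, y_tr); Y_va <- cbind(1 - y_va, y_va)

  net <- withr::with_seed(seed, init_net(topo, ncol(X_tr)))
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(v) v * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(loss = Inf, net = net, epoch = 0L)
  wait <- 0L
  for (ep in seq_len(epochs)) {
    fw <- forward_net(net, X_tr)
    gr <- backward_net(net, X_tr, Y_tr, fw)
    for (l in seq_along(net$W)) {
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gr$W[[l]]
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gr$W[[l]]^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gr$b[[l]]
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gr$b[[l]]^2
      mhW <- mW[[l]] / (1 - b1^ep); vhW <- vW[[l]] / (1 - b2^ep)
      mhb <- mb[[l]] / (1 - b1^ep); vhb <- vb[[l]] / (1 - b2^ep)
      net$W[[l]] <- net$W[[l]] - lr * mhW / (sqrt(vhW) + eps)
      net$b[[l]] <- net$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
    }
    val_loss <- ce_loss(forward_net(net, X_va)$P, Y_va)
    if (val_loss < best$loss - 1e-6) {
      best <- list(loss = val_loss, net = net, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  net <- best$net
  pred_va <- max.col(forward_net(net, X_va)$P) - 1L   # 1 = positive
  pred_tr <- max.col(forward_net(net, X_tr)$P) - 1L
  cm <- c(tp = sum(pred_va == 1 & y_va == 1), fp = sum(pred_va == 1 & y_va == 0),
          fn = sum(pred_va == 0 & y_va == 1), tn = sum(pred_va == 0 & y_va == 0))
  structure(list(net = net, topology = topo, center = ctr, scale = scl,
                 train_idx = train_idx, val_confusion = cm,
                 val_accuracy = mean(pred_va == y_va),
                 train_accuracy = mean(pred_tr == y_tr),
                 epochs_run = best$epoch),
            class = "ann_fit")
}

#' @export
predict.ann_fit <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "labeled_dataset")) ds_features(newdata) else as.matrix(newdata)
  X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  P <- forward_net(object$net, X)$P
  if (type == "prob") P[, 2] else max.col(P) - 1L
}

# stratified split; subject-wise keeps all repetitions of a subject on one
# side. Redraws (bounded) until both folds contain both classes.
draw_split <- function(ds, policy, seed, train_frac) {
  y <- ds_y(ds)
  for (try in 0:19) {
    idx <- withr::with_seed((seed + try * 100003) %% .Machine$integer.max, {
      if (policy == "repetition") {
        unlist(lapply(unique(y), function(cl) {
          rows <- which(y == cl)
          sample(rows, max(1, round(train_frac * length(rows))))
        }))
      } else {
        unlist(lapply(unique(y), function(cl) {
          subj <- unique(ds$subject_id[y == cl])
          tr_subj <- sample(subj, max(1, round(train_frac * length(subj))))
          which(ds$subject_id %in% tr_subj & y == cl)
        }))
      }
    })
    idx <- sort(idx)
    if (length(unique(y[idx])) == 2 && length(unique(y[-idx])) == 2 &&
        length(idx) < length(y))
      return(idx)
  }
  pds_error("resample_split", "could not draw a split with both classes in both folds")
}
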