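# Supervised per-omics feature learning: a two-layer graph convolutional
# network with a linear output head, trained transductively with a masked
# cross-entropy loss. Gradients are derived and applied by hand (base R
# matrix algebra); no autodiff framework is involved, which keeps runs
# bit-reproducible under a fixed seed.
#
# Forward pass:
#   H1 = elu(L H0 W0 + b0)
#   H2 = elu(L H1 W1 + b1)
#   Y  = H2 W2 + b2            (class logits; softmax for probabilities)
# with inverted dropout applied to H1 and H2 during training only.

#' Initialise a graph convolutional network
#'
#' Weights use uniform fan-in scaled initialisation; biases start at zero.
#' Call `set.seed()` beforehand (or use [train_gcn()], which seeds for
#' you) for reproducibility.
#'
#' @param n_features input width d.
#' @param hidden_size hidden width h (default 100).
#' @param n_classes output width.
#' @param dropout_rate dropout probability between layers (default 0.5).
#' @return object of class `gcn_model`.
#' @export
gcn_init <- function(n_features, hidden_size = 100L, n_classes,
                     dropout_rate = 0.5) {
  model <- list(
    params = list(
      W0 = init_weight(n_features, hidden_size), b0 = numeric(hidden_size),
      W1 = init_weight(hidden_size, hidden_size), b1 = numeric(hidden_size),
      W2 = init_weight(hidden_size, n_classes), b2 = numeric(n_classes)
    ),
    hidden_size = as.integer(hidden_size),
    n_features = as.integer(n_features),
    n_classes = as.integer(n_classes),
    dropout_rate = dropout_rate
  )
  class(model) <- "gcn_model"
  model
}

#' Forward pass of the graph convolutional network
#'
#' @param H0 feature matrix (n x d).
#' @param L row-stochastic graph Laplacian (n x n).
#' @param model `gcn_model`.
#' @param training logical; when `TRUE`, dropout masks are drawn from the
#'   current RNG stream and applied between layers.
#' @return list with `H1`, `H2` (post-activation hidden layers) and `Y`
#'   (logits), plus internal caches used by the trainer.
#' @export
gcn_forward <- function(H0, L, model, training = FALSE) {
  p <- model$params
  if (ncol(H0) != nrow(p$W0)) {
    stopf("layer 1 dimension mismatch: H0 has %d columns, W0 expects %d",
          ncol(H0), nrow(p$W0))
  }
  LH0 <- L %*% H0
  Z0 <- add_bias(LH0 %*% p$W0, p$b0)
  H1 <- elu(Z0)
  M1 <- if (training) dropout_mask(nrow(H1), ncol(H1), model$dropout_rate)
        else NULL
  H1d <- if (training) H1 * M1 else H1
  LH1 <- L %*% H1d
  Z1 <- add_bias(LH1 %*% p$W1, p$b1)
  H2 <- elu(Z1)
  M2 <- if (training) dropout_mask(nrow(H2), ncol(H2), model$dropout_rate)
        else NULL
  H2d <- if (training) H2 * M2 else H2
  Y <- add_bias(H2d %*% p$W2, p$b2)
  list(H1 = H1, H2 = H2, Y = Y,
       cache = list(LH0 = LH0, Z0 = Z0, H1d = H1d, LH1 = LH1, Z1 = Z1,
                    H2d = H2d, M1 = M1, M2 = M2))
}

# Manual backward pass. dY is the gradient of the loss w.r.t. the logits.
gcn_backward <- function(H0, L, model, fwd, dY) {
  p <- model$params
  c_ <- fwd$cache
  grads <- list()
  grads$W2 <- t(c_$H2d) %*% dY
  grads$b2 <- colSums(dY)
  dH2d <- dY %*% t(p$W2)
  dH2 <- if (is.null(c_$M2)) dH2d else dH2d * c_$M2
  dZ1 <- dH2 * elu_grad(c_$Z1)
  grads$W1 <- t(c_$LH1) %*% dZ1
  grads$b1 <- colSums(dZ1)
  dH1d <- t(L) %*% dZ1 %*% t(p$W1)
  dH1 <- if (is.null(c_$M1)) dH1d else dH1d * c_$M1
  dZ0 <- dH1 * elu_grad(c_$Z0)
  grads$W0 <- t(c_$LH0) %*% dZ0
  grads$b0 <- colSums(dZ0)
  grads
}

# gradient of mean cross-entropy over `idx` w.r.t. logits (zero elsewhere)
softmax_ce_grad <- function(Y, labels, idx) {
  probs <- softmax_rows(Y)
  dY <- matrix(0, nrow(Y), ncol(Y))
  dY[idx, ] <- probs[idx, , drop = FALSE]
  dY[cbind(idx, labels[idx])] <- dY[cbind(idx, labels[idx])] - 1
  dY / length(idx)
}

#' Train a graph convolutional network
#'
#' Transductive training: the forward pass covers every aligned sample but
#' the cross-entropy loss is masked to `train_indices`. A stratified
#' validation slice carved out of the training rows drives early stopping
#' and supplies the "initial prediction" accuracy used for omics
#' selection; the best-validation-loss parameters are restored at the end.
#'
#' @param H0 feature matrix (n x d).
#' @param L row-stochastic Laplacian.
#' @param labels integer class vector in `1..n_classes` (see
#'   [encode_labels()]).
#' @param train_indices integer indices of rows whose labels may be used.
#' @param config list overriding any of: `hidden` (100), `dropout` (0.5),
#'   `lr` (0.001), `weight_decay` (0.01), `epochs` (300), `patience` (30),
#'   `val_fraction` (0.1), `seed` (1).
#' @return trained `gcn_model` with attributes `loss_trace`,
#'   `val_accuracy` and `config`.
#' @export
train_gcn <- function(H0, L, labels, train_indices, config = list()) {
  cfg <- utils::modifyList(list(
    hidden = 100L, dropout = 0.5, lr = 1e-3, weight_decay = 0.01,
    epochs = 300L, patience = 30L, val_fraction = 0.1, seed = 1L
  ), config)
  n_classes <- max(labels)
  set.seed(cfg$seed)

  # stratified validation slice from the training rows
  val_idx <- integer(0)
  if (cfg$val_fraction > 0) {
    for (cl in unique(labels[train_indices])) {
      cl_idx <- train_indices[labels[train_indices] == cl]
      n_val <- floor(cfg$val_fraction * length(cl_idx))
      if (n_val >= 1L && length(cl_idx) - n_val >= 1L) {
        val_idx <- c(val_idx, cl_idx[sample.int(length(cl_idx), n_val)])
      }
    }
  }
  fit_idx <- setdiff(train_indices, val_idx)

  model <- gcn_init(ncol(H0), cfg$hidden, n_classes, cfg$dropout)
  opt <- adam_init(model$params, lr = cfg$lr,
                   weight_decay = cfg$weight_decay)
  trace <- numeric(0)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  for (epoch in seq_len(cfg$epochs)) {
    fwd <- gcn_forward(H0, L, model, training = TRUE)
    if (!all(is.finite(fwd$Y))) {
      stopf("non-finite logits at epoch %d; inspect input scaling", epoch)
    }
    loss <- masked_cross_entropy(softmax_rows(fwd$Y), labels, fit_idx)
    if (!is.finite(loss)) stopf("non-finite training loss at epoch %d", epoch)
    trace <- c(trace, loss)
    dY <- softmax_ce_grad(fwd$Y, labels, fit_idx)
    grads <- gcn_backward(H0, L, model, fwd, dY)
    upd <- adam_step(opt, model$params, grads)
    opt <- upd$state
    model$params <- upd$params

    if (length(val_idx) > 0L) {
      ev <- gcn_forward(H0, L, model, training = FALSE)
      val_loss <- masked_cross_entropy(softmax_rows(ev$Y), labels, val_idx)
      if (val_loss < best$loss - 1e-8) {
        best <- list(loss = val_loss, params = model$params, epoch = epoch)
      } else if (epoch - best$epoch >= cfg$patience) {
        model$params <- best$params
        break
      }
    }
  }
  if (length(val_idx) > 0L && is.finite(best$loss)) {
    model$params <- best$params
  }

  ev <- gcn_forward(H0, L, model, training = FALSE)
  pred <- max.col(ev$Y, ties.method = "first")
  acc_idx <- if (length(val_idx) > 0L) val_idx else fit_idx
  attr(model, "val_accuracy") <- mean(pred[acc_idx] == labels[acc_idx])
  attr(model, "loss_trace") <- trace
  attr(model, "config") <- cfg
  model
}

#' Extract a latent embedding from a trained network
#'
#' Deterministic forward pass with dropout disabled, returning the
#' activations of the requested layer. Layer 1 is the recommended latent
#' space; `"output"` returns the class-probability (label-space) features
#' for comparison studies.
#'
#' @param H0 feature matrix.
#' @param L Laplacian.
#' @param model trained `gcn_model`.
#' @param layer one of `1`, `2`, `"output"`.
#' @return numeric matrix (n x h, or n x n_classes for `"output"`), with
#'   attributes `layer` and rownames carried over from `H0`.
#' @export
extract_latent <- function(H0, L, model, layer = 1L) {
  fwd <- gcn_forward(H0, L, model, training = FALSE)
  out <- if (identical(layer, "output")) softmax_rows(fwd$Y)
         else if (layer == 1L) fwd$H1
         else if (layer == 2L) fwd$H2
         else stopf("layer must be 1, 2 or \"output\"")
  rownames(out) <- rownames(H0)
  attr(out, "layer") <- layer
  out
}

#' Select omics views from their initial prediction accuracies
#'
#' Default `"margin"` rule keeps every view whose held-out accuracy is
#' within `margin` of the best view. `"top_k"` keeps the `k` best;
#' `"all"` keeps everything.
#'
#' @param accuracy named numeric vector of per-view accuracies.
#' @param rule `"margin"`, `"top_k"` or `"all"`.
#' @param margin accuracy tolerance for `"margin"` (default 0.15).
#' @param k number kept by `"top_k"`.
#' @return character vector of selected view names, in input order.
#' @export
select_omics <- function(accuracy, rule = c("margin", "top_k", "all"),
                         margin = 0.15, k = 2L) {
  rule <- match.arg(rule)
  stopifnot(length(accuracy) >= 1L, !is.null(names(accuracy)))
  sel <- switch(rule,
    all = names(accuracy),
    margin = names(accuracy)[accuracy >= max(accuracy) - margin],
    top_k = names(sort(accuracy, decreasing = TRUE))[
      seq_len(min(k, length(accuracy)))]
  )
  sel <- names(accuracy)[names(accuracy) %in% sel]
  if (length(sel) == 0L) {
    warnf("selection rule excluded every omics; falling back to best view")
    sel <- names(which.max(accuracy))
  }
  sel
}

#' Concatenate latent embeddings column-wise
#'
#' @param latents list of matrices sharing row count and sample order
#'   (checked by rowname equality when available).
#' @return single matrix, column blocks in list order.
#' @export
concatenate_latents <- function(latents) {
  stopifnot(length(latents) >= 1L)
  ids <- rownames(latents[[1L]])
  for (l in latents) {
    if (nrow(l) != nrow(latents[[1L]])) stopf("latent sample counts differ")
    if (!is.null(ids) && !is.null(rownames(l)) &&
        !identical(rownames(l), ids)) {
      stopf("latent sample orders differ; align samples first")
    }
  }
  do.call(cbind, lapply(latents, unclass))
}
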