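# Graph attention classifier over the fused patient network. Two
# single-head attention layers run in parallel and their outputs are
# concatenated before a softmax linear head. Neighborhoods are the
# non-zero entries of the (sparsified) fused network, self included.
#
# Per head, with G = H W:
#   e_ij   = LeakyReLU(a_src . g_i + a_dst . g_j)     for P(i,j) > 0
#   alpha  = softmax_j(e_ij) over the neighborhood of i
#   h_i'   = elu(sum_j alpha_ij g_j)
# The split of the attention vector a into source and destination halves
# is algebraically identical to scoring the concatenation [g_i || g_j].

#' Initialise a graph attention model
#'
#' @param n_features input width (columns of the concatenated latent
#'   matrix).
#' @param width per-head output width (default 100).
#' @param n_heads number of attention heads (default 2, concatenated).
#' @param n_classes output classes.
#' @param dropout_rate dropout on the input features and the concatenated
#'   head output during training (default 0.5).
#' @param leaky_slope negative slope of the LeakyReLU attention
#'   nonlinearity (default 0.2).
#' @return object of class `gat_model`.
#' @export
gat_init <- function(n_features, width = 100L, n_heads = 2L, n_classes,
                     dropout_rate = 0.5, leaky_slope = 0.2) {
  params <- list()
  for (h in seq_len(n_heads)) {
    params[[paste0("W", h)]] <- init_weight(n_features, width)
    lim <- 1 / sqrt(2 * width)
    params[[paste0("a_src", h)]] <- stats::runif(width, -lim, lim)
    params[[paste0("a_dst", h)]] <- stats::runif(width, -lim, lim)
  }
  params$Wcls <- init_weight(width * n_heads, n_classes)
  params$bcls <- numeric(n_classes)
  model <- list(params = params, n_heads = as.integer(n_heads),
                width = as.integer(width), n_classes = as.integer(n_classes),
                n_features = as.integer(n_features),
                dropout_rate = dropout_rate, leaky_slope = leaky_slope)
  class(model) <- "gat_model"
  model
}

#' Attention coefficients over graph neighborhoods
#'
#' Computes the row-stochastic attention matrix for one head: softmax of
#' `LeakyReLU(a^T [W h_i || W h_j])` over `{j : P(i, j) > 0}`, exactly 0
#' elsewhere.
#'
#' @param H node feature matrix (n x d).
#' @param P non-negative graph matrix; `P(i, j) > 0` defines the
#'   neighborhood (the diagonal of a fused network is 0.5, so every node
#'   attends to itself).
#' @param W projection matrix (d x w).
#' @param a attention vector of length `2 w` (first half scores the
#'   source projection, second half the destination).
#' @param leaky_slope LeakyReLU negative slope (default 0.2).
#' @return n x n matrix; each row sums to 1 over the node's neighborhood.
#' @export
attention_coefficients <- function(H, P, W, a, leaky_slope = 0.2) {
  w <- ncol(W)
  stopifnot(length(a) == 2L * w)
  att <- attention_forward(H, P, W, a[seq_len(w)], a[w + seq_len(w)],
                           leaky_slope)
  att$alpha
}

# internal: attention forward with caches for backprop
attention_forward <- function(Hd, P, W, a_src, a_dst, slope) {
  n <- nrow(Hd)
  mask <- P > 0
  if (any(rowSums(mask) == 0L)) {
    stopf(paste("node(s) %s have no neighbors in the graph;",
                "re-run dynamic threshold selection on the fused network"),
          paste(utils::head(which(rowSums(mask) == 0L), 5L), collapse = ", "))
  }
  G <- Hd %*% W
  s <- as.vector(G %*% a_src)
  t_ <- as.vector(G %*% a_dst)
  Epre <- outer(s, rep(1, n)) + outer(rep(1, n), t_)
  E <- leaky_relu(Epre, slope)
  E[!mask] <- -Inf
  E <- E - apply(E, 1L, max)
  ex <- exp(E)
  ex[!mask] <- 0
  alpha <- ex / rowSums(ex)
  list(alpha = alpha, G = G, Epre = Epre, mask = mask)
}

#' Forward pass of the graph attention classifier
#'
#' @param H node features (n x d).
#' @param P fused network defining neighborhoods.
#' @param model `gat_model`.
#' @param training logical; draws dropout masks from the RNG stream when
#'   `TRUE`.
#' @return list with `H_att` (concatenated head outputs, post-ELU),
#'   `H_cls` (row-stochastic class probabilities), `alpha` (list of
#'   per-head attention matrices) and trainer caches.
#' @export
gat_forward <- function(H, P, model, training = FALSE) {
  p <- model$params
  if (ncol(H) != model$n_features) {
    stopf("feature width %d does not match model input width %d",
          ncol(H), model$n_features)
  }
  Min <- if (training) dropout_mask(nrow(H), ncol(H), model$dropout_rate)
         else NULL
  Hd <- if (training) H * Min else H
  heads <- vector("list", model$n_heads)
  for (h in seq_len(model$n_heads)) {
    att <- attention_forward(Hd, P, p[[paste0("W", h)]],
                             p[[paste0("a_src", h)]],
                             p[[paste0("a_dst", h)]], model$leaky_slope)
    O <- att$alpha %*% att$G
    heads[[h]] <- c(att, list(O = O, Hh = elu(O)))
  }
  H_att <- do.call(cbind, lapply(heads, `[[`, "Hh"))
  Matt <- if (training) dropout_mask(nrow(H_att), ncol(H_att),
                                     model$dropout_rate) else NULL
  H_attd <- if (training) H_att * Matt else H_att
  logits <- add_bias(H_attd %*% p$Wcls, p$bcls)
  H_cls <- softmax_rows(logits)
  list(H_att = H_att, H_cls = H_cls, logits = logits,
       alpha = lapply(heads, `[[`, "alpha"),
       cache = list(Hd = Hd, Min = Min, Matt = Matt, H_attd = H_attd,
                    heads = heads))
}

# Manual backward pass; dLogits is the loss gradient w.r.t. the logits.
gat_backward <- function(H, P, model, fwd, dLogits) {
  p <- model$params
  c_ <- fwd$cache
  grads <- list()
  grads$Wcls <- t(c_$H_attd) %*% dLogits
  grads$bcls <- colSums(dLogits)
  dH_attd <- dLogits %*% t(p$Wcls)
  dH_att <- if (is.null(c_$Matt)) dH_attd else dH_attd * c_$Matt
  w <- model$width
  for (h in seq_len(model$n_heads)) {
    hd <- c_$heads[[h]]
    dHh <- dH_att[, (h - 1L) * w + seq_len(w), drop = FALSE]
    dO <- dHh * elu_grad(hd$O)
    dAlpha <- dO %*% t(hd$G)
    dG <- t(hd$alpha) %*% dO
    # softmax backward, row-wise over the neighborhood
    dE <- hd$alpha * (dAlpha - rowSums(hd$alpha * dAlpha))
    dEpre <- dE * leaky_relu_grad(hd$Epre, model$leaky_slope)
    dEpre[!hd$mask] <- 0
    ds <- rowSums(dEpre)
    dt <- colSums(dEpre)
    a_src <- p[[paste0("a_src", h)]]
    a_dst <- p[[paste0("a_dst", h)]]
    dG <- dG + outer(ds, a_src) + outer(dt, a_dst)
    grads[[paste0("a_src", h)]] <- as.vector(t(hd$G) %*% ds)
    grads[[paste0("a_dst", h)]] <- as.vector(t(hd$G) %*% dt)
    grads[[paste0("W", h)]] <- t(c_$Hd) %*% dG
  }
  grads
}

#' Train the graph attention classifier
#'
#' Same training recipe as [train_gcn()]: Adam with L2 weight decay,
#' cross-entropy masked to training rows, early stopping on a stratified
#' validation slice.
#'
#' @inheritParams train_gcn
#' @param H concatenated latent feature matrix.
#' @param P fused (and sparsified) patient network.
#' @param config list overriding any of: `width` (100), `heads` (2),
#'   `dropout` (0.5), `lr` (0.001), `weight_decay` (0.01), `epochs` (300),
#'   `patience` (30), `val_fraction` (0.1), `leaky_slope` (0.2), `seed`
#'   (1).
#' @return trained `gat_model` with attributes `loss_trace`,
#'   `val_accuracy`, `config`.
#' @export
train_gat <- function(H, P, labels, train_indices, config = list()) {
  cfg <- utils::modifyList(list(
    width = 100L, heads = 2L, dropout = 0.5, lr = 1e-3,
    weight_decay = 0.01, epochs = 300L, patience = 30L,
    val_fraction = 0.1, leaky_slope = 0.2, seed = 1L
  ), config)
  n_classes <- max(labels)
  set.seed(cfg$seed)

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

  model <- gat_init(ncol(H), cfg$width, cfg$heads, n_classes,
                    cfg$dropout, cfg$leaky_slope)
  opt <- adam_init(model$params, lr = cfg$lr,
                   weight_decay = cfg$weight_decay)
  trace <- numeric(0)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  for (epoch in seq_len(cfg$epochs)) {
    fwd <- gat_forward(H, P, model, training = TRUE)
    if (!all(is.finite(fwd$logits))) {
      stopf("non-finite logits at epoch %d; inspect input scaling", epoch)
    }
    loss <- masked_cross_entropy(fwd$H_cls, labels, fit_idx)
    if (!is.finite(loss)) stopf("non-finite training loss at epoch %d", epoch)
    trace <- c(trace, loss)
    dLogits <- softmax_ce_grad(fwd$logits, labels, fit_idx)
    grads <- gat_backward(H, P, model, fwd, dLogits)
    upd <- adam_step(opt, model$params, grads)
    opt <- upd$state
    model$params <- upd$params

    if (length(val_idx) > 0L) {
      ev <- gat_forward(H, P, model, training = FALSE)
      val_loss <- masked_cross_entropy(ev$H_cls, labels, val_idx)
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

  ev <- gat_forward(H, P, model, training = FALSE)
  pred <- max.col(ev$H_cls, ties.method = "first")
  acc_idx <- if (length(val_idx) > 0L) val_idx else fit_idx
  attr(model, "val_accuracy") <- mean(pred[acc_idx] == labels[acc_idx])
  attr(model, "loss_trace") <- trace
  attr(model, "config") <- cfg
  model
}

#' Multiclass evaluation metrics
#'
#' Accuracy, per-class precision/recall/F1 with macro (unweighted)
#' averaging, and the confusion matrix (rows = truth, columns =
#' prediction). A class with no predicted or no true instances in the
#' evaluation set contributes 0 to the affected macro mean, with a
#' warning.
#'
#' @param truth integer labels in `1..n_classes`.
#' @param pred integer predictions, same coding.
#' @param n_classes total class count (defaults to the max seen).
#' @param classes optional class names for the confusion matrix dimnames.
#' @return list with `accuracy`, `macro_precision`, `macro_recall`,
#'   `macro_f1`, `per_class` data.frame, `confusion` matrix.
#' @export
classification_metrics <- function(truth, pred,
                                   n_classes = max(c(truth, pred)),
                                   classes = NULL) {
  stopifnot(length(truth) == length(pred), length(truth) > 0L)
  lv <- seq_len(n_classes)
  conf <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  conf <- matrix(as.integer(conf), n_classes, n_classes)
  nm <- classes %||% as.character(lv)
  dimnames(conf) <- list(truth = nm, predicted = nm)
  tp <- diag(conf)
  pred_n <- colSums(conf)
  true_n <- rowSums(conf)
  if (any(pred_n == 0L) || any(true_n == 0L)) {
    warnf("class(es) with no predicted or no true instances score 0 in macro averages")
  }
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(true_n > 0, tp / true_n, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(
    accuracy = mean(truth == pred),
    macro_precision = mean(precision),
    macro_recall = mean(recall),
    macro_f1 = mean(f1),
    per_class = data.frame(class = nm, precision = precision,
                           recall = recall, f1 = f1, support = true_n),
    confusion = conf
  )
}

#' Evaluate class-probability predictions against truth
#'
#' @param probs row-stochastic matrix (n x n_classes).
#' @param truth integer labels in `1..n_classes` for all n samples.
#' @param eval_indices rows to score (e.g. the test partition).
#' @param classes optional class names.
#' @return list with `probabilities`, `hard_labels` (all n samples) and
#'   `metrics` computed on `eval_indices` only.
#' @export
evaluate_predictions <- function(probs, truth, eval_indices,
                                 classes = NULL) {
  stopifnot(length(eval_indices) > 0L)
  hard <- max.col(probs, ties.method = "first")
  metrics <- classification_metrics(truth[eval_indices], hard[eval_indices],
                                    n_classes = ncol(probs),
                                    classes = classes)
  list(probabilities = probs, hard_labels = hard, metrics = metrics)
}
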