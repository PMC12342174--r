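test_that("attention coefficients are a masked row-stochastic softmax", {
  set.seed(61)
  n <- 5; d <- 4; w <- 3
  H <- matrix(rnorm(n * d), n, d)
  W <- matrix(rnorm(d * w), d, w)
  a <- rnorm(2 * w)

  # singleton neighborhood: attention 1 on the only neighbor
  P1 <- diag(n)
  al <- attention_coefficients(H, P1, W, a)
  expect_equal(al, diag(n))

  # zero attention vector: uniform over each neighborhood
  P <- matrix(0, n, n)
  P[1, 1:3] <- 1; P[2, ] <- 1; P[3, 3] <- 1; P[4, 4:5] <- 1; P[5, c(1, 5)] <- 1
  al0 <- attention_coefficients(H, P, W, rep(0, 2 * w))
  expect_equal(al0[1, 1:3], rep(1 / 3, 3))
  expect_equal(al0[2, ], rep(1 / 5, 5))
  expect_equal(al0[4, 4:5], rep(1 / 2, 2))

  # scalar oracle on a 3-node toy, LeakyReLU slope 0.2
  H3 <- matrix(c(1, -1, 0.5, 2, 0, -0.5), 3, 2)
  W3 <- matrix(c(0.3, -0.2, 0.5, 0.1), 2, 2)
  a3 <- c(0.4, -0.3, 0.2, 0.6)
  P3 <- matrix(c(1, 1, 0, 1, 1, 1, 0, 1, 1), 3, 3)
  got <- attention_coefficients(H3, P3, W3, a3, leaky_slope = 0.2)
  want <- oracle_attention(H3, P3, W3, a3, slope = 0.2)
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(rowSums(got), rep(1, 3), tolerance = 1e-12)
  expect_true(all(got[P3 == 0] == 0))

  # isolated node points the user at threshold selection
  Piso <- diag(c(1, 1, 0))
  expect_error(attention_coefficients(H3, Piso, W3, a3), "threshold")
})

test_that("gat_forward matches the scalar pipeline oracle", {
  # degenerate self-only neighborhoods: H_att = elu(W h_i) per head
  set.seed(62)
  n <- 4; d <- 3
  H <- matrix(rnorm(n * d), n, d)
  model <- mogfuse:::gat_init(d, width = 2L, n_heads = 2L, n_classes = 2L,
                              dropout_rate = 0)
  fwd <- gat_forward(H, diag(n), model)
  expect_equal(fwd$H_att[, 1:2], mogfuse:::elu(H %*% model$params$W1))
  expect_equal(fwd$H_att[, 3:4], mogfuse:::elu(H %*% model$params$W2))

  # random graphs vs full scalar oracle
  for (seed in 1:10) {
    set.seed(seed)
    n <- 6; d <- 4
    H <- matrix(rnorm(n * d), n, d)
    P <- random_affinity(n, seed = seed + 300)
    P[P < 0.5] <- 0
    diag(P) <- 0.5
    model <- mogfuse:::gat_init(d, width = 3L, n_heads = 2L, n_classes = 3L,
                                dropout_rate = 0)
    fwd <- gat_forward(H, P, model)
    expect_equal(fwd$H_cls, oracle_gat_forward(H, P, model),
                 tolerance = 1e-6)
    expect_equal(rowSums(fwd$H_cls), rep(1, n), tolerance = 1e-9)
    for (al in fwd$alpha) {
      expect_equal(rowSums(al), rep(1, n), tolerance = 1e-9)
      expect_true(all(al[P == 0] == 0))
    }
  }
})

test_that("gat analytic gradients match numerical differentiation", {
  set.seed(63)
  n <- 6; d <- 4; C <- 3
  H <- matrix(rnorm(n * d), n, d)
  P <- random_affinity(n, seed = 301)
  P[P < 0.4] <- 0
  diag(P) <- 0.5
  y <- sample(1:C, n, TRUE)
  idx <- 1:4
  model <- mogfuse:::gat_init(d, width = 3L, n_heads = 2L, n_classes = C,
                              dropout_rate = 0)
  loss_fn <- function(params) {
    model$params <- params
    fwd <- gat_forward(H, P, model)
    mogfuse:::masked_cross_entropy(fwd$H_cls, y, idx)
  }
  fwd <- gat_forward(H, P, model)
  dL <- mogfuse:::softmax_ce_grad(fwd$logits, y, idx)
  grads <- mogfuse:::gat_backward(H, P, model, fwd, dL)
  for (nm in names(model$params)) {
    expect_equal(grads[[nm]], numeric_grad(loss_fn, model$params, nm),
                 tolerance = 1e-5, info = nm)
  }
})

test_that("gat_forward is permutation-equivariant", {
  set.seed(64)
  n <- 6; d <- 4
  H <- matrix(rnorm(n * d), n, d)
  P <- random_affinity(n, seed = 302)
  P[P < 0.4] <- 0
  diag(P) <- 0.5
  model <- mogfuse:::gat_init(d, width = 3L, n_heads = 2L, n_classes = 2L,
                              dropout_rate = 0)
  perm <- c(4, 1, 6, 2, 5, 3)
  f1 <- gat_forward(H, P, model)
  f2 <- gat_forward(H[perm, ], P[perm, perm], model)
  expect_equal(f2$H_cls, f1$H_cls[perm, ], tolerance = 1e-10)
})

test_that("gat training fits separable graphs and fails shuffled labels", {
  set.seed(65)
  n <- 60
  y <- rep(1:3, each = n / 3)
  H <- matrix(rnorm(n * 8), n, 8) + 2.5 * outer(y, 1:8, function(a, b) {
    sin(a * b)
  })
  P <- build_affinity(H, k_neighbors = 8L)
  sp <- sparsify(P, 0.2)$A_sparse
  cfg <- list(width = 8L, epochs = 300L, seed = 9L, val_fraction = 0)
  model <- train_gat(H, sp, y, seq_len(n), cfg)
  pred <- max.col(gat_forward(H, sp, model)$H_cls, ties.method = "first")
  expect_gte(mean(pred == y), 0.95)

  # determinism
  model2 <- train_gat(H, sp, y, seq_len(n), cfg)
  expect_identical(model$params, model2$params)

  # negative control: shuffled labels give near-chance held-out accuracy
  set.seed(66)
  y_shuf <- sample(y)
  train_idx <- seq_len(45)
  test_idx <- 46:60
  ms <- train_gat(H, sp, y_shuf, train_idx,
                  list(width = 8L, epochs = 150L, seed = 10L))
  preds <- max.col(gat_forward(H, sp, ms)$H_cls, ties.method = "first")
  expect_lte(mean(preds[test_idx] == y_shuf[test_idx]), 1 / 3 + 0.15 + 0.1)
})

test_that("classification metrics match hand counts and the brute-force oracle", {
  # perfect prediction
  m <- classification_metrics(c(1, 2, 3, 1), c(1, 2, 3, 1))
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro_precision, 1)
  expect_equal(m$macro_recall, 1)
  expect_equal(m$macro_f1, 1)
  expect_equal(unname(diag(m$confusion)), c(2L, 1L, 1L))

  # hand-counted contingency: truth (2,2,1,1) vs pred (2,1,1,1) in 1-based
  # coding of classes (0 -> 1, 1 -> 2)
  m2 <- classification_metrics(c(2, 2, 1, 1), c(2, 1, 1, 1))
  expect_equal(m2$accuracy, 0.75)
  expect_equal(m2$per_class$precision[2], 1.0)    # class "1"
  expect_equal(m2$per_class$recall[2], 0.5)
  expect_equal(m2$per_class$precision[1], 2 / 3)  # class "0"
  expect_equal(m2$per_class$recall[1], 1.0)
  expect_equal(m2$macro_precision, 5 / 6)

  # constant predictor on balanced two-class data: macro recall 0.5
  expect_warning(
    m3 <- classification_metrics(c(1, 1, 2, 2), c(1, 1, 1, 1)),
    "macro")
  expect_equal(m3$macro_recall, 0.5)

  # oracle agreement on random label vectors
  for (seed in 1:15) {
    set.seed(seed)
    K <- sample(2:4, 1)
    truth <- sample(1:K, 30, TRUE)
    pred <- sample(1:K, 30, TRUE)
    got <- suppressWarnings(classification_metrics(truth, pred, K))
    want <- oracle_metrics(truth, pred, K)
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$macro_precision, want$macro_precision)
    expect_equal(got$macro_recall, want$macro_recall)
    expect_equal(got$macro_f1, want$macro_f1)
    expect_equal(unname(got$confusion), unname(want$confusion),
                 ignore_attr = TRUE)
    expect_equal(sum(got$confusion), 30L)
  }
})

test_that("evaluate_predictions scores the requested partition only", {
  probs <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.6, 0.4), c(0.3, 0.7))
  truth <- c(1L, 2L, 2L, 2L)
  ev <- suppressWarnings(
    evaluate_predictions(probs, truth, eval_indices = 3:4,
                         classes = c("a", "b")))
  expect_equal(ev$hard_labels, c(1L, 2L, 1L, 2L))
  expect_equal(ev$metrics$accuracy, 0.5)
  expect_equal(dimnames(ev$metrics$confusion)$truth, c("a", "b"))
  expect_error(evaluate_predictions(probs, truth, integer(0)))
})
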