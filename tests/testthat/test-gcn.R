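# helper: tiny separable two-class dataset on a simple graph
make_separable <- function(n = 40, d = 6, shift = 3, seed = 1) {
  set.seed(seed)
  y <- rep(1:2, each = n / 2)
  H0 <- matrix(rnorm(n * d), n, d) + shift * (y - 1.5)
  A <- build_affinity(H0, k_neighbors = 5L)
  L <- dynamic_threshold_select(A, 0.05, 0.05)$L
  list(H0 = H0, L = L, y = y)
}

test_that("gcn_forward propagates identically through an identity graph", {
  set.seed(1)
  H0 <- abs(matrix(rnorm(12), 4, 3))   # non-negative: ELU is identity
  model <- mogfuse:::gcn_init(3, 3, 2, dropout_rate = 0)
  model$params$W0 <- diag(3)
  model$params$b0 <- rep(0, 3)
  fwd <- gcn_forward(H0, diag(4), model)
  expect_equal(fwd$H1, H0)

  # analytic limit: all-identity weights give elu(elu(H0)) at layer 2
  model$params$W1 <- diag(3)
  model$params$b1 <- rep(0, 3)
  H0n <- matrix(rnorm(12), 4, 3)       # mixed signs now
  fwd2 <- gcn_forward(H0n, diag(4), model)
  expect_equal(fwd2$H2, mogfuse:::elu(mogfuse:::elu(H0n)))
})

test_that("gcn_forward equals the per-node message-passing oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 6; d <- 4; h <- 3; C <- 2
    H0 <- matrix(rnorm(n * d), n, d)
    A <- random_affinity(n, seed = seed + 100)
    L <- degree_and_laplacian(A)$L
    model <- mogfuse:::gcn_init(d, h, C, dropout_rate = 0)
    fwd <- gcn_forward(H0, L, model)
    want <- oracle_gcn_forward(H0, L, model$params)
    expect_equal(fwd$H1, want$H1, tolerance = 1e-6)
    expect_equal(fwd$H2, want$H2, tolerance = 1e-6)
    expect_equal(fwd$Y, want$Y, tolerance = 1e-6)
  }
})

test_that("message passing is local: an isolated pair sees only itself", {
  set.seed(3)
  n <- 6
  L <- matrix(0, n, n)
  L[1, 1:2] <- L[2, 2:1] <- 0.5          # nodes 1-2 mix only each other
  for (i in 3:n) L[i, 3:n] <- 1 / (n - 2)
  H0 <- matrix(rnorm(n * 4), n, 4)
  model <- mogfuse:::gcn_init(4, 3, 2, dropout_rate = 0)
  f1 <- gcn_forward(H0, L, model)
  H0b <- H0
  H0b[3:n, ] <- matrix(rnorm((n - 2) * 4), n - 2, 4)  # perturb the rest
  f2 <- gcn_forward(H0b, L, model)
  expect_equal(f1$H1[1:2, ], f2$H1[1:2, ])
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(11)
  n <- 6; d <- 4; h <- 3; C <- 3
  H0 <- matrix(rnorm(n * d), n, d)
  L <- degree_and_laplacian(random_affinity(n, 201))$L
  y <- sample(1:C, n, TRUE)
  idx <- 1:4
  model <- mogfuse:::gcn_init(d, h, C, dropout_rate = 0)
  loss_fn <- function(params) {
    model$params <- params
    fwd <- gcn_forward(H0, L, model)
    mogfuse:::masked_cross_entropy(mogfuse:::softmax_rows(fwd$Y), y, idx)
  }
  fwd <- gcn_forward(H0, L, model)
  dY <- mogfuse:::softmax_ce_grad(fwd$Y, y, idx)
  grads <- mogfuse:::gcn_backward(H0, L, model, fwd, dY)
  for (nm in names(model$params)) {
    expect_equal(grads[[nm]], numeric_grad(loss_fn, model$params, nm),
                 tolerance = 1e-5, info = nm)
  }
})

test_that("training fits separable data, is deterministic, survives degeneracy", {
  dat <- make_separable(seed = 5)
  cfg <- list(hidden = 16L, epochs = 200L, seed = 42L)
  model <- train_gcn(dat$H0, dat$L, dat$y, seq_along(dat$y), cfg)
  fwd <- gcn_forward(dat$H0, dat$L, model)
  pred <- max.col(fwd$Y, ties.method = "first")
  expect_gte(mean(pred == dat$y), 0.95)
  expect_true(all(vapply(model$params, function(p) all(is.finite(p)),
                         logical(1))))

  # determinism: identical seeds give identical parameters
  model2 <- train_gcn(dat$H0, dat$L, dat$y, seq_along(dat$y), cfg)
  expect_identical(model$params, model2$params)

  # zero-variance input: trains without crashing, predicts one class
  H0c <- matrix(1, 20, 3)
  Lc <- diag(20)
  yc <- rep(c(1L, 1L, 1L, 2L), 5)
  mc <- train_gcn(H0c, Lc, yc, 1:20,
                  list(hidden = 4L, epochs = 50L, seed = 1L))
  pc <- max.col(gcn_forward(H0c, Lc, mc)$Y, ties.method = "first")
  expect_equal(length(unique(pc)), 1L)
  expect_equal(pc[1], 1L)   # majority class
})

test_that("extract_latent returns the requested layer, deterministically", {
  dat <- make_separable(seed = 6)
  model <- train_gcn(dat$H0, dat$L, dat$y, seq_along(dat$y),
                     list(hidden = 8L, epochs = 30L, seed = 2L))
  l1 <- extract_latent(dat$H0, dat$L, model, 1L)
  expect_equal(dim(l1), c(40L, 8L))
  l2 <- extract_latent(dat$H0, dat$L, model, 2L)
  expect_equal(dim(l2), c(40L, 8L))
  lo <- extract_latent(dat$H0, dat$L, model, "output")
  expect_equal(dim(lo), c(40L, 2L))
  expect_equal(rowSums(lo), rep(1, 40), tolerance = 1e-9)  # label space
  expect_equal(l1, extract_latent(dat$H0, dat$L, model, 1L))  # pure
  expect_error(extract_latent(dat$H0, dat$L, model, 5), "layer")
})

test_that("select_omics applies margin, top_k and all rules", {
  acc <- c(omics1 = 0.9, omics2 = 0.88, omics3 = 0.5, omics4 = 0.89)
  expect_equal(select_omics(acc, "margin", margin = 0.15),
               c("omics1", "omics2", "omics4"))
  expect_equal(select_omics(rep(c(o1 = 0.7, o2 = 0.7), 1), "margin"),
               c("o1", "o2"))
  expect_equal(select_omics(acc, "all"), names(acc))
  expect_equal(select_omics(acc, "top_k", k = 2), c("omics1", "omics4"))
  expect_warning(got <- select_omics(c(a = 0.2, b = 0.9), "margin",
                                     margin = -1), "best view")
  expect_equal(got, "b")
})

test_that("concatenate_latents stacks column blocks in declared order", {
  n <- 5
  l1 <- matrix(1, n, 3, dimnames = list(paste0("s", 1:n), NULL))
  l2 <- matrix(2, n, 5, dimnames = list(paste0("s", 1:n), NULL))
  got <- concatenate_latents(list(l1, l2))
  expect_equal(dim(got), c(5L, 8L))
  expect_true(all(got[, 1:3] == 1) && all(got[, 4:8] == 2))
  expect_equal(concatenate_latents(list(l1)), l1, ignore_attr = TRUE)
  l3 <- l2[n:1, ]
  expect_error(concatenate_latents(list(l1, l3)), "order")
})

test_that("supervised latents separate classes better than unsupervised PCA", {
  # mean silhouette width of the class labeling, plain Euclidean
  silhouette_mean <- function(X, y) {
    D <- as.matrix(dist(X))
    s <- vapply(seq_along(y), function(i) {
      a <- mean(D[i, y == y[i] & seq_along(y) != i])
      b <- min(vapply(setdiff(unique(y), y[i]),
                      function(cl) mean(D[i, y == cl]), numeric(1)))
      (b - a) / max(a, b)
    }, numeric(1))
    mean(s)
  }
  set.seed(9)
  n <- 60; d <- 30
  y <- rep(1:3, each = n / 3)
  mu <- matrix(rnorm(3 * d), 3, d) * 1.2
  H0 <- mu[y, ] + matrix(rnorm(n * d), n, d)
  A <- build_affinity(H0, k_neighbors = 10L)
  L <- dynamic_threshold_select(A, 0.05, 0.05)$L
  model <- train_gcn(H0, L, y, seq_len(n),
                     list(hidden = 10L, epochs = 200L, seed = 4L))
  lat <- extract_latent(H0, L, model, 1L)
  pca <- prcomp(H0, rank. = 10L)$x
  expect_gt(silhouette_mean(lat, y), silhouette_mean(pca, y))
})
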