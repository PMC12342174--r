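# Independent brute-force oracles. Everything here is written as scalar
# loops over the defining formulas, deliberately avoiding the vectorised
# code paths in R/ so the two routes stay independent.

oracle_sq_dist <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (m in seq_len(ncol(X))) s <- s + (X[i, m] - X[j, m])^2
    D[i, j] <- s
  }
  D
}

oracle_scaling <- function(rho, k) {
  n <- nrow(rho)
  knn <- numeric(n)
  for (i in seq_len(n)) {
    d <- rho[i, setdiff(seq_len(n), i)]
    knn[i] <- mean(sort(d)[seq_len(k)])
  }
  nu <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    nu[i, j] <- (knn[i] + knn[j] + rho[i, j]) / 3
  }
  nu
}

oracle_kernel <- function(rho_sq, nu, mu) {
  n <- nrow(rho_sq)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    A[i, j] <- if (i == j) 1 else exp(-rho_sq[i, j] / (mu * nu[i, j]))
  }
  A
}

# smallest grid fraction whose binarized top-fraction graph leaves no
# isolated node; returns NA if none up to 1
oracle_threshold_scan <- function(A, p0, step) {
  n2 <- length(A)
  k <- 0L
  repeat {
    p <- min(p0 + k * step, 1)
    m <- max(1L, floor(p * n2))
    eps <- sort(as.vector(A), decreasing = TRUE)[m]
    B <- matrix(as.numeric(A >= eps), nrow(A))
    B <- pmax(B, t(B))
    if (min(rowSums(B)) > 0) return(p)
    if (p >= 1) return(NA_real_)
    k <- k + 1L
  }
}

# per-node message passing: H1 = elu(sum_j L[i,j] x_j W + b)
oracle_gcn_layer <- function(H, L, W, b) {
  n <- nrow(H)
  out <- matrix(0, n, ncol(W))
  for (i in seq_len(n)) {
    agg <- numeric(ncol(H))
    for (j in seq_len(n)) agg <- agg + L[i, j] * H[j, ]
    z <- as.vector(agg %*% W) + b
    out[i, ] <- ifelse(z > 0, z, exp(z) - 1)
  }
  out
}

oracle_gcn_forward <- function(H0, L, params) {
  H1 <- oracle_gcn_layer(H0, L, params$W0, params$b0)
  H2 <- oracle_gcn_layer(H1, L, params$W1, params$b1)
  Y <- matrix(0, nrow(H0), ncol(params$W2))
  for (i in seq_len(nrow(H0))) {
    Y[i, ] <- as.vector(H2[i, ] %*% params$W2) + params$b2
  }
  list(H1 = H1, H2 = H2, Y = Y)
}

# scalar attention for one head: alpha_ij = softmax over neighborhood of
# LeakyReLU(a . [W h_i || W h_j])
oracle_attention <- function(H, P, W, a, slope = 0.2) {
  n <- nrow(H)
  w <- ncol(W)
  alpha <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nbr <- which(P[i, ] > 0)
    e <- numeric(length(nbr))
    for (t in seq_along(nbr)) {
      j <- nbr[t]
      cat_ij <- c(as.vector(H[i, ] %*% W), as.vector(H[j, ] %*% W))
      z <- sum(a * cat_ij)
      e[t] <- if (z > 0) z else slope * z
    }
    ex <- exp(e - max(e))
    alpha[i, nbr] <- ex / sum(ex)
  }
  alpha
}

oracle_gat_forward <- function(H, P, model) {
  p <- model$params
  heads <- list()
  for (h in seq_len(model$n_heads)) {
    W <- p[[paste0("W", h)]]
    a <- c(p[[paste0("a_src", h)]], p[[paste0("a_dst", h)]])
    alpha <- oracle_attention(H, P, W, a, model$leaky_slope)
    G <- H %*% W
    O <- matrix(0, nrow(H), ncol(W))
    for (i in seq_len(nrow(H))) {
      for (j in which(alpha[i, ] > 0)) O[i, ] <- O[i, ] + alpha[i, j] * G[j, ]
    }
    heads[[h]] <- ifelse(O > 0, O, exp(O) - 1)
  }
  Hatt <- do.call(cbind, heads)
  logits <- matrix(0, nrow(H), ncol(p$Wcls))
  for (i in seq_len(nrow(H))) {
    logits[i, ] <- as.vector(Hatt[i, ] %*% p$Wcls) + p$bcls
  }
  t(apply(logits, 1, function(z) { e <- exp(z - max(z)); e / sum(e) }))
}

oracle_metrics <- function(truth, pred, K) {
  conf <- matrix(0L, K, K)
  for (i in seq_along(truth)) {
    conf[truth[i], pred[i]] <- conf[truth[i], pred[i]] + 1L
  }
  prec <- rec <- f1 <- numeric(K)
  for (c in seq_len(K)) {
    tp <- conf[c, c]
    prec[c] <- if (sum(conf[, c]) > 0) tp / sum(conf[, c]) else 0
    rec[c] <- if (sum(conf[c, ]) > 0) tp / sum(conf[c, ]) else 0
    f1[c] <- if (prec[c] + rec[c] > 0) {
      2 * prec[c] * rec[c] / (prec[c] + rec[c])
    } else 0
  }
  list(accuracy = sum(diag(conf)) / length(truth),
       macro_precision = mean(prec), macro_recall = mean(rec),
       macro_f1 = mean(f1), confusion = conf)
}

oracle_normalize_similarity <- function(A) {
  n <- nrow(A)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sum(A[i, -i])
    for (j in seq_len(n)) P[i, j] <- if (i == j) 0.5 else A[i, j] / (2 * s)
  }
  P
}

oracle_local_affinity <- function(A, K) {
  n <- nrow(A)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    nbr <- others[order(A[i, others], decreasing = TRUE)][seq_len(K)]
    for (j in nbr) S[i, j] <- A[i, j] / sum(A[i, nbr])
  }
  S
}

# one literal cross-diffusion sweep (no renormalization)
oracle_snf_step <- function(A_list, K) {
  m <- length(A_list)
  P <- lapply(A_list, oracle_normalize_similarity)
  S <- lapply(A_list, oracle_local_affinity, K = K)
  out <- vector("list", m)
  for (u in seq_len(m)) {
    acc <- 0
    for (k in setdiff(seq_len(m), u)) acc <- acc + P[[k]]
    Pu <- S[[u]] %*% (acc / (m - 1)) %*% t(S[[u]])
    out[[u]] <- (Pu + t(Pu)) / 2
  }
  out
}

# numerical gradient of a scalar function of a flat named parameter list
numeric_grad <- function(loss_fn, params, nm, eps = 1e-6) {
  g <- params[[nm]] * 0
  for (i in seq_along(params[[nm]])) {
    p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
    g[i] <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
  }
  g
}

# small random symmetric affinity-like matrix with unit diagonal
random_affinity <- function(n, seed) {
  set.seed(seed)
  A <- matrix(runif(n * n), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  A
}
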