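# Similarity network fusion: cross-diffusion of per-omics patient
# similarity networks into one fused network.

#' Normalized patient similarity
#'
#' Self-similarity is fixed at 1/2 and each off-diagonal entry carries half
#' of its row's relative affinity mass:
#' `P(i, j) = A(i, j) / (2 sum_{k != i} A(i, k))` for `j != i`. Every row
#' sums to exactly 1, which keeps the cross-diffusion update numerically
#' stable regardless of the affinity scale.
#'
#' @param A non-negative affinity matrix with positive off-diagonal row
#'   sums.
#' @return row-stochastic matrix with diagonal 0.5.
#' @export
normalize_similarity <- function(A) {
  W <- A
  diag(W) <- 0
  rs <- rowSums(W)
  if (any(rs <= 0)) {
    stopf("sample(s) %s have zero affinity to every other sample",
          paste(utils::head(which(rs <= 0), 5L), collapse = ", "))
  }
  P <- W / (2 * rs)
  diag(P) <- 0.5
  P
}

#' Local affinity (k-nearest-neighbor kernel)
#'
#' Row-normalizes affinity over each sample's K most similar neighbors
#' (self excluded) and zeroes everything else. This sparse operator
#' confines the diffusion to locally trusted similarities.
#'
#' @param A affinity matrix.
#' @param k_neighbors neighborhood size K; clamped to n - 1 with a warning
#'   when too large.
#' @return matrix whose rows sum to 1 over the neighborhood, zero
#'   elsewhere (including the diagonal).
#' @export
local_affinity <- function(A, k_neighbors = 20L) {
  n <- nrow(A)
  stopifnot(k_neighbors >= 1L)
  if (k_neighbors >= n) {
    warnf("k_neighbors = %d >= n = %d; clamping to n - 1", k_neighbors, n)
    k_neighbors <- n - 1L
  }
  S <- matrix(0, n, n, dimnames = dimnames(A))
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    nb <- others[order(A[i, others], decreasing = TRUE)[seq_len(k_neighbors)]]
    S[i, nb] <- A[i, nb] / sum(A[i, nb])
  }
  S
}

#' Fuse per-omics affinity networks by cross-diffusion
#'
#' Initializes `P^(u)` by [normalize_similarity()] and `S^(u)` by
#' [local_affinity()], then iterates the simultaneous update
#' `P^(u) <- S^(u) (mean of the other views' P) t(S^(u))`. After each
#' sweep the matrices are symmetrized and (by default) renormalized back
#' to the 0.5-diagonal row-stochastic form, the standard practice that
#' keeps the diffusion mass-conserving; switch `renormalize = FALSE` for
#' the literal one-shot update. The fused network is the average of the
#' view-specific matrices after `iterations` sweeps (or earlier if the
#' largest entry change drops below `tol`).
#'
#' @param A_list list of >= 2 affinity matrices, identical dimnames/order.
#' @param k_neighbors K for the local kernel (default 20).
#' @param iterations diffusion sweeps t (default 20).
#' @param renormalize logical, default `TRUE`.
#' @param tol optional early-stop tolerance on the max absolute change
#'   (default 1e-6; set to 0 to always run all sweeps).
#' @return object of class `fused_network`: list with `P_fused`, `P_list`,
#'   `S_list`, `iterations_run`, `convergence` (max-abs change per sweep).
#' @export
snf_fuse <- function(A_list, k_neighbors = 20L, iterations = 20L,
                     renormalize = TRUE, tol = 1e-6) {
  m <- length(A_list)
  if (m == 1L) {
    warnf("single omics view: fusion degenerates to similarity normalization")
    P <- normalize_similarity(A_list[[1L]])
    out <- list(P_fused = P, P_list = list(P), S_list = NULL,
                iterations_run = 0L, convergence = numeric(0))
    class(out) <- "fused_network"
    return(out)
  }
  dims <- vapply(A_list, nrow, integer(1))
  if (length(unique(dims)) != 1L ||
      any(vapply(A_list, ncol, integer(1)) != dims[1L])) {
    stopf("all affinity matrices must share one n x n shape")
  }
  P_list <- lapply(A_list, normalize_similarity)
  S_list <- lapply(A_list, local_affinity, k_neighbors = k_neighbors)
  conv <- numeric(0)
  iters_run <- 0L
  for (t_ in seq_len(iterations)) {
    P_new <- vector("list", m)
    for (u in seq_len(m)) {
      P_others <- Reduce(`+`, P_list[-u]) / (m - 1)
      P_u <- S_list[[u]] %*% P_others %*% t(S_list[[u]])
      P_u <- (P_u + t(P_u)) / 2
      if (renormalize) P_u <- normalize_similarity(P_u)
      P_new[[u]] <- P_u
    }
    delta <- max(vapply(seq_len(m), function(u) {
      max(abs(P_new[[u]] - P_list[[u]]))
    }, numeric(1)))
    conv <- c(conv, delta)
    P_list <- P_new
    iters_run <- t_
    if (tol > 0 && delta < tol) break
  }
  P_fused <- Reduce(`+`, P_list) / m
  dimnames(P_fused) <- dimnames(A_list[[1L]])
  out <- list(P_fused = P_fused, P_list = P_list, S_list = S_list,
              iterations_run = iters_run, convergence = conv)
  class(out) <- "fused_network"
  out
}
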