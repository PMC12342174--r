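# Patient affinity graphs: scaled exponential similarity kernel,
# top-percentile sparsification with dynamic threshold selection, and the
# row-normalized graph Laplacian used by the graph-convolution layers.

#' Pairwise squared Euclidean distances
#'
#' `rho(i, j) = sum_m (x_im - x_jm)^2`, the sum of squared per-feature
#' differences between two samples.
#'
#' @param m numeric matrix (samples x features), no missing values.
#' @return symmetric n x n matrix with zero diagonal.
#' @export
pairwise_squared_distance <- function(m) {
  if (anyNA(m)) stopf("distance input contains missing values; clean first")
  d <- as.matrix(stats::dist(m, method = "euclidean"))^2
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Neighborhood scaling factor for the similarity kernel
#'
#' `nu(i, j)` averages three terms: the mean distance from i to its k
#' nearest neighbors, the same for j, and the distance between i and j.
#' Scaling by local density keeps the kernel comparable between dense and
#' sparse regions of the cohort.
#'
#' @param rho symmetric distance matrix (squared or plain Euclidean,
#'   depending on the kernel convention in use).
#' @param k_neighbors neighborhood size k (default 20); clamped to n - 1
#'   with a warning when too large.
#' @return symmetric n x n matrix.
#' @export
scaling_factor <- function(rho, k_neighbors = 20L) {
  n <- nrow(rho)
  stopifnot(k_neighbors >= 1L)
  if (k_neighbors >= n) {
    warnf("k_neighbors = %d >= n = %d; clamping to n - 1", k_neighbors, n)
    k_neighbors <- n - 1L
  }
  knn_mean <- vapply(seq_len(n), function(i) {
    d <- sort(rho[i, -i])[seq_len(k_neighbors)]
    mean(d)
  }, numeric(1))
  (outer(knn_mean, knn_mean, "+") + rho) / 3
}

#' Scaled exponential similarity kernel
#'
#' `A(i, j) = exp(-rho_sq(i, j) / (mu * nu(i, j)))` where `rho_sq` is the
#' squared Euclidean distance between the two samples. The diagonal is set
#' to 1 (a sample is maximally similar to itself). Duplicate samples
#' (`nu = 0` off-diagonal) get affinity 1.
#'
#' @param rho_sq squared-distance matrix entering the exponent.
#' @param nu scaling-factor matrix from [scaling_factor()].
#' @param mu kernel bandwidth, default 0.5.
#' @return symmetric affinity matrix with entries in `[0, 1]` and unit
#'   diagonal.
#' @export
affinity_kernel <- function(rho_sq, nu, mu = 0.5) {
  stopifnot(mu > 0)
  A <- exp(-rho_sq / (mu * nu))
  A[nu == 0] <- 1   # coincident samples: zero distance, maximal affinity
  diag(A) <- 1
  A <- (A + t(A)) / 2
  A
}

#' Build the affinity matrix for one omics view
#'
#' Convenience wrapper chaining distance, scaling factor and kernel. Two
#' distance conventions are provided: `"squared"` (default) feeds the
#' squared Euclidean distance to both the scaling factor and the kernel
#' exponent exactly once; `"snf"` builds the scaling factor from plain
#' Euclidean distances and squares the distance only inside the exponent,
#' matching the original similarity-network-fusion recipe. See the methods
#' vignette for why both exist.
#'
#' @param m omics matrix (samples x features).
#' @param k_neighbors neighborhood size (default 20).
#' @param mu kernel bandwidth (default 0.5).
#' @param distance_convention `"squared"` or `"snf"`.
#' @return affinity matrix with sample IDs as dimnames.
#' @export
build_affinity <- function(m, k_neighbors = 20L, mu = 0.5,
                           distance_convention = c("squared", "snf")) {
  distance_convention <- match.arg(distance_convention)
  rho_sq <- pairwise_squared_distance(m)
  rho <- switch(distance_convention, squared = rho_sq, snf = sqrt(rho_sq))
  nu <- scaling_factor(rho, k_neighbors)
  affinity_kernel(rho_sq, nu, mu)
}

#' Keep only the strongest connections of an affinity matrix
#'
#' Ranks all n^2 cells (diagonal and both symmetric copies included) in
#' descending order and keeps the top `floor(p * n^2)`; the threshold
#' `epsilon` is the value of the last kept cell and the comparison is
#' inclusive, so ties at the threshold are all retained. Entries below
#' `epsilon` are zeroed; survivors keep their weights. Symmetry is restored
#' afterwards by keeping a cell if either of its two copies survived.
#'
#' @param A affinity matrix.
#' @param retained_fraction p in (0, 1].
#' @return list with `A_sparse`, `threshold` (epsilon), `n_retained`
#'   (cells `>= epsilon` before symmetrisation; equals `floor(p * n^2)`
#'   when all entries are distinct) and `retained_fraction`.
#' @export
sparsify <- function(A, retained_fraction) {
  p <- retained_fraction
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1) {
    stopf("retained_fraction must be a single value in (0, 1], got %s",
          format(p))
  }
  v <- sort(as.vector(A), decreasing = TRUE)
  m <- max(1L, floor(p * length(v)))
  eps <- v[m]
  keep <- A >= eps
  n_retained <- sum(keep)
  keep <- keep | t(keep)
  A_sparse <- A * keep
  list(A_sparse = A_sparse, threshold = eps, n_retained = n_retained,
       retained_fraction = p)
}

#' Degree matrix and row-normalized Laplacian
#'
#' `D(i, i) = sum_j A_sparse(i, j)`; `L = D^{-1} A_sparse`, so each row of
#' L sums to 1 and the graph-convolution aggregation averages over
#' neighbors weighted by affinity. A zero row degree makes D singular and
#' raises an error of class `mogfuse_singular` — the condition the dynamic
#' threshold search exists to avoid.
#'
#' @param A_sparse non-negative matrix.
#' @return list with `D` (diagonal degree matrix) and `L`.
#' @export
degree_and_laplacian <- function(A_sparse) {
  deg <- rowSums(A_sparse)
  if (any(deg <= 0)) {
    bad <- which(deg <= 0)
    stop(structure(
      class = c("mogfuse_singular", "error", "condition"),
      list(message = sprintf(
        "singular degree matrix: node(s) %s have zero degree; raise the edge-retention fraction",
        paste(utils::head(bad, 5L), collapse = ", ")),
        call = NULL)
    ))
  }
  list(D = diag(deg, nrow = length(deg)), L = A_sparse / deg)
}

#' Dynamic edge-retention threshold selection
#'
#' Scans the grid `p0, p0 + step, p0 + 2 step, ...` and returns the
#' smallest retention fraction whose sparsified graph leaves no node
#' isolated (equivalently: the diagonal degree matrix is full rank, so the
#' row-normalized Laplacian exists). The rank check uses the zero pattern
#' of the sparsified matrix only, so weighted and binarized graphs give
#' identical outcomes.
#'
#' @param A affinity matrix.
#' @param p0 starting fraction (default 0.01).
#' @param step grid increment (default 0.005).
#' @return list with `p_star`, `threshold`, `n_retained`, `A_sparse`, `D`,
#'   `L`.
#' @export
dynamic_threshold_select <- function(A, p0 = 0.01, step = 0.005) {
  stopifnot(p0 > 0, p0 <= 1, step > 0)
  k <- 0L
  repeat {
    p <- min(p0 + k * step, 1)
    sp <- sparsify(A, p)
    deg_ok <- all(rowSums(sp$A_sparse != 0) > 0)
    if (deg_ok) {
      dl <- degree_and_laplacian(sp$A_sparse)
      return(list(p_star = p, threshold = sp$threshold,
                  n_retained = sp$n_retained, A_sparse = sp$A_sparse,
                  D = dl$D, L = dl$L))
    }
    if (p >= 1) {
      stopf("no retention fraction up to 1.0 yields a full-rank degree matrix")
    }
    k <- k + 1L
  }
}

#' Export a sparse affinity matrix as a weighted edge list
#'
#' @param A_sparse matrix with dimnames.
#' @param path optional TSV path; when `NULL` the data.frame is returned
#'   only.
#' @return data.frame (sample_i, sample_j, weight) for the upper triangle
#'   plus diagonal of non-zero entries.
#' @export
edge_list <- function(A_sparse, path = NULL) {
  idx <- which(A_sparse != 0 & upper.tri(A_sparse, diag = TRUE),
               arr.ind = TRUE)
  ids <- rownames(A_sparse) %||% as.character(seq_len(nrow(A_sparse)))
  df <- data.frame(sample_i = ids[idx[, 1L]], sample_j = ids[idx[, 2L]],
                   weight = A_sparse[idx])
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  df
}
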