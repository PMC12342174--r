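# Shared numerical helpers: activations, softmax, Adam, seeding.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exponential linear unit
#'
#' ELU(x) = x for x > 0, alpha * (exp(x) - 1) otherwise. Used as the
#' nonlinearity in both the graph-convolution and graph-attention layers.
#'
#' @param x numeric vector or matrix.
#' @param alpha saturation level for negative inputs (default 1).
#' @return object of the same shape as `x`.
#' @keywords internal
elu <- function(x, alpha = 1) {
  ifelse(x > 0, x, alpha * (exp(x) - 1))
}

# derivative of ELU w.r.t. its input, expressed via the activation value
elu_grad <- function(x, alpha = 1) {
  ifelse(x > 0, 1, alpha * exp(x))
}

leaky_relu <- function(x, slope = 0.2) {
  ifelse(x > 0, x, slope * x)
}

leaky_relu_grad <- function(x, slope = 0.2) {
  ifelse(x > 0, 1, slope)
}

#' Row-wise softmax
#'
#' Numerically stabilised by subtracting the row maximum before
#' exponentiation.
#'
#' @param x numeric matrix of logits.
#' @return row-stochastic matrix of the same shape.
#' @keywords internal
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  ex <- exp(x)
  ex / rowSums(ex)
}

# Cross-entropy of softmax probabilities against integer labels in 1..C,
# averaged over `idx` rows only (transductive masking).
masked_cross_entropy <- function(probs, labels, idx) {
  p <- probs[cbind(idx, labels[idx])]
  -mean(log(pmax(p, 1e-12)))
}

# ---- Adam optimizer -------------------------------------------------------

# `params` is a flat named list of numeric arrays. State keeps first and
# second moment estimates per parameter. Weight decay is applied as an L2
# penalty added to the raw gradient (coupled, as in stock Adam
# implementations), matching the training recipe the pipeline documents.
adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  list(
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
    weight_decay = weight_decay, t = 0L,
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0)
  )
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (state$weight_decay > 0) g <- g + state$weight_decay * params[[nm]]
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - state$lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(state = state, params = params)
}

# ---- Seeding --------------------------------------------------------------

#' Derive a stage-specific seed from a global seed
#'
#' A single pipeline seed fans out to deterministic per-stage seeds so that
#' individual stages can be re-run in isolation with identical randomness.
#' The result always fits in a 32-bit signed integer.
#'
#' @param seed global integer seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h * 7919) %% 2147483647)
}

# uniform fan-in scaled initialisation (seeded by the caller)
init_weight <- function(n_in, n_out) {
  lim <- 1 / sqrt(n_in)
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# dropout mask scaled by inverse keep-probability (inverted dropout)
dropout_mask <- function(dim1, dim2, rate) {
  if (rate <= 0) return(matrix(1, dim1, dim2))
  matrix(stats::rbinom(dim1 * dim2, 1L, 1 - rate), dim1, dim2) / (1 - rate)
}

# add a bias row-vector to every row of a matrix
add_bias <- function(x, b) sweep(x, 2L, b, "+")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
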