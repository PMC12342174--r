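# Seeded synthetic multi-omics generator. Emulates the structure the
# pipeline is built for: several omics views of the same cohort,
# class-dependent mean shifts on a subset of features, per-view Gaussian
# (or log-normal) noise, uniformly injected missing values, and class
# imbalance. With `complementary = TRUE` each view can separate only the
# classes assigned to it, so full subtype recovery requires integration.

#' Configuration for the synthetic multi-omics generator
#'
#' Defaults describe the reference fixture used throughout the test
#' suite: 150 samples, 3 balanced classes, 2 omics views of 200 features
#' each, 20% informative features, class-mean shifts of 5 noise standard
#' deviations, and 2% missing cells.
#'
#' @param n_samples cohort size.
#' @param n_classes number of subtypes (>= 2).
#' @param class_proportions simplex vector of length `n_classes`
#'   (default balanced).
#' @param n_omics number of views.
#' @param features_per_omics integer vector (recycled to `n_omics`).
#' @param informative_fraction fraction of features carrying class signal.
#' @param effect_size class-mean shift in units of `noise_sd`.
#' @param noise_sd within-class standard deviation.
#' @param na_fraction fraction of cells set to `NA` (before cleaning).
#' @param complementary logical; when `TRUE`, view u gives a distinct mean
#'   only to the classes assigned to it round-robin (class `n_classes`
#'   stays at the background mean everywhere), so no single view separates
#'   all subtypes.
#' @param feature_model `"gaussian"` or `"lognormal"` (heavy-tailed
#'   stress case for the distance kernel).
#' @param seed integer seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 150L, n_classes = 3L,
                             class_proportions = NULL, n_omics = 2L,
                             features_per_omics = 200L,
                             informative_fraction = 0.2,
                             effect_size = 5, noise_sd = 1,
                             na_fraction = 0.02, complementary = TRUE,
                             feature_model = c("gaussian", "lognormal"),
                             seed = 1L) {
  feature_model <- match.arg(feature_model)
  class_proportions <- class_proportions %||%
    rep(1 / n_classes, n_classes)
  if (length(class_proportions) != n_classes ||
      any(class_proportions <= 0) ||
      abs(sum(class_proportions) - 1) > 1e-8) {
    stopf("class_proportions must be %d positive values summing to 1",
          n_classes)
  }
  stopifnot(n_samples >= 2L, n_classes >= 2L, n_omics >= 1L,
            informative_fraction > 0, informative_fraction <= 1,
            na_fraction >= 0, na_fraction < 1, noise_sd > 0)
  cfg <- list(
    n_samples = as.integer(n_samples), n_classes = as.integer(n_classes),
    class_proportions = class_proportions, n_omics = as.integer(n_omics),
    features_per_omics = rep_len(as.integer(features_per_omics), n_omics),
    informative_fraction = informative_fraction,
    effect_size = effect_size, noise_sd = noise_sd,
    na_fraction = na_fraction, complementary = complementary,
    feature_model = feature_model, seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic multi-omics dataset
#'
#' Samples class labels from `class_proportions`, then for each view draws
#' informative-feature class means of magnitude
#' `effect_size * noise_sd` (random signs per class group and feature)
#' and adds Gaussian noise. With complementary signal, classes not
#' assigned to a view share the background mean there. `NA`s are injected
#' uniformly at `na_fraction` so the cleaning path is exercised.
#'
#' @param config from [synthetic_config()].
#' @return list with `omics` (named list of matrices with sample/feature
#'   dimnames), `labels` (data.frame sample_id, label), and
#'   `ground_truth` (class assignment per view, informative feature
#'   indices, mean matrices).
#' @export
simulate_multiomics <- function(config = synthetic_config()) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_samples
  K <- cfg$n_classes
  sample_ids <- sprintf("S%03d", seq_len(n))
  y <- sample.int(K, n, replace = TRUE, prob = cfg$class_proportions)
  # guarantee every class appears at least twice
  for (cl in seq_len(K)) {
    while (sum(y == cl) < 2L) y[sample.int(n, 1L)] <- cl
  }
  labels <- data.frame(sample_id = sample_ids,
                       label = sprintf("C%d", y),
                       stringsAsFactors = FALSE)

  # round-robin class-to-view assignment for complementary signal; the
  # last class is background everywhere and is recovered by elimination
  assigned <- vector("list", cfg$n_omics)
  if (cfg$complementary) {
    for (cl in seq_len(K - 1L)) {
      u <- (cl - 1L) %% cfg$n_omics + 1L
      assigned[[u]] <- c(assigned[[u]], cl)
    }
  } else {
    assigned <- rep(list(seq_len(K)), cfg$n_omics)
  }

  omics <- list()
  truth <- list(class_assignment = assigned, informative = list(),
                means = list(), labels_int = y)
  for (u in seq_len(cfg$n_omics)) {
    d <- cfg$features_per_omics[u]
    n_inf <- max(1L, round(cfg$informative_fraction * d))
    inf_idx <- seq_len(n_inf)   # leading block; order carries no meaning
    # group means: background group 0 plus one group per assigned class
    mu <- matrix(0, K, d)
    for (cl in assigned[[u]]) {
      signs <- sample(c(-1, 1), n_inf, replace = TRUE)
      mu[cl, inf_idx] <- cfg$effect_size * cfg$noise_sd * signs
    }
    X <- mu[y, , drop = FALSE] +
      matrix(stats::rnorm(n * d, 0, cfg$noise_sd), n, d)
    if (cfg$feature_model == "lognormal") X <- exp(X / 2)
    if (cfg$na_fraction > 0) {
      nas <- which(stats::runif(n * d) < cfg$na_fraction)
      X[nas] <- NA_real_
    }
    dimnames(X) <- list(sample_ids, sprintf("o%d_f%03d", u, seq_len(d)))
    omics[[sprintf("omics%d", u)]] <- X
    truth$informative[[u]] <- inf_idx
    truth$means[[u]] <- mu
  }
  list(omics = omics, labels = labels, ground_truth = truth)
}

#' Write a synthetic dataset to disk in pipeline input format
#'
#' @param sim result of [simulate_multiomics()].
#' @param dir output directory (created if missing).
#' @return named character vector of written file paths.
#' @export
write_multiomics <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in names(sim$omics)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_omics_matrix(sim$omics[[nm]], p)
    paths[nm] <- p
  }
  lp <- file.path(dir, "labels.tsv")
  utils::write.table(sim$labels, lp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["labels"] <- lp
  paths
}

#' Fixed six-sample two-view worked example
#'
#' A hard-coded toy dataset small enough that every pipeline intermediate
#' (distances, scaling factors, kernel, normalized similarity, local
#' affinity, one fusion sweep, attention rows) can be recomputed by hand.
#' The frozen intermediates live in the test suite as scalar oracles.
#' Two clusters of three samples each; view 2 separates the clusters more
#' weakly than view 1.
#'
#' @return list with `omics` (two 6 x 4 matrices), `labels` (two classes
#'   of three) and `params` (the kernel settings the frozen oracle values
#'   assume: `mu = 0.5`, `k_neighbors = 2`).
#' @export
make_toy_worked_example <- function() {
  ids <- paste0("T", 1:6)
  o1 <- matrix(c(
    0.0, 0.1, 0.0, 0.2,
    0.2, 0.0, 0.1, 0.0,
    0.1, 0.2, 0.0, 0.1,
    3.0, 2.9, 3.1, 3.0,
    3.1, 3.0, 2.9, 3.2,
    2.9, 3.1, 3.0, 2.8
  ), nrow = 6, byrow = TRUE,
  dimnames = list(ids, paste0("a", 1:4)))
  o2 <- matrix(c(
    1.0, 0.9, 1.1, 1.0,
    1.1, 1.0, 0.9, 1.1,
    0.9, 1.1, 1.0, 0.9,
    2.0, 2.1, 1.9, 2.0,
    2.1, 1.9, 2.0, 2.1,
    1.9, 2.0, 2.1, 1.9
  ), nrow = 6, byrow = TRUE,
  dimnames = list(ids, paste0("b", 1:4)))
  list(
    omics = list(omics1 = o1, omics2 = o2),
    labels = data.frame(sample_id = ids,
                        label = rep(c("G1", "G2"), each = 3),
                        stringsAsFactors = FALSE),
    params = list(mu = 0.5, k_neighbors = 2L)
  )
}
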