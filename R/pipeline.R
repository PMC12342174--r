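# End-to-end two-stage pipeline:
#   preprocess -> per-omics affinity + dynamic threshold -> per-omics GCN
#   -> latent extraction -> omics selection -> concatenation -> SNF fusion
#   -> fused-network threshold -> GAT training -> test-set evaluation.
# All randomness fans out from one global seed via stage_seed(), so any
# stage can be re-run in isolation and full runs are bit-reproducible.

#' Pipeline configuration with printed defaults
#'
#' Every tunable of the two-stage pipeline, pre-filled with the reference
#' settings: kernel neighbors K = 20, bandwidth mu = 0.5, edge-retention
#' grid starting at 0.01 in steps of 0.005, hidden width 100, dropout
#' 0.5, Adam with learning rate 0.001 and weight decay 0.01, a 75/25
#' stratified split, 20 fusion sweeps and a two-head attention
#' classifier.
#'
#' @param mu kernel bandwidth.
#' @param k_neighbors kernel / local-affinity neighborhood size.
#' @param p0,step dynamic threshold grid origin and increment.
#' @param distance_convention `"squared"` (default) or `"snf"`; see
#'   [build_affinity()].
#' @param gcn named list merged over the [train_gcn()] defaults.
#' @param gat named list merged over the [train_gat()] defaults.
#' @param latent_layer `1`, `2` or `"output"`.
#' @param selection_rule,selection_margin,selection_k omics selection; see
#'   [select_omics()].
#' @param snf_iterations fusion sweeps.
#' @param train_fraction stratified split fraction.
#' @param max_na_fraction missing-data cap per feature.
#' @param scale_features z-score each feature across the cohort before
#'   graph building and training (default `TRUE`).
#' @param seed global seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mu = 0.5, k_neighbors = 20L, p0 = 0.01,
                            step = 0.005,
                            distance_convention = "squared",
                            gcn = list(), gat = list(),
                            latent_layer = 1L,
                            selection_rule = "margin",
                            selection_margin = 0.15,
                            selection_k = 2L,
                            snf_iterations = 20L,
                            train_fraction = 0.75,
                            max_na_fraction = 0.10,
                            scale_features = TRUE,
                            seed = 1L) {
  cfg <- list(mu = mu, k_neighbors = as.integer(k_neighbors), p0 = p0,
              step = step, distance_convention = distance_convention,
              gcn = gcn, gat = gat, latent_layer = latent_layer,
              selection_rule = selection_rule,
              selection_margin = selection_margin,
              selection_k = as.integer(selection_k),
              snf_iterations = as.integer(snf_iterations),
              train_fraction = train_fraction,
              max_na_fraction = max_na_fraction,
              scale_features = scale_features,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

# z-score columns; zero-variance features pass through centred
scale_columns <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  sd[sd == 0] <- 1
  sweep(sweep(m, 2L, mu, "-"), 2L, sd, "/")
}

# load omics inputs given either matrices or file paths
resolve_omics <- function(omics) {
  if (is.character(omics)) {
    nms <- names(omics) %||% sub("\\.[^.]*$", "", basename(omics))
    omics <- lapply(omics, read_omics_matrix)
    names(omics) <- nms
  }
  if (is.null(names(omics))) {
    names(omics) <- sprintf("omics%d", seq_along(omics))
  }
  omics
}

# Stage 1: preprocessing, per-omics graphs + GCNs, latents, selection,
# SNF fusion. Shared by run_pipeline() and sweep_edge_retention().
pipeline_stage1 <- function(omics, labels, config) {
  cfg <- config
  omics <- resolve_omics(omics)
  if (is.character(labels)) labels <- read_labels(labels)

  omics <- lapply(omics, deduplicate_samples)
  aligned <- align_samples(omics, labels)
  omics <- lapply(aligned$omics, filter_missing_features,
                  max_na_fraction = cfg$max_na_fraction)
  if (cfg$scale_features) omics <- lapply(omics, scale_columns)
  y <- encode_labels(aligned$labels$label)
  classes <- attr(y, "classes")
  n <- length(y)

  split <- stratified_split(aligned$labels$label, cfg$train_fraction,
                            seed = stage_seed(cfg$seed, "split"))

  per_omics <- list()
  latents <- list()
  for (nm in names(omics)) {
    A <- build_affinity(omics[[nm]], cfg$k_neighbors, cfg$mu,
                        cfg$distance_convention)
    thr <- dynamic_threshold_select(A, cfg$p0, cfg$step)
    gcn_cfg <- utils::modifyList(
      list(seed = stage_seed(cfg$seed, paste0("gcn_", nm))), cfg$gcn)
    model <- train_gcn(omics[[nm]], thr$L, y, split$train, gcn_cfg)
    lat <- extract_latent(omics[[nm]], thr$L, model, cfg$latent_layer)
    fwd <- gcn_forward(omics[[nm]], thr$L, model, training = FALSE)
    pred <- max.col(fwd$Y, ties.method = "first")
    per_omics[[nm]] <- list(
      A = A, p_star = thr$p_star, threshold = thr$threshold, L = thr$L,
      model = model,
      val_accuracy = attr(model, "val_accuracy"),
      test_accuracy = mean(pred[split$test] == y[split$test])
    )
    latents[[nm]] <- lat
  }

  val_acc <- vapply(per_omics, `[[`, numeric(1), "val_accuracy")
  selected <- select_omics(val_acc, cfg$selection_rule,
                           margin = cfg$selection_margin,
                           k = cfg$selection_k)
  H <- concatenate_latents(latents[selected])

  fused <- snf_fuse(lapply(per_omics[selected], `[[`, "A"),
                    k_neighbors = cfg$k_neighbors,
                    iterations = cfg$snf_iterations)

  list(omics = omics, labels = aligned$labels, y = y, classes = classes,
       n = n, split = split, per_omics = per_omics, latents = latents,
       selected = selected, H = H, fused = fused, config = cfg)
}

# Stage 2: sparsify the fused network at `p` (or dynamically), train the
# GAT and evaluate on the test partition.
pipeline_stage2 <- function(state, p = NULL) {
  cfg <- state$config
  if (is.null(p)) {
    thr <- dynamic_threshold_select(state$fused$P_fused, cfg$p0, cfg$step)
  } else {
    sp <- sparsify(state$fused$P_fused, p)
    dl <- degree_and_laplacian(sp$A_sparse)  # errors if p is below minimum
    thr <- list(p_star = p, threshold = sp$threshold,
                n_retained = sp$n_retained, A_sparse = sp$A_sparse,
                D = dl$D, L = dl$L)
  }
  gat_cfg <- utils::modifyList(
    list(seed = stage_seed(cfg$seed, "gat")), cfg$gat)
  model <- train_gat(state$H, thr$A_sparse, state$y, state$split$train,
                     gat_cfg)
  fwd <- gat_forward(state$H, thr$A_sparse, model, training = FALSE)
  eval_out <- evaluate_predictions(fwd$H_cls, state$y, state$split$test,
                                   classes = state$classes)
  list(p_star = thr$p_star, threshold = thr$threshold,
       P_sparse = thr$A_sparse, model = model, forward = fwd,
       evaluation = eval_out)
}

#' Run the full two-stage pipeline
#'
#' @param omics named list of omics matrices (samples x features) or a
#'   character vector of file paths.
#' @param labels data.frame(sample_id, label) or a label file path.
#' @param config from [pipeline_config()].
#' @param output_dir optional directory; when given, metrics, predictions,
#'   the fused network, latents and a re-runnable run record are written
#'   there.
#' @param keep_intermediates keep stage-1 state (graphs, models, latents)
#'   in the returned record (default `TRUE`).
#' @return `run_record` list: resolved config, per-omics retention
#'   fractions and accuracies, selected views, fused-network retention,
#'   test metrics, loss traces and predictions.
#' @export
run_pipeline <- function(omics, labels, config = pipeline_config(),
                         output_dir = NULL, keep_intermediates = TRUE) {
  state <- pipeline_stage1(omics, labels, config)
  s2 <- pipeline_stage2(state)
  metrics <- s2$evaluation$metrics

  record <- list(
    config = config,
    n_samples = state$n,
    classes = state$classes,
    split = list(train = state$labels$sample_id[state$split$train],
                 test = state$labels$sample_id[state$split$test],
                 seed = state$split$seed),
    per_omics = lapply(state$per_omics, function(po) {
      list(p_star = po$p_star, threshold = po$threshold,
           val_accuracy = po$val_accuracy,
           test_accuracy = po$test_accuracy)
    }),
    selected_omics = state$selected,
    fused_p_star = s2$p_star,
    metrics = metrics,
    loss_traces = c(
      stats::setNames(lapply(state$per_omics, function(po)
        attr(po$model, "loss_trace")), paste0("gcn_", names(state$per_omics))),
      list(gat = attr(s2$model, "loss_trace"))
    ),
    predictions = data.frame(
      sample_id = state$labels$sample_id,
      truth = state$labels$label,
      predicted = state$classes[s2$evaluation$hard_labels],
      stringsAsFactors = FALSE
    ),
    probabilities = s2$evaluation$probabilities,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  if (keep_intermediates) {
    record$state <- state
    record$stage2 <- s2
  }
  class(record) <- "run_record"
  if (!is.null(output_dir)) write_run_outputs(record, s2, state, output_dir)
  record
}

write_run_outputs <- function(record, s2, state, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  m <- record$metrics
  jsonlite::write_json(
    list(accuracy = m$accuracy, macro_precision = m$macro_precision,
         macro_recall = m$macro_recall, macro_f1 = m$macro_f1,
         fused_p_star = record$fused_p_star,
         per_omics = record$per_omics,
         selected_omics = record$selected_omics),
    file.path(output_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  probs <- record$probabilities
  colnames(probs) <- record$classes
  utils::write.table(
    cbind(record$predictions, round(probs, 6)),
    file.path(output_dir, "predictions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(m$confusion, file.path(output_dir, "confusion.tsv"),
                     sep = "\t", quote = FALSE)
  write_omics_matrix(state$fused$P_fused,
                     file.path(output_dir, "fused_network.tsv"))
  lat_dir <- file.path(output_dir, "latents")
  dir.create(lat_dir, showWarnings = FALSE)
  for (nm in names(state$latents)) {
    write_omics_matrix(state$latents[[nm]],
                       file.path(lat_dir, paste0(nm, ".tsv")))
  }
  rec <- record[c("config", "n_samples", "classes", "split", "per_omics",
                  "selected_omics", "fused_p_star", "timestamp")]
  rec$config <- unclass(rec$config)
  jsonlite::write_json(rec, file.path(output_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}

#' Sweep the fused-network edge-retention fraction
#'
#' Runs stage 1 once, then re-runs only the graph-dependent stages
#' (fused-network sparsification, GAT training, evaluation) for each
#' requested retention fraction. Fractions below the singularity minimum
#' are recorded as failed rows rather than crashing.
#'
#' @inheritParams run_pipeline
#' @param p_values numeric vector of retention fractions; `NULL` uses the
#'   dynamic minimum plus four increments of 0.1.
#' @return data.frame (p, accuracy, macro_f1, status).
#' @export
sweep_edge_retention <- function(omics, labels, config = pipeline_config(),
                                 p_values = NULL) {
  state <- pipeline_stage1(omics, labels, config)
  if (is.null(p_values)) {
    thr <- dynamic_threshold_select(state$fused$P_fused, config$p0,
                                    config$step)
    p_values <- pmin(thr$p_star + 0.1 * (0:4), 1)
  }
  rows <- lapply(p_values, function(p) {
    res <- tryCatch(pipeline_stage2(state, p = p), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(p = p, accuracy = NA_real_, macro_f1 = NA_real_,
                 status = paste("failed:", conditionMessage(res)))
    } else {
      data.frame(p = p, accuracy = res$evaluation$metrics$accuracy,
                 macro_f1 = res$evaluation$metrics$macro_f1,
                 status = "ok")
    }
  })
  do.call(rbind, rows)
}

#' @export
print.run_record <- function(x, ...) {
  cat("Two-stage multi-omics run\n")
  cat(sprintf("  samples: %d, classes: %s\n", x$n_samples,
              paste(x$classes, collapse = ", ")))
  for (nm in names(x$per_omics)) {
    po <- x$per_omics[[nm]]
    cat(sprintf("  %s: p* = %.3f, validation accuracy = %.3f\n",
                nm, po$p_star, po$val_accuracy))
  }
  cat(sprintf("  selected omics: %s\n",
              paste(x$selected_omics, collapse = ", ")))
  cat(sprintf("  fused network p* = %.3f\n", x$fused_p_star))
  m <- x$metrics
  cat(sprintf(
    "  test accuracy %.4f | macro P %.4f | macro R %.4f | macro F1 %.4f\n",
    m$accuracy, m$macro_precision, m$macro_recall, m$macro_f1))
  invisible(x)
}
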