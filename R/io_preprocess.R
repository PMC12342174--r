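# Reading, cleaning and splitting omics matrices.
#
# Canonical in-memory form of one omics layer is a plain numeric matrix with
# sample IDs as rownames and feature names as colnames ("OmicsMatrix").
# Cleaning rules: keep the most recent duplicate sample, drop features with
# more than `max_na_fraction` missing values, set remaining NAs to 0.

#' Read a delimited omics matrix
#'
#' Reads a samples-x-features numeric matrix from CSV/TSV. The first row
#' holds feature names and the first column sample IDs; set
#' `samples_in_columns = TRUE` for the transposed convention used by many
#' cBioPortal exports (features as rows). Unparseable cells become `NA`.
#'
#' @param path file path.
#' @param delimiter field separator; `","` or `"\t"`. Guessed from the file
#'   extension when `NULL`.
#' @param samples_in_columns logical; transpose after reading.
#' @return numeric matrix with sample IDs as rownames, feature names as
#'   colnames. Possibly containing `NA`.
#' @export
read_omics_matrix <- function(path, delimiter = NULL,
                              samples_in_columns = FALSE) {
  if (!file.exists(path)) stopf("omics file not found: %s", path)
  delimiter <- delimiter %||%
    (if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t")
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           row.names = NULL, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stopf("empty or degenerate matrix in %s", path)
  }
  ids <- raw[[1L]]
  feats <- colnames(raw)[-1L]
  dup_feats <- unique(feats[duplicated(feats)])
  if (length(dup_feats) > 0L) {
    stopf("duplicated header names in %s: %s", path,
          paste(dup_feats, collapse = ", "))
  }
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(ids, feats))
  if (samples_in_columns) vals <- t(vals)
  if (nrow(vals) < 1L || ncol(vals) < 1L) stopf("empty matrix in %s", path)
  vals
}

#' Write an omics matrix as TSV
#'
#' @param m numeric matrix with dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column label table
#'
#' @param path CSV/TSV with columns (sample_id, label); a header row is
#'   detected and skipped if its second field is not a repeated label.
#' @param delimiter field separator, guessed from extension when `NULL`.
#' @return data.frame with character columns `sample_id` and `label`.
#' @export
read_labels <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stopf("label file not found: %s", path)
  delimiter <- delimiter %||%
    (if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t")
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) stopf("label file must have two columns: %s", path)
  out <- data.frame(sample_id = df[[1L]], label = df[[2L]],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id)) {
    keep <- !duplicated(out$sample_id, fromLast = TRUE)
    warnf("duplicate sample IDs in labels; keeping last occurrence")
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Collapse duplicate sample rows
#'
#' When a cohort export carries several rows for one sample ID, the most
#' recent record is retained. Recency is taken as file order: by default the
#' last occurrence wins (`order = "last"`); set `order = "first"` for the
#' opposite convention.
#'
#' @param m omics matrix (samples x features).
#' @param order `"last"` (default) or `"first"`.
#' @return matrix with unique rownames; row order follows first appearance
#'   of each retained ID.
#' @export
deduplicate_samples <- function(m, order = c("last", "first")) {
  order <- match.arg(order)
  ids <- rownames(m)
  keep <- if (order == "last") {
    !duplicated(ids, fromLast = TRUE)
  } else {
    !duplicated(ids)
  }
  m[keep, , drop = FALSE]
}

#' Drop high-missingness features and zero-fill the rest
#'
#' Features whose fraction of missing values is strictly greater than
#' `max_na_fraction` are removed; `NA`s surviving the filter are replaced
#' by 0. The operation is idempotent.
#'
#' @param m omics matrix, possibly with `NA`s.
#' @param max_na_fraction tolerated missing fraction per feature
#'   (default 0.10).
#' @return cleaned matrix with no missing values.
#' @export
filter_missing_features <- function(m, max_na_fraction = 0.10) {
  na_frac <- colMeans(is.na(m))
  keep <- na_frac <= max_na_fraction
  if (!any(keep)) stopf("all %d features exceed the %.0f%% missing-data cap",
                        ncol(m), 100 * max_na_fraction)
  out <- m[, keep, drop = FALSE]
  if (anyNA(out)) out[is.na(out)] <- 0
  out
}

#' Align samples across omics views and the label table
#'
#' Restricts every omics matrix and the label table to the samples present
#' in all views and labelled, in one canonical order (label-table order).
#'
#' @param omics named list of omics matrices.
#' @param labels data.frame(sample_id, label).
#' @return list with elements `omics` (list of matrices, identical row
#'   order) and `labels` (aligned data.frame).
#' @export
align_samples <- function(omics, labels) {
  stopifnot(length(omics) >= 1L)
  common <- Reduce(intersect, lapply(omics, rownames))
  common <- labels$sample_id[labels$sample_id %in% common]
  if (length(common) == 0L) stopf("no samples shared by all omics views and the label table")
  list(
    omics = lapply(omics, function(m) m[common, , drop = FALSE]),
    labels = labels[match(common, labels$sample_id), , drop = FALSE]
  )
}

#' Stratified train/test split
#'
#' Per-class proportional allocation by the largest-remainder method: each
#' class contributes `floor(train_fraction * n_c)` training samples plus at
#' most one extra, chosen so the overall training size equals
#' `round(train_fraction * n)`. Every class deviates from the target
#' fraction by less than one sample. Deterministic given `seed`. A
#' singleton class is placed in the training set with a warning.
#'
#' @param labels character/factor vector, or data.frame with a `label`
#'   column.
#' @param train_fraction default 0.75.
#' @param seed integer seed.
#' @return list with integer vectors `train` and `test` (indices into
#'   `labels`), and the `seed`.
#' @export
stratified_split <- function(labels, train_fraction = 0.75, seed = 1L) {
  if (is.data.frame(labels)) labels <- labels$label
  labels <- as.character(labels)
  stopifnot(train_fraction > 0, train_fraction <= 1)
  set.seed(seed)
  cls <- unique(labels)
  n_c <- vapply(cls, function(cl) sum(labels == cl), integer(1))
  n_tr <- floor(train_fraction * n_c)
  rem <- train_fraction * n_c - n_tr
  singles <- n_c == 1L
  if (any(singles)) {
    warnf("class(es) %s have a single sample; placed in the training set",
          paste(sQuote(cls[singles]), collapse = ", "))
    n_tr[singles] <- 1L
    rem[singles] <- 0
  }
  n_tr[n_tr < 1L] <- 1L  # keep every class represented in training
  deficit <- round(train_fraction * length(labels)) - sum(n_tr)
  if (deficit > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(deficit)]
    n_tr[bump] <- pmin(n_tr[bump] + 1L, n_c[bump])
  }
  train <- integer(0)
  for (i in seq_along(cls)) {
    idx <- which(labels == cls[i])
    train <- c(train, idx[sample.int(length(idx), n_tr[i])])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train), seed = seed)
}

#' Encode labels as integer class indices
#'
#' Classes are numbered in first-appearance order; the mapping is attached
#' so it can be persisted alongside predictions.
#'
#' @param labels character vector.
#' @return integer vector in `1..n_classes` with attribute `classes`
#'   (ordered class names).
#' @export
encode_labels <- function(labels) {
  labels <- as.character(labels)
  classes <- unique(labels)
  y <- match(labels, classes)
  attr(y, "classes") <- classes
  y
}

#' Save / load a data split as JSON
#'
#' @param split list from [stratified_split()].
#' @param sample_ids character vector mapping indices to IDs.
#' @param path output path.
#' @return `path` invisibly; `read_split` returns the split with indices
#'   resolved against `sample_ids`.
#' @export
write_split <- function(split, sample_ids, path) {
  jsonlite::write_json(
    list(train = sample_ids[split$train], test = sample_ids[split$test],
         seed = split$seed),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path, sample_ids) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(train = match(x$train, sample_ids),
       test = match(x$test, sample_ids),
       seed = as.integer(x$seed))
}
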