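# Holdout and cross-validated evaluation: accuracy and macro-F1 per
# decision mode, per-class support analysis, and 2-D PCA projection of the
# learned embedding space.
#
# The fixed pipeline order is the leakage-safe one: stratified split ->
# vocabulary from the training side only -> encode -> pairs from the
# training side only -> train the Siamese encoder -> index the training
# records -> suggest for each held-out record -> decide -> aggregate.

#' Train the full field-mapping model on a training corpus
#'
#' Builds the vocabulary and encoded sequences from this corpus only,
#' generates contrastive pairs, trains the Siamese encoder and indexes the
#' corpus in embedding space. Everything downstream of the split lives
#' here, so deleting held-out records can never change the result.
#'
#' @param train_corpus labeled [crf_corpus()] with >= 2 labels.
#' @param model_config optional [siamese_config()]; when `NULL`, defaults
#'   are used with `vocab_size`/`max_len` taken from this corpus (`max_len`
#'   = the longest observed training sequence, capped by `max_len_cap`).
#' @param seed top-level seed; per-stage seeds are derived from it.
#' @param n_same,n_diff pairs per record (defaults 20/20).
#' @param max_len_cap optional hard cap on the sequence length, for memory
#'   control on corpora with pathological field texts.
#' @param k neighbourhood size the index must support.
#' @return A `crf_field_mapper`: encoder (with vocab), index, pairs, config,
#'   and the training-set pair accuracy.
#' @export
train_field_mapper <- function(train_corpus, model_config = NULL, seed = 1L,
                               n_same = 20L, n_diff = 20L, max_len_cap = Inf,
                               k = 5L) {
  train_corpus <- normalize_corpus(train_corpus)
  validate_corpus(train_corpus, require_labels = TRUE, require_multiclass = TRUE)
  texts <- concatenate_fields(train_corpus)
  vocab <- build_vocabulary(texts)
  observed_max <- max(vapply(texts, function(t) length(tokenize(t)), integer(1)))
  max_len <- as.integer(min(observed_max, max_len_cap))
  if (is.null(model_config)) {
    model_config <- siamese_config(vocab_size = vocab$size, max_len = max_len,
                                   seed = as.integer(stage_seed(seed, 2L)))
  }
  enc <- encode_corpus(train_corpus, vocab, model_config$max_len)
  pairs <- generate_pairs(enc, train_corpus$label, n_same = n_same,
                          n_diff = n_diff, seed = as.integer(stage_seed(seed, 3L)))
  encoder <- train_siamese(pairs, model_config)
  encoder$vocab <- vocab
  index <- build_index(encoder, train_corpus, k = k)
  structure(list(encoder = encoder, vocab = vocab, index = index,
                 pairs = pairs, config = model_config, seed = seed,
                 train_corpus = train_corpus,
                 train_pair_accuracy = pair_accuracy(encoder, pairs)),
            class = "crf_field_mapper")
}

#' Macro-averaged F1 score
#'
#' Unweighted mean over the classes present in `true_labels` of the
#' per-class F1 = 2TP / (2TP + FP + FN), so rare SDTM variables weigh as
#' much as abundant ones. A class with zero true and predicted positives
#' contributes 0.
#'
#' @param true_labels,predicted_labels equal-length character vectors.
#' @return real in `[0, 1]`.
#' @export
macro_f1 <- function(true_labels, predicted_labels) {
  if (length(true_labels) == 0L) stop("macro_f1 needs at least one label")
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors differ in length")
  }
  classes <- unique(true_labels)
  f1 <- vapply(classes, function(cl) {
    tp <- sum(true_labels == cl & predicted_labels == cl)
    fp <- sum(true_labels != cl & predicted_labels == cl)
    fn <- sum(true_labels == cl & predicted_labels != cl)
    den <- 2 * tp + fp + fn
    if (den == 0) 0 else 2 * tp / den
  }, numeric(1))
  mean(f1)
}

# Score a test corpus against a trained mapper; shared by the holdout and
# cross-validation drivers. For the "contains" mode the effective predicted
# label is the true label when contained, else the nearest neighbour's
# label (see the vignette for the macro-F1 convention per mode).
score_test_side <- function(mapper, test_corpus, k) {
  test_corpus <- normalize_corpus(test_corpus)
  enc <- encode_corpus(test_corpus, mapper$vocab, mapper$config$max_len)
  emb <- embed_sequences(mapper$encoder, enc)
  cls <- classify_index(mapper$index, emb, k = k)
  truth <- test_corpus$label
  contains_hit <- vapply(seq_along(truth),
                         function(i) truth[i] %in% cls$labels[i, ], logical(1))
  nearest_hit <- cls$nearest == truth
  majority_hit <- cls$majority == truth
  contains_pred <- ifelse(contains_hit, truth, cls$nearest)

  train_support <- c(table(mapper$train_corpus$label))
  per_class <- do.call(rbind, lapply(unique(truth), function(cl) {
    seen <- cl %in% names(train_support)
    sel <- truth == cl
    data.frame(label = cl,
               train_support = if (seen) unname(train_support[cl]) else 0L,
               test_count = sum(sel),
               accuracy = mean(nearest_hit[sel]),
               seen_in_train = seen)
  }))

  list(
    accuracy = c(contains = mean(contains_hit),
                 nearest = mean(nearest_hit),
                 majority = mean(majority_hit)),
    macro_f1 = c(contains = macro_f1(truth, contains_pred),
                 nearest = macro_f1(truth, cls$nearest),
                 majority = macro_f1(truth, cls$majority)),
    per_class = per_class,
    n_test = length(truth)
  )
}

new_eval_report <- function(scores, mapper, seed, test_fraction, k) {
  structure(list(
    accuracy = scores$accuracy,
    macro_f1 = scores$macro_f1,
    per_class = scores$per_class,
    train_pair_accuracy = mapper$train_pair_accuracy,
    n_train = nrow(mapper$train_corpus),
    n_test = scores$n_test,
    seed = seed, test_fraction = test_fraction, k = k,
    config = unclass(mapper$config),
    history = mapper$encoder$history
  ), class = "crf_eval_report")
}

#' Evaluate the full pipeline on a stratified holdout
#'
#' The headline protocol: a 20% stratified holdout, with the vocabulary and
#' all training pairs rebuilt from the training side only. Test labels
#' absent from the training side count as automatic misses in all three
#' modes and are flagged in `per_class`.
#'
#' @param corpus labeled [crf_corpus()] with >= 2 labels.
#' @param model_config optional [siamese_config()] (defaults derived from
#'   the training split when `NULL`).
#' @param test_fraction holdout share (default 0.2).
#' @param seed top-level seed driving split, pairing and training.
#' @param k neighbourhood size (default 5).
#' @param n_same,n_diff pairs per training record.
#' @param max_len_cap optional sequence-length cap.
#' @param keep_model also return the trained mapper and the split.
#' @return A `crf_eval_report`; with `keep_model = TRUE`, a list
#'   `(report, mapper, split)`.
#' @export
evaluate_holdout <- function(corpus, model_config = NULL, test_fraction = 0.2,
                             seed = 1L, k = 5L, n_same = 20L, n_diff = 20L,
                             max_len_cap = Inf, keep_model = FALSE) {
  corpus <- normalize_corpus(corpus)
  split <- stratified_split(corpus, test_fraction = test_fraction, seed = seed)
  mapper <- train_field_mapper(split$train, model_config = model_config,
                               seed = seed, n_same = n_same, n_diff = n_diff,
                               max_len_cap = max_len_cap, k = k)
  scores <- score_test_side(mapper, split$test, k = k)
  report <- new_eval_report(scores, mapper, seed, test_fraction, k)
  if (keep_model) list(report = report, mapper = mapper, split = split) else report
}

#' Stratified k-fold cross-validation of the pipeline
#'
#' Records are assigned to folds stratified by label (labels smaller than
#' `folds` allocated best-effort). The vocabulary, pairs and encoder are
#' rebuilt per fold from that fold's training side only.
#'
#' @param corpus labeled [crf_corpus()].
#' @param folds number of folds (>= 2; default 5).
#' @inheritParams evaluate_holdout
#' @return list of `crf_eval_report`, one per fold.
#' @export
cross_validate <- function(corpus, folds = 5L, model_config = NULL, seed = 1L,
                           k = 5L, n_same = 20L, n_diff = 20L, max_len_cap = Inf) {
  if (folds < 2L) stop("folds must be >= 2")
  corpus <- normalize_corpus(corpus)
  validate_corpus(corpus, require_labels = TRUE, require_multiclass = TRUE)
  n <- nrow(corpus)
  fold_of <- integer(n)
  with_seed(stage_seed(seed, 11L), {
    for (ids in split(seq_len(n), corpus$label)) {
      ids <- ids[sample.int(length(ids))]
      fold_of[ids] <- rep_len(seq_len(folds), length(ids))
    }
  })
  lapply(seq_len(folds), function(f) {
    train <- crf_corpus(corpus[fold_of != f, , drop = FALSE],
                        source = sprintf("fold %d/%d [train]", f, folds))
    test <- crf_corpus(corpus[fold_of == f, , drop = FALSE],
                       source = sprintf("fold %d/%d [test]", f, folds))
    mapper <- train_field_mapper(train, model_config = model_config,
                                 seed = as.integer(stage_seed(seed, 100L + f)),
                                 n_same = n_same, n_diff = n_diff,
                                 max_len_cap = max_len_cap, k = k)
    scores <- score_test_side(mapper, test, k = k)
    rep <- new_eval_report(scores, mapper, seed, NA_real_, k)
    rep$fold <- f
    rep
  })
}

#' Per-class accuracy versus training support
#'
#' Groups the per-class table of a report at a support threshold (default
#' 100 training examples, the level below which the method visibly starves)
#' and reports the unweighted group mean accuracies.
#'
#' @param report a `crf_eval_report`.
#' @param threshold training-support cut (default 100).
#' @return list: `per_class` (label, train_support, accuracy), `below_mean`,
#'   `above_mean`, `threshold`.
#' @export
support_accuracy_table <- function(report, threshold = 100L) {
  pc <- report$per_class
  below <- pc$train_support < threshold
  list(per_class = pc[order(pc$train_support), c("label", "train_support", "accuracy")],
       below_mean = if (any(below)) mean(pc$accuracy[below]) else NA_real_,
       above_mean = if (any(!below)) mean(pc$accuracy[!below]) else NA_real_,
       threshold = threshold)
}

#' Project embeddings to principal-component coordinates
#'
#' Mean-centered PCA scores of the first `dims` components, with each
#' component's sign fixed so its largest-magnitude loading is positive
#' (making the projection deterministic).
#'
#' @param embeddings numeric matrix, one embedding per row (needs at least
#'   `dims + 1` rows).
#' @param dims number of components (default 2, for plotting).
#' @return score matrix with a `"rotation"` attribute.
#' @export
pca_project <- function(embeddings, dims = 2L) {
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) < dims + 1L) {
    stop("PCA needs at least dims + 1 = ", dims + 1L, " vectors")
  }
  p <- stats::prcomp(embeddings, center = TRUE, scale. = FALSE)
  dims <- min(dims, ncol(p$x))
  scores <- p$x[, seq_len(dims), drop = FALSE]
  rot <- p$rotation[, seq_len(dims), drop = FALSE]
  for (j in seq_len(dims)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  attr(scores, "rotation") <- rot
  scores
}

#' Scatter plot of the 2-D PCA projection, coloured by class
#'
#' @param index a `crf_reference_index` (or any embedding matrix plus
#'   `labels`).
#' @param labels class labels (taken from the index when omitted).
#' @param file optional output file (png); when `NULL`, plots to the active
#'   device.
#' @export
plot_embedding <- function(index, labels = NULL, file = NULL) {
  emb <- if (inherits(index, "crf_reference_index")) index$embeddings else as.matrix(index)
  if (is.null(labels) && inherits(index, "crf_reference_index")) labels <- index$labels
  xy <- pca_project(emb, 2L)
  df <- data.frame(PC1 = xy[, 1], PC2 = xy[, 2], label = labels)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = PC1, y = PC2, colour = label)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(title = "Field embeddings (first two principal components)")
    if (!is.null(file)) {
      ggplot2::ggsave(file, p, width = 7, height = 5, dpi = 150)
      return(invisible(file))
    }
    return(p)
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 650)
    on.exit(grDevices::dev.off())
  }
  cls <- factor(df$label)
  graphics::plot(df$PC1, df$PC2, col = as.integer(cls), pch = 19,
                 xlab = "PC1", ylab = "PC2",
                 main = "Field embeddings (first two principal components)")
  invisible(file)
}

#' Serialize an evaluation report
#'
#' Writes the report as JSON and the per-class table as CSV next to it.
#'
#' @param report a `crf_eval_report`.
#' @param path JSON output path (`<path>` minus extension + `-per-class.csv`
#'   for the table).
#' @export
write_eval_report <- function(report, path) {
  out <- unclass(report)
  out$accuracy <- as.list(out$accuracy)      # named vectors -> JSON objects
  out$macro_f1 <- as.list(out$macro_f1)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  csv <- sub("\\.json$", "", path)
  utils::write.csv(report$per_class, paste0(csv, "-per-class.csv"), row.names = FALSE)
  invisible(path)
}

#' @export
print.crf_eval_report <- function(x, ...) {
  cat("<crf_eval_report>", x$n_train, "train /", x$n_test, "test records\n")
  cat(sprintf("  accuracy: contains %.3f | nearest %.3f | majority %.3f\n",
              x$accuracy["contains"], x$accuracy["nearest"], x$accuracy["majority"]))
  cat(sprintf("  macro-F1: contains %.3f | nearest %.3f | majority %.3f\n",
              x$macro_f1["contains"], x$macro_f1["nearest"], x$macro_f1["majority"]))
  cat(sprintf("  training-pair accuracy %.4f\n", x$train_pair_accuracy))
  invisible(x)
}
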