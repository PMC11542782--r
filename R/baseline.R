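# Comparison method: TF-IDF features over the same concatenated metadata
# text, classified with gradient-boosted trees (xgboost) at library
# defaults. The baseline shares concatenate_fields(), tokenize() and
# stratified_split() with the main pipeline, so a head-to-head run on the
# same seed sees byte-identical train/test membership and text — isolating
# the representational difference being measured.

# TF-IDF with a minimum document frequency of 2, natural term counts,
# smoothed idf (log((1+N)/(1+df)) + 1) and L2 row normalization.
build_tfidf_vocab <- function(texts, min_df = 2L) {
  toks <- lapply(texts, tokenize)
  df_tab <- c(table(unlist(lapply(toks, unique), use.names = FALSE)))
  all_terms <- unique(unlist(toks, use.names = FALSE))   # first-seen order
  terms <- all_terms[df_tab[all_terms] >= min_df]
  if (length(terms) == 0L) stop("no term meets the document-frequency floor of ", min_df)
  idf <- log((1 + length(texts)) / (1 + unname(df_tab[terms]))) + 1
  list(terms = terms, idf = idf, min_df = min_df)
}

tfidf_features <- function(texts, vocab) {
  X <- matrix(0, length(texts), length(vocab$terms),
              dimnames = list(NULL, vocab$terms))
  for (i in seq_along(texts)) {
    cnt <- table(tokenize(texts[i]))
    keep <- intersect(names(cnt), vocab$terms)
    if (length(keep)) X[i, keep] <- as.numeric(cnt[keep])
  }
  X <- X * rep(vocab$idf, each = nrow(X))
  nrm <- sqrt(rowSums(X^2))
  nrm[nrm == 0] <- 1
  X / nrm
}

#' Train the TF-IDF + gradient-boosted-tree baseline
#'
#' Features are TF-IDF over the concatenated four-field text with a minimum
#' document frequency of 2; the classifier is multiclass xgboost at default
#' parameters (max_depth 6, eta 0.3, 100 rounds), single-threaded and
#' seeded for reproducibility.
#'
#' @param train_corpus labeled [crf_corpus()] with >= 2 labels and >= 2
#'   records.
#' @param seed integer seed passed to the booster.
#' @param nrounds boosting rounds (default 100).
#' @return A `crf_baseline` model.
#' @export
train_baseline <- function(train_corpus, seed = 1L, nrounds = 100L) {
  train_corpus <- normalize_corpus(train_corpus)
  validate_corpus(train_corpus, require_labels = TRUE, require_multiclass = TRUE)
  if (nrow(train_corpus) < 2L) stop("baseline needs at least 2 training documents")
  texts <- concatenate_fields(train_corpus)
  vocab <- build_tfidf_vocab(texts, min_df = 2L)
  X <- tfidf_features(texts, vocab)
  levels <- sort(unique(train_corpus$label))
  y <- match(train_corpus$label, levels) - 1L
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  booster <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = length(levels),
                  max_depth = 6L, eta = 0.3, nthread = 1L,
                  seed = as.integer(seed)),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
  structure(list(booster = booster, feature_vocabulary = vocab,
                 labels = levels, seed = seed),
            class = "crf_baseline")
}

#' Predict SDTM targets with the baseline
#'
#' Unseen terms contribute no features; a record with entirely unseen
#' vocabulary still receives a label (from its all-zero feature row).
#'
#' @param model a [train_baseline()] result.
#' @param corpus a [crf_corpus()] (labels not required).
#' @return character vector of predicted labels, one per record.
#' @export
predict_baseline <- function(model, corpus) {
  stopifnot(inherits(model, "crf_baseline"))
  corpus <- normalize_corpus(corpus)
  X <- tfidf_features(concatenate_fields(corpus), model$feature_vocabulary)
  prob <- predict(model$booster, xgboost::xgb.DMatrix(X))
  if (is.null(dim(prob))) {
    prob <- matrix(prob, nrow = nrow(X), ncol = length(model$labels), byrow = TRUE)
  }
  model$labels[max.col(prob, ties.method = "first")]
}

#' Evaluate the baseline on a stratified holdout
#'
#' Uses the identical split discipline (and, for the same seed, the
#' byte-identical split) as [evaluate_holdout()], reporting one overall
#' accuracy and one macro-F1 — the baseline has no k-NN decision modes.
#'
#' @inheritParams evaluate_holdout
#' @return A `crf_baseline_report`: `accuracy`, `macro_f1`, `n_train`,
#'   `n_test`, `seed`, `test_fraction`.
#' @export
evaluate_baseline <- function(corpus, test_fraction = 0.2, seed = 1L,
                              nrounds = 100L) {
  corpus <- normalize_corpus(corpus)
  split <- stratified_split(corpus, test_fraction = test_fraction, seed = seed)
  model <- train_baseline(split$train, seed = seed, nrounds = nrounds)
  pred <- predict_baseline(model, split$test)
  truth <- split$test$label
  structure(list(accuracy = mean(pred == truth),
                 macro_f1 = macro_f1(truth, pred),
                 n_train = nrow(split$train), n_test = nrow(split$test),
                 seed = seed, test_fraction = test_fraction),
            class = "crf_baseline_report")
}

#' @export
print.crf_baseline_report <- function(x, ...) {
  cat(sprintf("<crf_baseline_report> accuracy %.3f | macro-F1 %.3f (%d train / %d test)\n",
              x$accuracy, x$macro_f1, x$n_train, x$n_test))
  invisible(x)
}
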