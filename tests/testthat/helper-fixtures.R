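# Shared fixtures. Heavy full-scale pipeline runs are computed once per
# test session and memoised here, since several properties are checked on
# the same trained model.

fixture_env <- new.env(parent = emptyenv())

# A 6-row corpus transcribing the canonical sample of real field metadata,
# with curated SDTM targets added.
sample_corpus <- function() {
  crf_corpus(data.frame(
    form_oid = c("DRUG_ADMINISTRATION", "VITAL_SIGNS", "RAND", "ELIG", "DC",
                 "EXPIRATION"),
    field_oid = c("AGT_ACTL_DOSE", "DIAST_BP_VAL", "RNDDAT", "ELIGBRTHDAT",
                  "DCSYSBP", "DEATH_MDY_DT"),
    pre_text = c("Actual Total Dose", "Diastolic Blood Pressure Value",
                 "<b>Randomization Date</b>", "Date of Birth:",
                 "Systolic blood pressure:", "<b>Date of Death</b>"),
    post_text = c("(ddddd.ddd)", "(dddddddd)", "(GMT)", "(MM/DD/YYYY)",
                  "(mmHg)", "(MMM dd yyyy)"),
    label = c("EXDOSE", "VSORRES", "DSSTDTC", "BRTHDTC", "VSORRES", "DTHDTC"),
    stringsAsFactors = FALSE
  ), source = "sample")
}

# Small, fast, separable corpus for unit tests of the pipeline stages.
small_groundtruth <- function(seed = 11L, n_classes = 5L, support = 24L, ...) {
  generate_corpus(synth_config(n_classes = n_classes, balanced_support = support,
                               seed = seed, ...))
}

# Reduced-size model config for fast training in unit tests.
small_config <- function(vocab_size, max_len, seed = 1L, ...) {
  siamese_config(vocab_size = vocab_size, max_len = max_len, lookup_dim = 32L,
                 recurrent_units = 16L, embedding_dim = 8L, seed = seed, ...)
}

# Train a tiny mapper once and reuse it (unit tests of embed/index/save).
small_mapper <- function() {
  if (is.null(fixture_env$small_mapper)) {
    gt <- small_groundtruth()
    split <- stratified_split(gt$corpus, 0.2, seed = 5L)
    cfg <- local({
      corpus <- normalize_corpus(split$train)
      texts <- concatenate_fields(corpus)
      vocab <- build_vocabulary(texts)
      ml <- max(vapply(texts, function(t) length(tokenize(t)), integer(1)))
      small_config(vocab$size, ml, seed = 5L, epochs = 2L)
    })
    fixture_env$small_mapper <- list(
      mapper = train_field_mapper(split$train, model_config = cfg, seed = 5L,
                                  n_same = 5L, n_diff = 5L),
      split = split, gt = gt
    )
  }
  fixture_env$small_mapper
}

# The full-scale reference experiment: balanced profile, 10 classes x 150
# records, shared_token_fraction 0.3, default model (256/64/32, 3 epochs,
# batch 64, k = 5) on a 20% stratified holdout. Shared by the end-to-end
# recovery, pair-accuracy and baseline-comparison tests.
reference_run <- function() {
  if (is.null(fixture_env$reference_run)) {
    gt <- generate_corpus(synth_config(n_classes = 10L,
                                       class_supports = "balanced",
                                       balanced_support = 150L,
                                       shared_token_fraction = 0.3,
                                       seed = 42L))
    res <- evaluate_holdout(gt$corpus, seed = 7L, keep_model = TRUE)
    fixture_env$reference_run <- list(gt = gt, report = res$report,
                                      mapper = res$mapper, split = res$split)
  }
  fixture_env$reference_run
}

# Independent brute-force oracles -------------------------------------------

oracle_euclidean <- function(a, b) {
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  sqrt(acc)
}

oracle_vocabulary <- function(texts) {
  seen <- character()
  for (tx in texts) {
    for (tok in tokenize(tx)) {
      if (!(tok %in% seen)) seen <- c(seen, tok)
    }
  }
  stats::setNames(seq_along(seen), seen)
}

oracle_encode <- function(text, index_of, max_len) {
  out <- integer(max_len)
  toks <- tokenize(text)
  for (i in seq_len(min(length(toks), max_len))) {
    out[i] <- if (toks[i] %in% names(index_of)) index_of[[toks[i]]] else 0L
  }
  out
}

oracle_knn <- function(ref, labels, query, k) {
  d <- numeric(nrow(ref))
  for (i in seq_len(nrow(ref))) d[i] <- oracle_euclidean(ref[i, ], query)
  ord <- order(d, seq_len(nrow(ref)))[seq_len(k)]
  list(refs = ord, labels = labels[ord], distances = d[ord])
}

oracle_macro_f1 <- function(truth, pred) {
  classes <- unique(truth)
  cm <- matrix(0, length(classes), length(classes) + 1L,
               dimnames = list(classes, NULL))
  f1 <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(truth)) {
      if (truth[i] == cl && pred[i] == cl) tp <- tp + 1
      if (truth[i] != cl && pred[i] == cl) fp <- fp + 1
      if (truth[i] == cl && pred[i] != cl) fn <- fn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[ci] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  mean(f1)
}
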