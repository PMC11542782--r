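test_that("generated corpora honor supports, labels and determinism exactly", {
  cfg <- synth_config(n_classes = 10, balanced_support = 150, seed = 7)
  gt <- generate_corpus(cfg)
  expect_identical(nrow(gt$corpus), 1500L)
  expect_length(unique(gt$corpus$label), 10L)
  expect_identical(unname(c(table(gt$corpus$label))), rep(150L, 10))
  # every record's label matches its generating template
  lab_of_template <- tapply(gt$corpus$label, gt$template, unique)
  expect_true(all(lengths(lab_of_template) == 1L))

  gt2 <- generate_corpus(synth_config(n_classes = 10, balanced_support = 150, seed = 7))
  expect_identical(gt2$corpus, gt$corpus)
  gt3 <- generate_corpus(synth_config(n_classes = 10, balanced_support = 150, seed = 8))
  expect_false(identical(gt3$corpus$pre_text, gt$corpus$pre_text))
})

test_that("the figure4 profile reproduces the imbalance ladder", {
  cfg <- synth_config(n_classes = 10, class_supports = "figure4", seed = 3)
  gt <- generate_corpus(cfg)
  st <- corpus_stats(gt)
  expect_identical(sort(unname(st$supports)), sort(rep(c(10L, 25L, 50L, 100L, 200L), 2)))
})

test_that("confusable classes share pre-text vocabulary but not OIDs", {
  cfg <- synth_config(n_classes = 4, balanced_support = 80,
                      confusable_groups = list(c(1L, 2L)), seed = 9)
  gt <- generate_corpus(cfg)
  corpus <- normalize_corpus(gt$corpus)
  labs <- unique(corpus$label[order(gt$template)])
  st <- corpus_stats(gt)
  # pre-text token overlap of the confusable pair >= 80%
  expect_gte(st$overlap[labs[1], labs[2]], 0.8)
  # their FieldOID token sets are disjoint
  fid_tokens <- function(l) unique(unlist(lapply(
    corpus$field_oid[corpus$label == l], tokenize)))
  expect_length(intersect(fid_tokens(labs[1]), fid_tokens(labs[2])), 0L)
  # non-confusable classes overlap far less than the confusable pair
  expect_lt(st$overlap[labs[3], labs[4]], st$overlap[labs[1], labs[2]])
})

test_that("shared_token_fraction drives cross-class lexical overlap", {
  lo <- corpus_stats(generate_corpus(synth_config(n_classes = 4, balanced_support = 60,
                                                  shared_token_fraction = 0,
                                                  seed = 5)))
  hi <- corpus_stats(generate_corpus(synth_config(n_classes = 4, balanced_support = 60,
                                                  shared_token_fraction = 1,
                                                  seed = 5)))
  off_lo <- lo$overlap[upper.tri(lo$overlap)]
  off_hi <- hi$overlap[upper.tri(hi$overlap)]
  expect_lt(mean(off_lo), 0.35)
  # variant-specific phrasing keeps the overlap below 1 even at fraction 1
  expect_gt(mean(off_hi), 0.7)
  expect_gt(mean(off_hi), mean(off_lo))
})

test_that("OOV injection creates test-side sequences containing zeros", {
  cfg <- synth_config(n_classes = 4, balanced_support = 40,
                      oov_injection_rate = 0.5, seed = 21)
  gt <- generate_corpus(cfg)
  sp <- stratified_split(gt$corpus, 0.25, seed = 2)
  train <- normalize_corpus(sp$train)
  vocab <- build_vocabulary(concatenate_fields(train))
  enc_test <- encode_corpus(normalize_corpus(sp$test), vocab, 16L)
  # injected novel tokens are unique per record, so test-side ones are OOV
  nonpad <- enc_test[, 1:10]
  expect_gt(sum(nonpad == 0L), 0L)
})

test_that("HTML wrappers appear and are removed by normalization", {
  cfg <- synth_config(n_classes = 3, balanced_support = 50, html_fraction = 0.5,
                      seed = 33)
  gt <- generate_corpus(cfg)
  expect_gt(sum(grepl("<", gt$corpus$pre_text, fixed = TRUE)), 0L)
  norm <- normalize_corpus(gt$corpus)
  expect_identical(sum(grepl("[<>]", norm$pre_text)), 0L)
})

test_that("corpus_stats reports vocabulary size and maximum sequence length", {
  gt <- small_groundtruth(seed = 3)
  st <- corpus_stats(gt)
  corpus <- normalize_corpus(gt$corpus)
  texts <- concatenate_fields(corpus)
  expect_identical(st$vocab_size, build_vocabulary(texts)$size)
  expect_identical(st$max_length,
                   max(vapply(texts, function(t) length(tokenize(t)), integer(1))))
})

test_that("invalid configs are rejected", {
  expect_error(synth_config(n_classes = 3, class_supports = c(5L, 5L)), "one entry")
  expect_error(synth_config(n_classes = 3, confusable_groups = list(c(1L, 9L))),
               "invalid class index")
  expect_error(synth_config(n_classes = 2, balanced_support = 0), ">= 1")
})

test_that("ground truth writes a CSV corpus plus a JSON sidecar that re-reads", {
  gt <- small_groundtruth(seed = 41, n_classes = 3L, support = 10L)
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "corpus.csv")
  write_groundtruth(gt, csv)
  back <- read_corpus(csv, has_labels = TRUE)
  expect_identical(back$pre_text, gt$corpus$pre_text)
  sidecar <- jsonlite::read_json(file.path(dir, "corpus-truth.json"))
  expect_identical(length(sidecar$template), nrow(gt$corpus))
  expect_equal(sidecar$config$seed, 41)
})
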