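test_that("pair_distance is the Euclidean metric and matches a loop oracle", {
  expect_identical(pair_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(pair_distance(c(3, 4, rep(0, 30)), rep(0, 32)), 5)
  expect_error(pair_distance(1:3, 1:4), "dimension mismatch")

  set.seed(21)
  for (i in 1:100) {
    a <- rnorm(32); b <- rnorm(32)
    expect_equal(pair_distance(a, b), oracle_euclidean(a, b), tolerance = 1e-12)
    expect_identical(pair_distance(a, b), pair_distance(b, a))
  }
})

test_that("encoder construction is seeded, shaped and validated", {
  cfg <- small_config(vocab_size = 100L, max_len = 12L, seed = 4L)
  enc1 <- build_encoder(cfg)
  enc2 <- build_encoder(cfg)
  probe <- matrix(sample(0:100, 24, TRUE), 2, 12)
  expect_identical(embed_sequences(enc1, probe), embed_sequences(enc2, probe))
  expect_identical(dim(embed_sequences(enc1, probe)), c(2L, cfg$embedding_dim))

  full <- siamese_config(vocab_size = 100L, max_len = 12L)
  expect_identical(ncol(embed_sequences(build_encoder(full), probe)), 32L)

  expect_error(siamese_config(vocab_size = 10, max_len = 5, embedding_dim = 0),
               "nonpositive")
  expect_error(embed_sequences(enc1, matrix(0L, 1, 5)), "max_len")
})

test_that("embedding is a pure function and tolerates unknown-only input", {
  enc <- build_encoder(small_config(50L, 8L, seed = 2L))
  s <- sample(0:50, 8, TRUE)
  expect_identical(embed_sequences(enc, s), embed_sequences(enc, s))
  z <- embed_sequences(enc, integer(8L))   # all-OOV/padding
  expect_true(all(is.finite(z)))
})

test_that("training separates classes, is seeded, and records its history", {
  gt <- small_groundtruth(seed = 31L, n_classes = 4L, support = 18L)
  corpus <- normalize_corpus(gt$corpus)
  texts <- concatenate_fields(corpus)
  vocab <- build_vocabulary(texts)
  max_len <- max(vapply(texts, function(t) length(tokenize(t)), integer(1)))
  enc <- encode_corpus(corpus, vocab, max_len)
  pairs <- generate_pairs(enc, corpus$label, 8, 8, seed = 31)
  cfg <- small_config(vocab$size, max_len, seed = 31L, epochs = 3L)

  trained <- train_siamese(pairs, cfg)
  expect_identical(nrow(trained$history), 3L)
  # loss decreases from the first epoch on separable data
  expect_lt(trained$history$loss[3], trained$history$loss[1])
  expect_gt(pair_accuracy(trained, pairs), 0.85)   # reduced-size config

  # same-class distances sit below different-class distances after training
  Z <- embed_sequences(trained, enc)
  D <- as.matrix(dist(Z))
  same <- outer(corpus$label, corpus$label, "==")
  diag(same) <- NA
  expect_lt(mean(D[which(same)]), mean(D[which(!same)]))
  # stochastic dominance of the same-class distance distribution (rank-sum)
  expect_lt(suppressWarnings(
    stats::wilcox.test(D[which(same)], D[which(!same)],
                       alternative = "less")$p.value), 1e-6)

  # bitwise determinism under an identical seed
  trained2 <- train_siamese(pairs, cfg)
  expect_identical(embed_sequences(trained2, enc[1:5, ]),
                   embed_sequences(trained, enc[1:5, ]))
})

test_that("twin weight sharing makes the head symmetric in its inputs", {
  fx <- small_mapper()
  enc <- fx$mapper
  pairs <- enc$pairs
  Za <- embed_sequences(enc$encoder, pairs$seq_a[1:20, ])
  Zb <- embed_sequences(enc$encoder, pairs$seq_b[1:20, ])
  d_ab <- sqrt(rowSums((Za - Zb)^2))
  d_ba <- sqrt(rowSums((Zb - Za)^2))
  expect_identical(d_ab, d_ba)
})

test_that("degenerate pair sets are rejected", {
  cfg <- small_config(10L, 4L)
  one_target <- structure(list(seq_a = matrix(1L, 4, 4), seq_b = matrix(2L, 4, 4),
                               target = rep(0L, 4), idx_a = 1:4, idx_b = 1:4,
                               n_records = 4L), class = "crf_pairs")
  expect_error(train_siamese(one_target, cfg), "both")
})

test_that("distance metric axioms hold on the trained embedding space", {
  fx <- small_mapper()
  Z <- fx$mapper$index$embeddings
  set.seed(8)
  for (i in 1:200) {
    tri <- sample(nrow(Z), 3)
    a <- Z[tri[1], ]; b <- Z[tri[2], ]; c <- Z[tri[3], ]
    expect_gte(pair_distance(a, b), 0)
    expect_equal(pair_distance(a, b), pair_distance(b, a))
    expect_lte(pair_distance(a, c), pair_distance(a, b) + pair_distance(b, c) + 1e-12)
  }
})

test_that("encoder archives round-trip and detect corruption", {
  fx <- small_mapper()
  encd <- fx$mapper$encoder
  dir <- withr::local_tempdir()
  save_encoder(encd, dir)
  back <- load_encoder(dir)
  probe <- encode_corpus(normalize_corpus(fx$split$test), fx$mapper$vocab,
                         encd$config$max_len)[1:10, ]
  expect_identical(embed_sequences(back, probe), embed_sequences(encd, probe))
  expect_identical(unclass(back$config), unclass(encd$config))
  expect_identical(back$vocab$index_of, encd$vocab$index_of)

  # truncated weights -> format error
  wfile <- file.path(dir, "weights.rds")
  raw <- readBin(wfile, "raw", file.size(wfile))
  writeBin(raw[1:20], wfile)
  expect_error(load_encoder(dir), "corrupt")
  # schema stamp checked
  writeLines("other-tool/9", file.path(dir, "FORMAT"))
  expect_error(load_encoder(dir), "schema mismatch")
})

test_that("the contrastive-loss mode also trains to separation", {
  gt <- small_groundtruth(seed = 13L, n_classes = 3L, support = 12L)
  corpus <- normalize_corpus(gt$corpus)
  texts <- concatenate_fields(corpus)
  vocab <- build_vocabulary(texts)
  ml <- max(vapply(texts, function(t) length(tokenize(t)), integer(1)))
  enc <- encode_corpus(corpus, vocab, ml)
  pairs <- generate_pairs(enc, corpus$label, 6, 6, seed = 13)
  cfg <- small_config(vocab$size, ml, seed = 13L, epochs = 3L, loss = "contrastive")
  trained <- train_siamese(pairs, cfg)
  Z <- embed_sequences(trained, enc)
  D <- as.matrix(dist(Z))
  same <- outer(corpus$label, corpus$label, "==")
  diag(same) <- NA
  expect_lt(mean(D[which(same)]), mean(D[which(!same)]))
})
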