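test_that("macro_f1 matches a confusion-matrix oracle and its closed forms", {
  expect_identical(macro_f1(c("A", "B", "A"), c("A", "B", "A")), 1)
  expect_equal(macro_f1(c("A", "A", "B", "B"), c("A", "B", "A", "B")), 0.5)
  expect_error(macro_f1(character(), character()), "at least one")
  expect_error(macro_f1(c("A", "B"), "A"), "length")

  set.seed(17)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    truth <- sample(LETTERS[1:5], n, TRUE)
    pred <- sample(LETTERS[1:6], n, TRUE)   # predictions may use an extra class
    expect_equal(macro_f1(truth, pred), oracle_macro_f1(truth, pred),
                 tolerance = 1e-14)
  }
  # 1 iff perfect on every class present in the truth
  truth <- c("A", "A", "B")
  expect_lt(macro_f1(truth, c("A", "A", "A")), 1)
})

test_that("holdout evaluation is reproducible end-to-end and reports mode dominance", {
  fx <- small_mapper()
  gt <- fx$gt
  cfg <- fx$mapper$config
  r1 <- evaluate_holdout(gt$corpus, model_config = cfg, seed = 5, n_same = 5, n_diff = 5)
  r2 <- evaluate_holdout(gt$corpus, model_config = cfg, seed = 5, n_same = 5, n_diff = 5)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$per_class, r2$per_class)

  expect_gte(r1$accuracy[["contains"]], r1$accuracy[["nearest"]])
  expect_gte(r1$accuracy[["contains"]], r1$accuracy[["majority"]])
  # per-class accuracies aggregate (test-count weighted) to the overall
  pc <- r1$per_class
  expect_equal(sum(pc$accuracy * pc$test_count) / sum(pc$test_count),
               unname(r1$accuracy["nearest"]))
})

test_that("test labels never seen in training count as misses and are flagged", {
  gt <- small_groundtruth(seed = 19L, n_classes = 4L, support = 15L)
  corpus <- gt$corpus
  # forge a label that exists only on the test side of any split: rename two
  # records of one class after splitting decisions by giving them a label of
  # their own and forcing them into test via a custom split
  sp <- stratified_split(corpus, 0.25, seed = 3)
  test2 <- sp$test
  test2$label[1:2] <- "GHOSTVAR"
  mapper <- train_field_mapper(sp$train, model_config = NULL, seed = 3,
                               n_same = 5, n_diff = 5)
  scores <- crfmapr:::score_test_side(mapper, test2, k = 5)
  ghost <- scores$per_class[scores$per_class$label == "GHOSTVAR", ]
  expect_identical(ghost$accuracy, 0)
  expect_false(ghost$seen_in_train)
  expect_identical(ghost$train_support, 0L)
})

test_that("cross-validation partitions every record into exactly one test fold", {
  gt <- small_groundtruth(seed = 23L, n_classes = 4L, support = 15L)
  corpus <- gt$corpus
  texts <- concatenate_fields(normalize_corpus(corpus))
  vocab <- build_vocabulary(texts)
  ml <- max(vapply(texts, function(t) length(tokenize(t)), integer(1)))
  cfg <- small_config(vocab$size, ml, epochs = 1L)
  reports <- cross_validate(corpus, folds = 3, model_config = cfg, seed = 2,
                            n_same = 3, n_diff = 3)
  expect_length(reports, 3L)
  expect_equal(sum(vapply(reports, function(r) r$n_test, numeric(1))),
               nrow(corpus))
  for (r in reports) {
    expect_gte(r$accuracy[["contains"]], r$accuracy[["nearest"]])
    expect_gte(r$accuracy[["contains"]], r$accuracy[["majority"]])
  }
})

test_that("support_accuracy_table groups classes at the threshold", {
  report <- list(per_class = data.frame(
    label = c("A", "B", "C", "D"),
    train_support = c(10L, 25L, 100L, 200L),
    test_count = c(5L, 5L, 5L, 5L),
    accuracy = c(0.2, 0.4, 0.9, 1.0),
    seen_in_train = TRUE
  ))
  class(report) <- "crf_eval_report"
  tab <- support_accuracy_table(report, threshold = 100)
  expect_equal(tab$below_mean, 0.3)
  expect_equal(tab$above_mean, 0.95)
  # all classes on one side: the empty group is NA, no error
  tab0 <- support_accuracy_table(report, threshold = 0)
  expect_true(is.na(tab0$below_mean))
  expect_equal(tab0$above_mean, mean(report$per_class$accuracy))
})

test_that("pca_project matches an eigendecomposition oracle up to sign", {
  set.seed(18)
  X <- matrix(rnorm(200 * 6), 200, 6)
  sc <- pca_project(X, 2)
  # oracle: eigenvectors of the covariance of centered data
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eg <- eigen(crossprod(Xc) / (nrow(X) - 1))
  orc <- Xc %*% eg$vectors[, 1:2]
  for (j in 1:2) {
    expect_equal(abs(sc[, j]), abs(orc[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_gte(stats::var(sc[, 1]), stats::var(sc[, 2]))

  # rank-2 data reconstructs exactly from 2 components
  B <- matrix(rnorm(2 * 32), 2, 32)
  Y <- matrix(rnorm(50 * 2), 50, 2) %*% B
  s2 <- pca_project(Y, 2)
  rot <- attr(s2, "rotation")
  recon <- s2 %*% t(rot)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  expect_equal(recon, Yc, tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(pca_project(matrix(0, 2, 5), 2), "at least")
})

test_that("evaluation reports serialize to JSON with the per-class CSV sidecar", {
  fx <- small_mapper()
  scores <- crfmapr:::score_test_side(fx$mapper, fx$split$test, k = 5)
  report <- crfmapr:::new_eval_report(scores, fx$mapper, 5L, 0.2, 5L)
  path <- file.path(withr::local_tempdir(), "report.json")
  write_eval_report(report, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$accuracy$nearest, unname(report$accuracy["nearest"]))
  expect_true(file.exists(sub("\\.json$", "-per-class.csv", path)))
})
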