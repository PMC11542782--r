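# Leakage-safe stratified splitting and same/different-class pair generation.
#
# The split always precedes pair generation and vocabulary building: pairs
# are drawn from one side only, so no training signal can leak across the
# holdout boundary.

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic per-stage seed fan-out from one top-level seed (kept < 2^31).
stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + stage) %% 2147483629
}

#' Stratified train/test split of a labeled corpus
#'
#' Allocates each label's records to the test side in proportion
#' `test_fraction` (within one record), shuffling within label under `seed`.
#' Labels with at least two records appear on both sides whenever the
#' arithmetic allows; singleton labels go to the training side with a
#' warning.
#'
#' @param corpus labeled [crf_corpus()] with >= 2 distinct labels.
#' @param test_fraction real in (0, 1); the headline protocol uses 0.2.
#' @param seed integer seed; identical corpus + seed gives identical splits.
#' @return A `crf_split`: list with `train`, `test` (corpora), `train_idx`,
#'   `test_idx` (row indices into the input), `fraction`, `seed`,
#'   `singletons` (labels forced entirely into train).
#' @export
stratified_split <- function(corpus, test_fraction = 0.2, seed = 1L) {
  validate_corpus(corpus, require_labels = TRUE, require_multiclass = TRUE)
  stopifnot(test_fraction > 0, test_fraction < 1)
  by_label <- split(seq_len(nrow(corpus)), corpus$label)
  test_idx <- integer()
  singletons <- character()
  with_seed(seed, {
    for (lab in names(by_label)) {
      ids <- by_label[[lab]]
      n <- length(ids)
      if (n < 2L) {
        singletons <- c(singletons, lab)
        next
      }
      n_test <- min(n - 1L, max(1L, round(n * test_fraction)))
      ids <- ids[sample.int(n)]
      test_idx <- c(test_idx, ids[seq_len(n_test)])
    }
  })
  if (length(singletons)) {
    warning("label(s) with a single record kept entirely in train: ",
            paste(singletons, collapse = ", "))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(nrow(corpus)), test_idx)
  src <- attr(corpus, "source") %||% "?"
  structure(list(
    train = crf_corpus(corpus[train_idx, , drop = FALSE],
                       source = paste0(src, " [train]")),
    test = crf_corpus(corpus[test_idx, , drop = FALSE],
                      source = paste0(src, " [test]")),
    train_idx = train_idx, test_idx = test_idx,
    fraction = test_fraction, seed = seed, singletons = singletons
  ), class = "crf_split")
}

#' Generate same-class / different-class training pairs
#'
#' For each record, draws `n_same` partners with the same label (never the
#' record itself; uniformly, with replacement across draws) with pair target
#' 0, and `n_diff` partners with a different label with target 1. Records
#' whose label has no other member contribute no same-class pairs (reported
#' via a message). Call on one side of a split only.
#'
#' @param encoded integer matrix of encoded sequences, one row per record.
#' @param labels character vector aligned with `encoded`'s rows.
#' @param n_same,n_diff pairs per record of each kind (both >= 1; default 20,
#'   the published recipe).
#' @param seed integer seed; output order is deterministic given the seed.
#' @return A `crf_pairs`: list with `seq_a`, `seq_b` (matrices), `target`
#'   (0 = same class, 1 = different), `idx_a`, `idx_b` (source row indices),
#'   `n_records`.
#' @export
generate_pairs <- function(encoded, labels, n_same = 20L, n_diff = 20L, seed = 1L) {
  if (is.null(dim(encoded))) encoded <- matrix(encoded, nrow = length(labels))
  n <- nrow(encoded)
  if (n == 0L) stop("cannot generate pairs from an empty record list")
  stopifnot(length(labels) == n, n_same >= 1L, n_diff >= 1L)
  if (length(unique(labels)) < 2L) {
    stop("all records share one label: no different-class pairs are possible")
  }
  ia <- ib <- vector("list", n)
  tg <- vector("list", n)
  n_singleton <- 0L
  with_seed(seed, {
    for (r in seq_len(n)) {
      same_pool <- which(labels == labels[r])
      same_pool <- same_pool[same_pool != r]
      diff_pool <- which(labels != labels[r])
      if (length(same_pool) == 0L) {
        n_singleton <- n_singleton + 1L
        same <- integer()
      } else {
        same <- same_pool[sample.int(length(same_pool), n_same, replace = TRUE)]
      }
      diff <- diff_pool[sample.int(length(diff_pool), n_diff, replace = TRUE)]
      ia[[r]] <- rep.int(r, length(same) + length(diff))
      ib[[r]] <- c(same, diff)
      tg[[r]] <- c(integer(length(same)), rep.int(1L, length(diff)))
    }
  })
  if (n_singleton > 0L) {
    message(n_singleton, " record(s) with a singleton label contributed no same-class pairs")
  }
  ia <- unlist(ia); ib <- unlist(ib); tg <- unlist(tg)
  structure(list(
    seq_a = encoded[ia, , drop = FALSE],
    seq_b = encoded[ib, , drop = FALSE],
    target = tg, idx_a = ia, idx_b = ib, n_records = n
  ), class = "crf_pairs")
}

#' @export
print.crf_pairs <- function(x, ...) {
  cat(sprintf("<crf_pairs> %d pair(s) from %d record(s): %d same-class (target 0), %d different-class (target 1)\n",
              length(x$target), x$n_records, sum(x$target == 0L), sum(x$target == 1L)))
  invisible(x)
}

#' Dump pair indices for debugging
#' @param pairs a `crf_pairs`.
#' @param path CSV path receiving (row_index_a, row_index_b, target).
#' @export
write_pairs <- function(pairs, path) {
  utils::write.csv(data.frame(row_index_a = pairs$idx_a,
                              row_index_b = pairs$idx_b,
                              target = pairs$target),
                   path, row.names = FALSE)
  invisible(path)
}
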