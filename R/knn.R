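# Exact k-nearest-neighbour suggestion over learned embeddings.
#
# The suggester answers the three auto-suggest decision questions: is the
# true SDTM variable (1) among the k nearest neighbours at all, (2) the
# single nearest neighbour's class, (3) the plurality class of the k
# neighbours. Search is exact (all pairwise Euclidean distances); corpus
# sizes in this domain never justify approximate structures. Ties on
# distance break by ascending record reference, majority-vote ties by the
# tied class whose member ranks nearest — both artifact conventions chosen
# for reproducibility.

#' Construct a reference index from raw embeddings
#'
#' @param embeddings numeric matrix, one embedding per row.
#' @param labels character vector aligned with the rows.
#' @param record_refs stable source-row identifiers (default row numbers);
#'   also the distance tie-break key.
#' @return A `crf_reference_index`.
#' @export
new_reference_index <- function(embeddings, labels, record_refs = seq_len(nrow(embeddings))) {
  stopifnot(nrow(embeddings) == length(labels),
            nrow(embeddings) == length(record_refs))
  structure(list(embeddings = embeddings, labels = as.character(labels),
                 record_refs = record_refs),
            class = "crf_reference_index")
}

#' Index the training corpus in embedding space
#'
#' Embeds every training record with the trained encoder (which must carry
#' the vocabulary built from this corpus's training split) and stores the
#' aligned labels.
#'
#' @param encoder trained `siamese_encoder` with `$vocab` attached.
#' @param train_corpus labeled, normalized [crf_corpus()].
#' @param k the neighbourhood size the index must support (default 5).
#' @return A `crf_reference_index`.
#' @export
build_index <- function(encoder, train_corpus, k = 5L) {
  validate_corpus(train_corpus, require_labels = TRUE)
  if (is.null(encoder$vocab)) stop("encoder carries no vocabulary; train via train_field_mapper() or attach one")
  if (nrow(train_corpus) < k) {
    stop("index needs at least k = ", k, " records; got ", nrow(train_corpus))
  }
  enc <- encode_corpus(train_corpus, encoder$vocab, encoder$config$max_len)
  new_reference_index(embed_sequences(encoder, enc), train_corpus$label)
}

# All query-vs-reference Euclidean distances (nq x nref).
cross_distances <- function(Q, R) {
  D2 <- outer(rowSums(Q^2), rowSums(R^2), "+") - 2 * tcrossprod(Q, R)
  D2[D2 < 0] <- 0
  sqrt(D2)
}

majority_label <- function(ranked_labels) {
  cnt <- table(ranked_labels)
  tied <- names(cnt)[cnt == max(cnt)]
  if (length(tied) == 1L) return(tied)
  ranked_labels[min(which(ranked_labels %in% tied))]
}

#' Suggest SDTM targets for one query embedding
#'
#' Exact k nearest neighbours by Euclidean distance, plus the three
#' decision-mode answers derived from them.
#'
#' @param index a `crf_reference_index`.
#' @param query numeric embedding vector.
#' @param k neighbourhood size (default 5, the published choice).
#' @return A `crf_suggestion`: `neighbors` (data.frame of label, distance,
#'   record_ref in ascending distance), `nearest_label`, `majority_label`,
#'   `top_k_labels`.
#' @export
suggest_fields <- function(index, query, k = 5L) {
  stopifnot(inherits(index, "crf_reference_index"), k >= 1L)
  if (length(query) != ncol(index$embeddings)) {
    stop("query dimension (", length(query), ") does not match index dimension (",
         ncol(index$embeddings), ")")
  }
  if (nrow(index$embeddings) < k) stop("index has fewer than k records")
  d <- sqrt(colSums((t(index$embeddings) - query)^2))
  ord <- order(d, index$record_refs)[seq_len(k)]
  labs <- index$labels[ord]
  structure(list(
    neighbors = data.frame(label = labs, distance = d[ord],
                           record_ref = index$record_refs[ord]),
    nearest_label = labs[1L],
    majority_label = majority_label(labs),
    top_k_labels = unique(labs)
  ), class = "crf_suggestion")
}

# Batched version used by the evaluators: returns per-query nearest and
# majority labels plus the k ranked neighbour labels as a matrix.
classify_index <- function(index, queries, k = 5L) {
  D <- cross_distances(queries, index$embeddings)
  nq <- nrow(queries)
  lab_mat <- matrix(NA_character_, nq, k)
  for (i in seq_len(nq)) {
    ord <- order(D[i, ], index$record_refs)[seq_len(k)]
    lab_mat[i, ] <- index$labels[ord]
  }
  list(labels = lab_mat,
       nearest = lab_mat[, 1L],
       majority = apply(lab_mat, 1L, majority_label))
}

#' Answer the three decision questions for a suggestion
#'
#' @param suggestion a [suggest_fields()] result.
#' @param true_label the curated SDTM target.
#' @return named logical vector: `contains` (true label among the k
#'   neighbours), `nearest` (nearest neighbour's label is the true label),
#'   `majority` (plurality vote is the true label).
#' @export
decide_suggestion <- function(suggestion, true_label) {
  stopifnot(inherits(suggestion, "crf_suggestion"))
  c(contains = true_label %in% suggestion$top_k_labels,
    nearest = identical(suggestion$nearest_label, true_label),
    majority = identical(suggestion$majority_label, true_label))
}

#' @export
print.crf_suggestion <- function(x, ...) {
  cat("<crf_suggestion> nearest:", x$nearest_label,
      "| majority:", x$majority_label, "\n")
  print(x$neighbors)
  invisible(x)
}
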