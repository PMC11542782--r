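# Concatenation, tokenization and first-seen dictionary encoding.
#
# The vocabulary maps tokens to the positive integers 1..size in order of
# first appearance in the training text stream; index 0 is reserved and
# doubles as the out-of-vocabulary code and the right-padding code. The
# vocabulary is always built from the training split only, so tokens unique
# to held-out records encode to 0 — the OOV failure mode the method has to
# live with at deployment time.

#' Concatenate the four metadata fields of a record
#'
#' Joins FormOID, FieldOID, PreText and PostText (in that order) with single
#' spaces, skipping empty fields. Vectorized: given a corpus, returns one
#' string per record.
#'
#' @param record a normalized record, or a whole [crf_corpus()].
#' @return character vector of concatenated texts.
#' @export
concatenate_fields <- function(record) {
  parts <- cbind(record$form_oid, record$field_oid, record$pre_text, record$post_text)
  apply(parts, 1L, function(p) paste(p[nzchar(p)], collapse = " "))
}

#' Tokenize field text
#'
#' Lowercases, splits on whitespace, strips leading/trailing punctuation
#' (other than underscore) from each token and drops empties. Interior
#' punctuation is kept, so `"(ddddd.ddd)"` tokenizes to `"ddddd.ddd"` and
#' OIDs like `"DIAST_BP_VAL"` stay one token.
#'
#' @param text a single string.
#' @return character vector of tokens (possibly empty).
#' @export
tokenize <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character())
  toks <- strsplit(trimws(tolower(text)), "[[:space:]]+")[[1L]]
  toks <- gsub("^[^[:alnum:]_]+|[^[:alnum:]_]+$", "", toks)
  toks[nzchar(toks)]
}

#' Build a first-seen-order vocabulary from training texts
#'
#' The first token observed in the stream gets index 1, the second new token
#' index 2, and so on; index 0 is never assigned. Deterministic for a fixed
#' input order. Build only from the training split — see the leakage
#' discussion in the package vignette.
#'
#' @param texts ordered character vector of (concatenated) training texts.
#' @return A `crf_vocabulary`: list with `index_of` (named integer vector)
#'   and `size`.
#' @export
build_vocabulary <- function(texts) {
  toks <- unlist(lapply(texts, tokenize), use.names = FALSE)
  if (length(toks) == 0L) stop("cannot build a vocabulary from an empty token stream")
  uniq <- unique(toks)
  structure(list(index_of = stats::setNames(seq_along(uniq), uniq),
                 size = length(uniq)),
            class = "crf_vocabulary")
}

#' Encode text as a fixed-length integer sequence
#'
#' Tokens are mapped through the vocabulary; unknown tokens become 0. The
#' sequence is right-padded with 0 to `max_len`, or truncated to the first
#' `max_len` tokens.
#'
#' @param text a single string.
#' @param vocab a [build_vocabulary()] result.
#' @param max_len sequence length L (>= 1).
#' @return integer vector of length `max_len`, entries in `[0, vocab$size]`.
#' @export
encode_text <- function(text, vocab, max_len) {
  stopifnot(inherits(vocab, "crf_vocabulary"), max_len >= 1L)
  toks <- tokenize(text)
  idx <- unname(vocab$index_of[toks])
  idx[is.na(idx)] <- 0L
  length(idx) <- max_len            # truncates or NA-pads
  idx[is.na(idx)] <- 0L
  as.integer(idx)
}

#' Encode every record of a corpus
#' @param corpus a [crf_corpus()] (normalized).
#' @param vocab a [build_vocabulary()] result.
#' @param max_len sequence length.
#' @return integer matrix, one row per record, `max_len` columns.
#' @export
encode_corpus <- function(corpus, vocab, max_len) {
  texts <- concatenate_fields(corpus)
  t(vapply(texts, encode_text, integer(max_len), vocab = vocab,
           max_len = max_len, USE.NAMES = FALSE))
}

#' Serialize / restore a vocabulary as JSON
#'
#' The on-disk form is a plain `{token: index}` object so the dictionary can
#' be reused at prediction time.
#'
#' @param vocab a `crf_vocabulary`.
#' @param path JSON file path.
#' @export
save_vocabulary <- function(vocab, path) {
  jsonlite::write_json(as.list(vocab$index_of), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_vocabulary
#' @export
load_vocabulary <- function(path) {
  lst <- jsonlite::read_json(path)
  idx <- stats::setNames(as.integer(unlist(lst)), names(lst))
  idx <- sort(idx)
  if (!identical(unname(idx), seq_along(idx))) {
    stop("corrupt vocabulary file: indices are not exactly 1..size")
  }
  structure(list(index_of = idx, size = length(idx)), class = "crf_vocabulary")
}

#' @export
print.crf_vocabulary <- function(x, ...) {
  cat(sprintf("<crf_vocabulary> %d token(s); index 0 reserved for OOV/padding\n", x$size))
  invisible(x)
}
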