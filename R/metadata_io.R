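# Reading, validating, normalizing and writing labeled eCRF-field metadata.
#
# A corpus is a data.frame with columns form_oid, field_oid, pre_text,
# post_text, label (label NA-free only when the corpus is labeled), carrying
# class "crf_corpus" and a "source" attribute. On disk it is a UTF-8 CSV with
# header FormOID, FieldOID, PreText, PostText, Target (RFC-4180 quoting);
# Target is optional for prediction-time corpora.

CORPUS_COLUMNS <- c(FormOID = "form_oid", FieldOID = "field_oid",
                    PreText = "pre_text", PostText = "post_text",
                    Target = "label")

#' Construct a corpus of eCRF field records
#'
#' @param records data.frame with columns `form_oid`, `field_oid`, `pre_text`,
#'   `post_text` and optionally `label` (the SDTM target, e.g. `"AESTDTC"`;
#'   composite targets such as `"AESTDTC/CMSTDTC"` are legal opaque strings).
#' @param source provenance note (file path, generator call, ...).
#' @param labeled whether a non-empty label is required on every record.
#' @return A `crf_corpus` (a data.frame subclass).
#' @export
crf_corpus <- function(records, source = "in-memory", labeled = !all(is.na(records$label))) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("form_oid", "field_oid", "pre_text", "post_text")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("corpus is missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(records) == 0L) stop("empty corpus: no records")
  if (is.null(records$label)) records$label <- NA_character_
  records <- records[c(need, "label")]
  for (cl in names(records)) records[[cl]] <- as.character(records[[cl]])
  out <- structure(records, source = source, class = c("crf_corpus", "data.frame"))
  validate_corpus(out, require_labels = labeled)
  out
}

validate_corpus <- function(corpus, require_labels = FALSE, require_multiclass = FALSE) {
  if (nrow(corpus) == 0L) stop("empty corpus: no records")
  if (require_labels) {
    bad <- which(is.na(corpus$label) | !nzchar(trimws(corpus$label)))
    if (length(bad)) {
      stop("record(s) with empty label at row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    if (require_multiclass && length(unique(corpus$label)) < 2L) {
      stop("training corpus must contain at least 2 distinct labels")
    }
  }
  invisible(corpus)
}

#' Read a labeled or unlabeled field-metadata corpus from CSV
#'
#' Expects a header with columns `FormOID`, `FieldOID`, `PreText`, `PostText`
#' and, when `has_labels = TRUE`, `Target`. Absent or null text cells become
#' empty strings; rows are kept in file order.
#'
#' @param path CSV file path.
#' @param has_labels whether a `Target` column is required and validated
#'   non-empty on every row.
#' @return A [crf_corpus()].
#' @export
read_corpus <- function(path, has_labels = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character(), fileEncoding = "UTF-8")
  need <- c("FormOID", "FieldOID", "PreText", "PostText", if (has_labels) "Target")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("corpus file is missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(raw) == 0L) stop("empty corpus: file '", path, "' has no data rows")
  records <- data.frame(
    form_oid  = raw$FormOID,
    field_oid = raw$FieldOID,
    pre_text  = raw$PreText,
    post_text = raw$PostText,
    label     = if ("Target" %in% names(raw)) raw$Target else NA_character_,
    stringsAsFactors = FALSE
  )
  if (has_labels) {
    bad <- which(!nzchar(trimws(records$label)))
    if (length(bad)) {
      stop("empty Target label at data row(s): ", paste(utils::head(bad, 5L), collapse = ", "))
    }
  } else if (!is.null(records$label)) {
    records$label[!nzchar(records$label)] <- NA_character_
  }
  crf_corpus(records, source = path, labeled = has_labels)
}

#' Write a corpus back to CSV
#'
#' Round-trip guarantee: `read_corpus(path)` on the written file reproduces
#' every field of the corpus exactly (RFC-4180 quoting handles embedded
#' commas, quotes and newlines).
#'
#' @param corpus a [crf_corpus()].
#' @param path output file path.
#' @export
write_corpus <- function(corpus, path) {
  validate_corpus(corpus)
  out <- data.frame(
    FormOID  = corpus$form_oid,
    FieldOID = corpus$field_oid,
    PreText  = corpus$pre_text,
    PostText = corpus$post_text,
    stringsAsFactors = FALSE
  )
  if (!all(is.na(corpus$label))) out$Target <- corpus$label
  utils::write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Strip HTML markup from field text
#'
#' Removes markup tags, unescapes character entities, collapses runs of
#' whitespace to single spaces and trims the result. Malformed markup is
#' stripped best-effort and never raises. Idempotent.
#'
#' @param text character vector (empty strings allowed).
#' @return character vector of plain text.
#' @export
strip_html <- function(text) {
  text[is.na(text)] <- ""
  vapply(text, strip_html_one, character(1), USE.NAMES = FALSE)
}

strip_html_one <- function(x) {
  if (grepl("[<&]", x)) {
    x <- tryCatch(
      xml2::xml_text(xml2::read_html(paste0("<div>", x, "</div>"))),
      error = function(e) gsub("<[^>]*>", " ", x)
    )
  }
  trimws(gsub("[[:space:]]+", " ", x))
}

#' Normalize one field record
#'
#' Applies [strip_html()] to all four metadata strings and trims the OIDs;
#' the label is never touched. Errors if either OID is empty after trimming.
#'
#' @param record one-row data.frame (or list) with the corpus columns.
#' @return the normalized record, same shape as the input.
#' @export
normalize_record <- function(record) {
  for (f in c("form_oid", "field_oid", "pre_text", "post_text")) {
    record[[f]] <- strip_html(record[[f]])
  }
  record$form_oid <- trimws(record$form_oid)
  record$field_oid <- trimws(record$field_oid)
  bad <- !nzchar(record$form_oid) | !nzchar(record$field_oid)
  if (any(bad)) {
    stop("empty FormOID/FieldOID after trimming at record(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  record
}

#' Normalize every record of a corpus
#' @param corpus a [crf_corpus()].
#' @return the corpus with [normalize_record()] applied row-wise.
#' @export
normalize_corpus <- function(corpus) {
  out <- normalize_record(corpus)
  attr(out, "source") <- attr(corpus, "source")
  out
}

#' @export
print.crf_corpus <- function(x, ...) {
  labeled <- !all(is.na(x$label))
  cat(sprintf("<crf_corpus> %d record(s), %s (source: %s)\n", nrow(x),
              if (labeled) sprintf("%d label(s)", length(unique(x$label[!is.na(x$label)])))
              else "unlabeled",
              attr(x, "source") %||% "?"))
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
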