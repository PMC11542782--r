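# Synthetic annotated-CRF corpus generator.
#
# Each class (SDTM target) is emitted by several "source-form variants",
# emulating the same field being collected on different forms across
# trials: every variant carries its own FormOID/FieldOID jargon and a
# little variant-specific phrasing, on top of the class-level pre-text
# vocabulary. Low-support classes therefore cannot cover all of their
# variants in a training split — the mechanism behind the real
# support-versus-accuracy dependence and the partial train/test vocabulary
# disjointness the method has to survive.
#
# Emulates the statistical structure of real eCRF metadata that the method
# relies on: UPPER_SNAKE OID jargon that is unique to a mapping target,
# natural-phrase pre-text drawn from a class vocabulary mixed with shared
# form-boilerplate, parenthesized format-hint post-text, optional HTML
# wrappers (so HTML stripping is exercised), heavy class-support imbalance,
# cross-domain confusable classes that share their pre/post text and differ
# only in OIDs, and partial train/test vocabulary disjointness via novel
# token injection. Everything is deterministic given the config seed.

#' Configuration for the synthetic corpus generator
#'
#' @param n_classes number of SDTM target classes.
#' @param class_supports integer vector of per-class record counts (one per
#'   class), or a profile name: `"balanced"` (every class gets
#'   `balanced_support` records) or `"figure4"` (the imbalance ladder
#'   `{10, 25, 50, 100, 200}` recycled over the classes, for
#'   support-versus-accuracy experiments).
#' @param balanced_support support per class under the `"balanced"` profile
#'   (default 150).
#' @param tokens_per_class size of each class's private pre-text vocabulary
#'   (default 30).
#' @param variants_per_class number of source-form variants per class
#'   (default 6); each has its own OIDs and two variant-specific pre-text
#'   tokens.
#' @param shared_token_fraction probability that a pre-text token is drawn
#'   from the shared boilerplate pool instead of the class pool (default
#'   0.3; raising it makes classes lexically confusable and the task
#'   harder).
#' @param confusable_groups list of integer vectors of class indices; the
#'   classes in a group share one pre/post-text pool and differ only in
#'   their OIDs (the cross-domain date-field failure mode).
#' @param oov_injection_rate fraction of records receiving globally unique
#'   novel tokens, so that wherever those records land after splitting,
#'   their tokens are out-of-vocabulary for the other side (default 0).
#' @param html_fraction fraction of pre-texts wrapped in HTML markup
#'   (default 0.15).
#' @param seed integer seed; corpora are byte-identical for equal configs.
#' @return A `synth_config`.
#' @export
synth_config <- function(n_classes = 10L, class_supports = "balanced",
                         balanced_support = 150L, tokens_per_class = 30L,
                         variants_per_class = 6L,
                         shared_token_fraction = 0.3,
                         confusable_groups = list(),
                         oov_injection_rate = 0, html_fraction = 0.15,
                         seed = 1L) {
  if (is.character(class_supports)) {
    class_supports <- switch(
      match.arg(class_supports, c("balanced", "figure4")),
      balanced = rep.int(as.integer(balanced_support), n_classes),
      figure4 = rep_len(c(10L, 25L, 50L, 100L, 200L), n_classes)
    )
  }
  class_supports <- as.integer(class_supports)
  if (length(class_supports) != n_classes) {
    stop("class_supports must have one entry per class (", n_classes, ")")
  }
  if (any(class_supports < 1L)) stop("all class supports must be >= 1")
  stopifnot(shared_token_fraction >= 0, shared_token_fraction <= 1,
            oov_injection_rate >= 0, oov_injection_rate <= 1,
            html_fraction >= 0, html_fraction <= 1, tokens_per_class >= 1,
            variants_per_class >= 1)
  for (grp in confusable_groups) {
    if (any(grp < 1L | grp > n_classes)) {
      stop("confusable group references an invalid class index: ",
           paste(grp, collapse = ","))
    }
  }
  structure(list(n_classes = as.integer(n_classes),
                 class_supports = class_supports,
                 tokens_per_class = as.integer(tokens_per_class),
                 variants_per_class = as.integer(variants_per_class),
                 shared_token_fraction = shared_token_fraction,
                 confusable_groups = confusable_groups,
                 oov_injection_rate = oov_injection_rate,
                 html_fraction = html_fraction, seed = as.integer(seed)),
            class = "synth_config")
}

title_case <- function(w) {
  paste0(toupper(substring(w, 1L, 1L)), substring(w, 2L))
}

#' Generate a labeled synthetic eCRF-metadata corpus
#'
#' @param config a [synth_config()].
#' @return A `crf_groundtruth`: `corpus` (a labeled [crf_corpus()]),
#'   `template` (generating class index per record) and the `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  nc <- config$n_classes
  with_seed(config$seed, {
    # --- class labels: SDTM-style names, unique ---
    combos <- expand.grid(d = lex_sdtm_domains, s = lex_sdtm_suffixes,
                          stringsAsFactors = FALSE)
    combos <- paste0(combos$d, combos$s)
    labels <- draw_distinct(combos, nc)

    # --- pre/post template pools; confusable groups share one pool ---
    pool_of <- seq_len(nc)
    for (grp in config$confusable_groups) pool_of[grp] <- grp[1L]
    nv <- config$variants_per_class
    class_words <- vector("list", nc)
    variant_words <- vector("list", nc)    # [[cl]][[v]]: phrasing jargon of one source form
    post_hint <- character(nc)
    used_words <- character()
    for (cl in seq_len(nc)) {
      if (pool_of[cl] != cl) {
        class_words[[cl]] <- class_words[[pool_of[cl]]]
        variant_words[[cl]] <- variant_words[[pool_of[cl]]]
        post_hint[cl] <- post_hint[pool_of[cl]]
        next
      }
      w <- draw_distinct(lex_topic_stems, config$tokens_per_class, used_words)
      used_words <- c(used_words, w)
      class_words[[cl]] <- w
      variant_words[[cl]] <- lapply(seq_len(nv), function(v) {
        vw <- draw_distinct(lex_topic_stems, 2L, used_words)
        used_words <<- c(used_words, vw)
        vw
      })
      post_hint[cl] <- sample(lex_format_hints, 1L)
    }

    # --- OIDs: single UPPER_SNAKE tokens, one set per source-form variant,
    # fragment combos unique across every class and variant ---
    form_oid <- matrix("", nc, nv)
    field_oid <- matrix("", nc, nv)
    seen_oid <- character()
    for (cl in seq_len(nc)) {
      for (v in seq_len(nv)) {
        repeat {
          fo <- paste(sample(lex_oid_fragments, 2L), collapse = "_")
          if (!fo %in% seen_oid) break
        }
        seen_oid <- c(seen_oid, fo)
        form_oid[cl, v] <- fo
        repeat {
          fi <- paste(sample(lex_oid_fragments, sample(2:4, 1L)), collapse = "_")
          if (!fi %in% seen_oid) break
        }
        seen_oid <- c(seen_oid, fi)
        field_oid[cl, v] <- fi
      }
    }

    # --- records ---
    total <- sum(config$class_supports)
    rows <- vector("list", total)
    template <- integer(total)
    r <- 0L
    novel_id <- 0L
    for (cl in seq_len(nc)) {
      for (j in seq_len(config$class_supports[cl])) {
        r <- r + 1L
        template[r] <- cl
        v <- sample.int(nv, 1L)
        npre <- sample(4:8, 1L)
        from_shared <- stats::runif(npre) < config$shared_token_fraction
        words <- ifelse(from_shared,
                        sample(lex_shared_words, npre, replace = TRUE),
                        sample(class_words[[cl]], npre, replace = TRUE))
        if (stats::runif(1) < 0.5) {
          words <- c(words, sample(variant_words[[cl]][[v]], 1L))
        }
        words[1L] <- title_case(words[1L])
        pre <- paste(words, collapse = " ")
        if (stats::runif(1) < config$oov_injection_rate) {
          novel_id <- novel_id + 1L
          pre <- paste(pre, sprintf("zqx%04d", novel_id))
        }
        if (stats::runif(1) < config$html_fraction) {
          tag <- sample(c("b", "i", "em", "span"), 1L)
          pre <- sprintf("<%s>%s</%s>", tag, pre, tag)
        }
        fid <- field_oid[cl, v]
        if (stats::runif(1) < 0.3) {
          fid <- paste0(fid, "_", sample(c("1", "2", "V2", "X"), 1L))
        }
        rows[[r]] <- data.frame(form_oid = form_oid[cl, v], field_oid = fid,
                                pre_text = pre, post_text = post_hint[cl],
                                label = labels[cl], stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, rows)
    ord <- sample.int(total)
    records <- records[ord, , drop = FALSE]
    rownames(records) <- NULL
    template <- template[ord]
    corpus <- crf_corpus(records,
                         source = sprintf("synthgen(seed=%d)", config$seed))
    structure(list(corpus = corpus, template = template, config = config),
              class = "crf_groundtruth")
  })
}

#' Summary statistics of a generated corpus
#'
#' @param gt a [generate_corpus()] result.
#' @return list: per-class `supports`, total `vocab_size`, `overlap` (pre-text
#'   token overlap matrix between classes, intersection over smaller set),
#'   `max_length` (longest concatenated token sequence).
#' @export
corpus_stats <- function(gt) {
  stopifnot(inherits(gt, "crf_groundtruth"))
  corpus <- normalize_corpus(gt$corpus)
  labs <- unique(corpus$label)
  supports <- c(table(corpus$label))[labs]
  token_sets <- lapply(labs, function(l) {
    unique(unlist(lapply(corpus$pre_text[corpus$label == l], tokenize)))
  })
  k <- length(labs)
  overlap <- matrix(1, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) {
      overlap[i, j] <- length(intersect(token_sets[[i]], token_sets[[j]])) /
        min(length(token_sets[[i]]), length(token_sets[[j]]))
    }
  }
  texts <- concatenate_fields(corpus)
  list(supports = supports,
       vocab_size = build_vocabulary(texts)$size,
       overlap = overlap,
       max_length = max(vapply(texts, function(t) length(tokenize(t)), integer(1))))
}

#' Write a generated corpus plus its ground-truth sidecar
#'
#' @param gt a `crf_groundtruth`.
#' @param csv_path corpus CSV path.
#' @param json_path sidecar path (defaults next to the CSV) recording the
#'   config and per-record generating template.
#' @export
write_groundtruth <- function(gt, csv_path,
                              json_path = sub("\\.csv$", "-truth.json", csv_path)) {
  write_corpus(gt$corpus, csv_path)
  cfg <- unclass(gt$config)
  jsonlite::write_json(list(config = cfg, template = gt$template),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
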