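# Maximum-entropy sequence tagger: per-token multinomial classification over
# lexical/context/auxiliary-stream features, beam-search decoded.

PAD_LEFT <- "<s>"
PAD_RIGHT <- "</s>"

#' Feature extraction for the base tagger
#'
#' Deterministic template expansion at one token position: the focus word,
#' context words in a window (default +/-2, boundary positions padded), one
#' feature per auxiliary stream per window slot, the previous predicted tag
#' and the previous-2-tag bigram, and a bias feature. Previous-tag features
#' come from the gold sequence during training and from the decoded prefix
#' during beam search.
#'
#' @param words lower-cased token surfaces of the sentence.
#' @param aux named list of per-token tag streams for the sentence.
#' @param pos 1-based token position.
#' @param prev_tags tags decoded (or gold) before `pos`.
#' @param window context half-width.
#' @return Character vector of feature names, namespaced by template.
#' @export
extract_features <- function(words, aux, pos, prev_tags, window = 2L) {
  n <- length(words)
  at <- function(v, i, lo = PAD_LEFT, hi = PAD_RIGHT) {
    if (i < 1L) lo else if (i > n) hi else v[i]
  }
  offs <- (-window):window
  otag <- ifelse(offs > 0, paste0("+", offs), as.character(offs))
  feats <- c("BIAS",
             vapply(seq_along(offs), function(i) {
               paste0("w", otag[i], "=", at(words, pos + offs[i]))
             }, character(1)))
  for (nm in names(aux)) {
    feats <- c(feats, vapply(seq_along(offs), function(i) {
      paste0("aux:", nm, ":", otag[i], "=", at(aux[[nm]], pos + offs[i]))
    }, character(1)))
  }
  p1 <- if (pos > 1L) prev_tags[pos - 1L] else PAD_LEFT
  p2 <- if (pos > 2L) prev_tags[pos - 2L] else PAD_LEFT
  c(feats, paste0("t-1=", p1), paste0("t-2t-1=", p2, "_", p1))
}

#' Train the maximum-entropy base tagger
#'
#' Fits an L2-regularized multinomial log-linear classifier over the features
#' of [extract_features()], with gold previous tags, across every token of
#' the training documents. Training is deterministic. The label inventory is
#' the set of tags observed in training; a configured class absent from the
#' training data simply never enters the inventory (a warning is emitted when
#' `classes` is supplied and not fully covered).
#'
#' @param docs list of `pheno_document`s with gold mentions.
#' @param window context half-width (default 2).
#' @param lambda L2 regularization strength (default 0.01).
#' @param maxit optimizer iteration cap.
#' @param aux_streams names of auxiliary streams to use; default all present
#'   in the first document.
#' @param classes optional entity-class inventory for coverage checking.
#' @return A `pheno_tagger` model.
#' @export
train_tagger <- function(docs, window = 2L, lambda = 0.01, maxit = 500,
                         aux_streams = NULL, classes = NULL) {
  if (!length(docs)) stop("no training documents", call. = FALSE)
  if (is.null(aux_streams)) aux_streams <- names(docs[[1]]$aux)
  feats <- list(); y <- character()
  for (doc in docs) {
    gold <- document_gold_bio(doc)
    for (s in seq_len(nrow(doc$sentences))) {
      words <- tolower(sentence_tokens(doc, s)$text)
      aux <- sentence_aux(doc, s)[aux_streams]
      tags <- gold[[s]]
      for (pos in seq_along(words)) {
        feats[[length(feats) + 1L]] <-
          extract_features(words, aux, pos, tags, window)
        y <- c(y, tags[pos])
      }
    }
  }
  if (!is.null(classes)) {
    missing <- setdiff(classes, tag_class(unique(y)))
    if (length(missing)) {
      warning("no training instances for class(es): ",
              paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  model <- fit_maxent(feats, y, lambda = lambda, maxit = maxit)
  structure(list(maxent = model, window = window, aux_streams = aux_streams),
            class = "pheno_tagger")
}

#' @export
print.pheno_tagger <- function(x, ...) {
  cat(sprintf("<pheno_tagger: %d label(s), %d feature(s), window +/-%d>\n",
              length(x$maxent$labels),
              if (is.null(x$maxent$W)) 0L else nrow(x$maxent$W), x$window))
  invisible(x)
}

# per-sentence scorer closure for beam/exhaustive decoding
tagger_scorer <- function(model, doc, s) {
  words <- tolower(sentence_tokens(doc, s)$text)
  aux <- sentence_aux(doc, s)[model$aux_streams]
  function(pos, prev_tags) {
    maxent_logprob(model$maxent,
                   extract_features(words, aux, pos, prev_tags, model$window))
  }
}

#' Beam-search decoding of one sentence
#'
#' Decodes the sentence with [beam_search()] over the tagger's per-position
#' log-probabilities and repairs the result to well-formed BIO.
#'
#' @param model a `pheno_tagger`.
#' @param doc a `pheno_document`.
#' @param s sentence index.
#' @param k beam width (default 3).
#' @return Character vector of BIO tags with attribute `score`.
#' @export
beam_decode <- function(model, doc, s, k = 3L) {
  n <- sum(doc$tokens$sentence == s)
  res <- beam_search(n, model$maxent$labels, tagger_scorer(model, doc, s), k)
  structure(repair_bio(as.character(res)), score = attr(res, "score"),
            source = "me_bs")
}

#' Exhaustive decoding of one sentence (test oracle)
#'
#' @inheritParams beam_decode
#' @param max_space refuse enumeration above this many sequences.
#' @return Character vector of BIO tags with attribute `score`.
#' @export
exhaustive_decode <- function(model, doc, s, max_space = 1e6) {
  n <- sum(doc$tokens$sentence == s)
  res <- exhaustive_search(n, model$maxent$labels, tagger_scorer(model, doc, s),
                           max_space)
  structure(repair_bio(as.character(res)), score = attr(res, "score"),
            source = "me_bs")
}

#' Tag a whole document with the base tagger
#'
#' @inheritParams beam_decode
#' @return List of per-sentence BIO tag vectors.
#' @export
tag_document_bio <- function(model, doc, k = 3L) {
  lapply(seq_len(nrow(doc$sentences)), function(s) {
    as.character(beam_decode(model, doc, s, k))
  })
}
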