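# Maximum-entropy hypothesis resolution: the labeler outputs become features
# of a second-stage maximum-entropy sequence model that re-labels every token
# (no ambiguity screening), decoded with beam search.

#' Feature extraction for the maximum-entropy resolver
#'
#' One feature per resolution-feature template at a position: the current
#' word, context words in the window, and each hypothesis stream's label at
#' every window slot (machine-learning tagger labels, rule-matching labels,
#' and one stream per per-class dictionary), plus previous predicted tags and
#' a bias term.
#'
#' @param words lower-cased token surfaces of the sentence.
#' @param hyps named list of labeler tag vectors for the sentence.
#' @param pos 1-based token position.
#' @param prev_tags tags before `pos` (gold during training, decoded prefix
#'   during beam search).
#' @param window context half-width.
#' @return Character vector of feature names.
#' @export
build_resolution_features <- function(words, hyps, pos, prev_tags,
                                      window = 2L) {
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
  for (nm in names(hyps)) {
    feats <- c(feats, vapply(seq_along(offs), function(i) {
      paste0("lab:", nm, ":", otag[i], "=", at(hyps[[nm]], pos + offs[i]))
    }, character(1)))
  }
  p1 <- if (pos > 1L) prev_tags[pos - 1L] else PAD_LEFT
  p2 <- if (pos > 2L) prev_tags[pos - 2L] else PAD_LEFT
  c(feats, paste0("t-1=", p1), paste0("t-2t-1=", p2, "_", p1))
}

# align a document's candidate sets to the model's source inventory,
# inserting all-O streams (with a warning) for missing sources
align_streams <- function(hyps, sources, n) {
  missing <- setdiff(sources, names(hyps))
  if (length(missing)) {
    warning("missing hypothesis stream(s) ", paste(missing, collapse = ", "),
            "; substituting all-O", call. = FALSE)
    for (nm in missing) hyps[[nm]] <- rep("O", n)
  }
  hyps[sources]
}

#' Train the maximum-entropy resolver
#'
#' Fits the second-stage maximum-entropy model over
#' [build_resolution_features()] with gold previous tags. The labeler outputs
#' supplied in `candsets` should be produced by cross-fitting within the
#' training partition when they come from a trained labeler (see
#' [cross_validate()]), so the resolver does not learn from optimistically
#' accurate label features.
#'
#' @param docs list of training `pheno_document`s.
#' @param candsets per-document list: `candsets[[d]][[s]]` is the named list
#'   of labeler tag vectors for sentence `s` of document `d`.
#' @param window context half-width.
#' @param lambda L2 regularization strength.
#' @param maxit optimizer iteration cap.
#' @return A `pheno_me_resolver` model.
#' @export
train_me_resolver <- function(docs, candsets, window = 2L, lambda = 0.01,
                              maxit = 500) {
  stopifnot(length(docs) == length(candsets))
  sources <- names(candsets[[1]][[1]])
  feats <- list(); y <- character()
  for (d in seq_along(docs)) {
    doc <- docs[[d]]
    gold <- document_gold_bio(doc)
    for (s in seq_len(nrow(doc$sentences))) {
      words <- tolower(sentence_tokens(doc, s)$text)
      hyps <- align_streams(candsets[[d]][[s]], sources, length(words))
      tags <- gold[[s]]
      for (pos in seq_along(words)) {
        feats[[length(feats) + 1L]] <-
          build_resolution_features(words, hyps, pos, tags, window)
        y <- c(y, tags[pos])
      }
    }
  }
  structure(list(maxent = fit_maxent(feats, y, lambda = lambda, maxit = maxit),
                 window = window, sources = sources),
            class = "pheno_me_resolver")
}

#' Resolve one document with the maximum-entropy resolver
#'
#' Re-labels every token by beam-search decoding over the resolution
#' features; no unambiguous/ambiguous screening is applied.
#'
#' @param model a `pheno_me_resolver`.
#' @param doc a `pheno_document`.
#' @param candset the document's candidate sets (list per sentence of named
#'   tag-vector lists).
#' @param k beam width (default 3).
#' @return List of per-sentence BIO tag vectors.
#' @export
resolve_me <- function(model, doc, candset, k = 3L) {
  lapply(seq_len(nrow(doc$sentences)), function(s) {
    words <- tolower(sentence_tokens(doc, s)$text)
    hyps <- align_streams(candset[[s]], model$sources, length(words))
    scorer <- function(pos, prev_tags) {
      maxent_logprob(model$maxent,
                     build_resolution_features(words, hyps, pos, prev_tags,
                                               model$window))
    }
    repair_bio(as.character(
      beam_search(length(words), model$maxent$labels, scorer, k)))
  })
}
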