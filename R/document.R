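#' Construct an annotated document
#'
#' A document bundles raw text with its sentence and token spans (0-based
#' half-open character offsets), gold-standard mentions, and optional named
#' auxiliary per-token tag streams (part-of-speech tags, species tags, or the
#' output of an externally trained tagger). Gold mentions may nest only as a
#' contained span inside a larger span (e.g. a gene mention inside a phenotype
#' mention); mentions crossing a sentence boundary are rejected.
#'
#' @param id document identifier.
#' @param text document text.
#' @param gold mention table (see [mentions()]); surfaces are validated
#'   against the text.
#' @param aux named list of character vectors, one tag per token.
#' @param tokenizer function mapping text to sentence/token spans; defaults to
#'   [segment_and_tokenize()]. Pluggable so other tokenizers can be used.
#' @return An object of class `pheno_document`.
#' @export
ner_document <- function(id, text, gold = NULL, aux = list(),
                         tokenizer = segment_and_tokenize) {
  tz <- tokenizer(text)
  if (is.null(gold)) gold <- empty_mentions()
  if (nrow(gold)) {
    slice <- substring(text, gold$start + 1L, gold$end)
    if (anyNA(gold$surface)) gold$surface[is.na(gold$surface)] <- slice[is.na(gold$surface)]
    bad <- which(gold$surface != slice)
    if (length(bad)) {
      stop("mention surface does not match text slice at [",
           paste0(gold$start[bad], ",", gold$end[bad], ")", collapse = "; "),
           ": ", paste(gold$surface[bad], collapse = "; "), call. = FALSE)
    }
    sidx <- mention_sentence(gold, tz$sentences)
    if (anyNA(sidx)) {
      bad <- which(is.na(sidx))
      stop("mention(s) cross a sentence boundary: ",
           paste(gold$surface[bad], collapse = "; "), call. = FALSE)
    }
    gold <- gold[order(gold$start, gold$end), , drop = FALSE]
    rownames(gold) <- NULL
  }
  n_tok <- nrow(tz$tokens)
  for (nm in names(aux)) {
    if (length(aux[[nm]]) != n_tok) {
      stop("aux stream '", nm, "' has ", length(aux[[nm]]),
           " tags for ", n_tok, " tokens", call. = FALSE)
    }
  }
  structure(list(id = id, text = text, sentences = tz$sentences,
                 tokens = tz$tokens, gold = gold, aux = aux),
            class = "pheno_document")
}

# sentence index containing each mention, NA when a mention crosses a boundary
mention_sentence <- function(m, sentences) {
  vapply(seq_len(nrow(m)), function(i) {
    hit <- which(sentences$start <= m$start[i] & sentences$end >= m$end[i])
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
}

#' @export
print.pheno_document <- function(x, ...) {
  cat(sprintf("<pheno_document '%s': %d sentence(s), %d token(s), %d gold mention(s)>\n",
              x$id, nrow(x$sentences), nrow(x$tokens), nrow(x$gold)))
  invisible(x)
}

# tokens of one sentence
sentence_tokens <- function(doc, s) {
  doc$tokens[doc$tokens$sentence == s, , drop = FALSE]
}

# aux streams restricted to one sentence
sentence_aux <- function(doc, s) {
  idx <- which(doc$tokens$sentence == s)
  lapply(doc$aux, function(a) a[idx])
}

#' Gold BIO tags of a document
#'
#' Encodes the document's gold mentions sentence by sentence with
#' [mentions_to_bio()] (nested mentions flatten to the outermost span).
#'
#' @param doc a `pheno_document`.
#' @return A list with one character vector of BIO tags per sentence.
#' @export
document_gold_bio <- function(doc) {
  sidx <- mention_sentence(doc$gold, doc$sentences)
  lapply(seq_len(nrow(doc$sentences)), function(s) {
    mentions_to_bio(sentence_tokens(doc, s),
                    doc$gold[which(sidx == s), , drop = FALSE])
  })
}

#' Decode per-sentence BIO tags of a document into mentions
#'
#' @param doc a `pheno_document`.
#' @param tag_list list of BIO tag vectors, one per sentence.
#' @return A mention table with document-level character offsets.
#' @export
document_bio_to_mentions <- function(doc, tag_list) {
  stopifnot(length(tag_list) == nrow(doc$sentences))
  out <- lapply(seq_along(tag_list), function(s) {
    bio_to_mentions(tag_list[[s]], sentence_tokens(doc, s), text = doc$text)
  })
  res <- do.call(rbind, c(list(empty_mentions()), out))
  rownames(res) <- NULL
  res
}

#' Export a document as CoNLL-style columns
#'
#' One row per token: token text, any auxiliary streams, and the gold BIO
#' tag; sentences are implicit in the `sentence` column.
#'
#' @param doc a `pheno_document`.
#' @return A data.frame.
#' @export
document_to_conll <- function(doc) {
  gold <- unlist(document_gold_bio(doc))
  out <- data.frame(sentence = doc$tokens$sentence, token = doc$tokens$text,
                    stringsAsFactors = FALSE)
  for (nm in names(doc$aux)) out[[nm]] <- doc$aux[[nm]]
  out$gold <- gold
  out
}
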