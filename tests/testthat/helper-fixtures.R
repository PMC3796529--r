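# In-code fixtures and independent oracles shared across test files.

# one-sentence document from explicit tokens joined by single spaces;
# mention spans given as token index ranges (1-based inclusive)
tok_doc <- function(tokens, spans = list(), id = "t") {
  text <- paste(tokens, collapse = " ")
  starts <- c(0L, cumsum(nchar(tokens) + 1L))[seq_along(tokens)]
  ends <- starts + nchar(tokens)
  m <- empty_m()
  for (sp in spans) {
    m <- rbind(m, mentions(sp$class, starts[sp$from], ends[sp$to], text = text))
  }
  ner_document(id, text, gold = m)
}

empty_m <- function() mentions()

# token index ranges -> BIO tags, written directly (independent of package
# encoders)
tags_from_spans <- function(n, spans) {
  tags <- rep("O", n)
  for (sp in spans) {
    tags[sp$from] <- paste0("B-", sp$class)
    if (sp$to > sp$from) tags[(sp$from + 1):sp$to] <- paste0("I-", sp$class)
  }
  tags
}

# brute-force dictionary-matching oracle: enumerate every matching n-gram,
# then greedily keep leftmost-longest non-overlapping matches
oracle_dict <- function(token_text, lexicon) {
  n <- length(token_text)
  norm <- phenoner:::normalize_term(token_text)
  hits <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (paste(norm[i:j], collapse = " ") %in% lexicon$entries) {
        hits[[length(hits) + 1L]] <- c(i, j)
      }
    }
  }
  tags <- rep("O", n)
  if (length(hits)) {
    hits <- hits[order(vapply(hits, `[[`, 0, 1),
                       -vapply(hits, function(h) h[2] - h[1], 0))]
    taken <- rep(FALSE, n)
    for (h in hits) {
      if (any(taken[h[1]:h[2]])) next
      taken[h[1]:h[2]] <- TRUE
      tags[h[1]] <- paste0("B-", lexicon$entity_class)
      if (h[2] > h[1]) tags[(h[1] + 1):h[2]] <- paste0("I-", lexicon$entity_class)
    }
  }
  tags
}

# random well-formed candidate set over n tokens: each labeler proposes a few
# random non-overlapping spans
random_candidate_set <- function(n, n_labelers = 4, classes = c("PH", "GG", "DS")) {
  hyps <- lapply(seq_len(n_labelers), function(l) {
    tags <- rep("O", n)
    pos <- 1L
    while (pos <= n) {
      if (stats::runif(1) < 0.3) {
        len <- min(sample(1:3, 1), n - pos + 1L)
        cl <- sample(classes, 1)
        tags[pos] <- paste0("B-", cl)
        if (len > 1) tags[(pos + 1):(pos + len - 1)] <- paste0("I-", cl)
        pos <- pos + len + 1L
      } else {
        pos <- pos + 1L
      }
    }
    tags
  })
  names(hyps) <- paste0("lab", seq_len(n_labelers))
  hyps
}

# random maximum-entropy scorer over a small label set: per-position scores
# depend on the two previous tags, like the tagger's decoding problem
random_scorer <- function(n, labels) {
  L <- length(labels)
  W <- array(stats::rnorm(n * (L + 1)^2 * L), c(n, L + 1, L + 1, L))
  function(pos, prev_tags) {
    p1 <- if (pos > 1) match(prev_tags[pos - 1], labels) else L + 1L
    p2 <- if (pos > 2) match(prev_tags[pos - 2], labels) else L + 1L
    s <- W[pos, p1, p2, ]
    stats::setNames(s - max(s) - log(sum(exp(s - max(s)))), labels)
  }
}
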