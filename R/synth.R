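# Seeded synthetic corpora: template token streams with embedded multi-token
# mentions, matching lexicons, and controlled-noise labeler outputs. The
# generator emulates the structural properties of a multi-class annotated
# abstract collection -- six entity classes, phenotype mentions averaging
# about three tokens while other classes run shorter, genes embeddable
# inside phenotypes -- without imitating natural prose: the algorithms
# operate on tokens and tags, and synthetic token streams keep expected
# outputs enumerable.

#' Generate a synthetic annotated corpus with matching lexicons
#'
#' Documents are sequences of template sentences: filler tokens interleaved
#' with mentions drawn from per-class term vocabularies (distinct token
#' pools per class, so dictionary matches are exact by construction).
#' Mention lengths are `1 + Poisson(mean - 1)`. Optionally a fraction of
#' mention slots draws from a vocabulary shared between two classes; the
#' gold class of such a mention is decided by a cue token placed directly
#' after it, producing the class-context-dependent ambiguity that separates
#' context-aware resolution from a fixed priority list. With positive
#' `nesting_prob`, phenotype mentions of length three or more may carry an
#' embedded single-token gene mention. Lexicons contain a configurable
#' fraction of each class's vocabulary so dictionary recall gaps can be
#' created. Fully reproducible from `seed`.
#'
#' @param n_docs number of documents.
#' @param sentences_per_doc sentences per document.
#' @param seed integer seed (mandatory).
#' @param classes entity classes to generate.
#' @param mention_rate named expected mentions per sentence per class.
#' @param mention_len_mean named mean mention length (tokens) per class.
#' @param nesting_prob probability that an eligible PH mention embeds a
#'   single-token GG gold mention.
#' @param vocab_terms named vocabulary sizes (terms per class).
#' @param filler_vocab number of distinct filler tokens.
#' @param lexicon_coverage fraction of each class vocabulary present in its
#'   lexicon.
#' @param ambiguous optional list describing shared-vocabulary ambiguity:
#'   `classes` (two class codes, default `c("PH", "DS")`), `n_terms`,
#'   `rate` (expected ambiguous mentions per sentence), `cue` (logical: emit
#'   the class cue token after each ambiguous mention, default `TRUE`).
#' @return A list with `docs` (list of `pheno_document`s), `lexicons`
#'   (named list of `pheno_lexicon`, one per class), `vocab` (the term
#'   strings per class) and `seed`.
#' @export
gen_corpus <- function(n_docs = 20L, sentences_per_doc = 4L, seed,
                       classes = entity_classes(),
                       mention_rate = c(PH = 0.8, GG = 0.8, DS = 0.6,
                                        OR = 0.4, AN = 0.3, CD = 0.3),
                       mention_len_mean = c(PH = 3, GG = 1.7, DS = 1.9,
                                            OR = 1.8, AN = 2.2, CD = 1.4),
                       nesting_prob = 0, vocab_terms = NULL,
                       filler_vocab = 150L, lexicon_coverage = 1,
                       ambiguous = NULL) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  mention_rate <- mention_rate[names(mention_rate) %in% classes]
  mention_len_mean <- mention_len_mean[names(mention_len_mean) %in% classes]
  if (is.null(vocab_terms)) {
    vocab_terms <- stats::setNames(rep(30L, length(classes)), classes)
  }
  exp_tokens <- sum(mention_rate * mention_len_mean[names(mention_rate)])
  if (!is.null(ambiguous)) {
    ambiguous <- utils::modifyList(
      list(classes = c("PH", "DS"), n_terms = 15L, rate = 0.5, cue = TRUE,
           len_mean = 2), ambiguous)
    exp_tokens <- exp_tokens + ambiguous$rate * (ambiguous$len_mean + 1)
  }
  if (exp_tokens > 40) {
    stop("mention densities exceed sentence capacity (expected ",
         round(exp_tokens, 1), " mention tokens per sentence)", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  gen_terms <- function(prefix, n_terms, len_mean, pool_size = 26L) {
    pool <- paste0(prefix, "w", seq_len(max(pool_size, 10L)))
    terms <- character(0)
    while (length(terms) < n_terms) {
      len <- 1L + stats::rpois(1L, max(0, len_mean - 1))
      len <- min(len, 6L)
      terms <- unique(c(terms, paste(sample(pool, len, replace = TRUE),
                                     collapse = " ")))
    }
    terms
  }
  len_mean_of <- function(cl) {
    if (cl %in% names(mention_len_mean)) mention_len_mean[[cl]] else 1.7
  }
  vocab <- stats::setNames(lapply(classes, function(cl) {
    gen_terms(tolower(cl), vocab_terms[[cl]], len_mean_of(cl))
  }), classes)
  amb_terms <- character(0)
  if (!is.null(ambiguous)) {
    amb_terms <- gen_terms("amb", ambiguous$n_terms, ambiguous$len_mean)
  }
  fillers <- paste0("f", seq_len(filler_vocab))
  gg_short <- if ("GG" %in% classes) {
    vocab$GG[lengths(strsplit(vocab$GG, " ", fixed = TRUE)) == 1L]
  } else {
    character(0)
  }

  make_sentence <- function() {
    slots <- list()     # each: list(tokens, class or NA, cue, nested_gg)
    for (cl in names(mention_rate)) {
      for (j in seq_len(stats::rpois(1L, mention_rate[[cl]]))) {
        term <- sample(vocab[[cl]], 1L)
        toks <- strsplit(term, " ", fixed = TRUE)[[1]]
        nested <- NA_integer_
        if (cl == "PH" && length(toks) >= 3L && length(gg_short) &&
            stats::runif(1L) < nesting_prob) {
          nested <- sample(2:(length(toks) - 1L), 1L)
          toks[nested] <- sample(gg_short, 1L)
        }
        slots[[length(slots) + 1L]] <-
          list(tokens = toks, class = cl, cue = NULL, nested = nested)
      }
    }
    if (!is.null(ambiguous)) {
      for (j in seq_len(stats::rpois(1L, ambiguous$rate))) {
        cl <- sample(ambiguous$classes, 1L)
        slots[[length(slots) + 1L]] <- list(
          tokens = strsplit(sample(amb_terms, 1L), " ", fixed = TRUE)[[1]],
          class = cl,
          cue = if (isTRUE(ambiguous$cue)) paste0("cue", tolower(cl)),
          nested = NA_integer_)
      }
    }
    if (length(slots)) slots <- slots[sample.int(length(slots))]
    tokens <- sample(fillers, sample(2:4, 1L), replace = TRUE)
    ments <- list()     # list(class, from, to) token indices
    for (sl in slots) {
      from <- length(tokens) + 1L
      tokens <- c(tokens, sl$tokens)
      ments[[length(ments) + 1L]] <-
        list(class = sl$class, from = from, to = length(tokens))
      if (!is.na(sl$nested)) {
        ments[[length(ments) + 1L]] <-
          list(class = "GG", from = from + sl$nested - 1L,
               to = from + sl$nested - 1L)
      }
      if (!is.null(sl$cue)) tokens <- c(tokens, sl$cue)
      tokens <- c(tokens, sample(fillers, sample(1:3, 1L), replace = TRUE))
    }
    list(tokens = c(tokens, "."), mentions = ments)
  }

  docs <- lapply(seq_len(n_docs), function(d) {
    text_parts <- character(0)
    gold <- empty_mentions()
    offset <- 0L
    for (s in seq_len(sentences_per_doc)) {
      sen <- make_sentence()
      starts <- offset + c(0L, cumsum(nchar(sen$tokens) + 1L))[seq_along(sen$tokens)]
      ends <- starts + nchar(sen$tokens)
      for (m in sen$mentions) {
        gold <- rbind(gold, mentions(m$class, starts[m$from], ends[m$to]))
      }
      text_parts <- c(text_parts, paste(sen$tokens, collapse = " "))
      offset <- offset + sum(nchar(sen$tokens)) + length(sen$tokens)
    }
    ner_document(sprintf("synth%03d", d), paste(text_parts, collapse = " "),
                 gold = mentions(gold$class, gold$start, gold$end,
                                 text = paste(text_parts, collapse = " ")))
  })

  lexicons <- stats::setNames(lapply(classes, function(cl) {
    terms <- vocab[[cl]]
    n_keep <- max(1L, round(lexicon_coverage * length(terms)))
    terms <- sample(terms, n_keep)
    if (!is.null(ambiguous) && cl %in% ambiguous$classes) {
      terms <- c(terms, amb_terms)
    }
    make_lexicon(terms, cl, source = paste0("synth_", cl))
  }), classes)

  list(docs = docs, lexicons = lexicons, vocab = vocab,
       ambiguous_terms = amb_terms, seed = seed)
}

#' Generate controlled-noise labeler outputs
#'
#' Derives candidate hypothesis streams from the gold annotation of each
#' document by applying per-labeler noise: recall loss (mentions dropped at
#' a given rate), class confusion (a mention's class rewritten according to
#' a per-class probability table, e.g. phenotype/disease confusion), and
#' boundary jitter (one span edge moved by one token where that does not
#' collide with another mention). The result is re-encoded as BIO per
#' sentence, giving labelers that disagree at controllable rates.
#'
#' @param docs list of `pheno_document`s.
#' @param noise_spec named list, one entry per labeler, each a list with any
#'   of `drop` (rate), `jitter` (rate), `confusion` (named list:
#'   `confusion$PH = c(DS = 0.3)` sends PH to DS with probability 0.3) and
#'   `emit_classes` (restrict the labeler's output to these classes).
#' @param seed integer seed.
#' @return Per-document candidate sets: `out[[d]][[sentence]]` is a named
#'   list of tag vectors, one per labeler.
#' @export
gen_labeler_outputs <- function(docs, noise_spec, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  defaults <- list(drop = 0, jitter = 0, confusion = NULL, emit_classes = NULL)
  lapply(docs, function(doc) {
    n_sent <- nrow(doc$sentences)
    streams <- lapply(names(noise_spec), function(nm) {
      sp <- utils::modifyList(defaults, noise_spec[[nm]])
      m <- doc$gold
      if (nrow(m) && sp$drop > 0) {
        m <- m[stats::runif(nrow(m)) >= sp$drop, , drop = FALSE]
      }
      if (nrow(m) && !is.null(sp$confusion)) {
        for (i in seq_len(nrow(m))) {
          conf <- sp$confusion[[m$class[i]]]
          if (is.null(conf)) next
          u <- stats::runif(1L)
          cum <- cumsum(conf)
          hit <- which(u < cum)
          if (length(hit)) m$class[i] <- names(conf)[hit[1]]
        }
      }
      if (nrow(m) && sp$jitter > 0) {
        tok <- doc$tokens
        for (i in seq_len(nrow(m))) {
          if (stats::runif(1L) >= sp$jitter) next
          idx <- which(tok$start < m$end[i] & tok$end > m$start[i])
          s_tok <- min(idx); e_tok <- max(idx)
          ops <- list()
          if (s_tok > 1L && tok$sentence[s_tok - 1L] == tok$sentence[s_tok]) {
            ops <- c(ops, list(c(tok$start[s_tok - 1L], m$end[i])))
          }
          if (e_tok < nrow(tok) &&
              tok$sentence[e_tok + 1L] == tok$sentence[e_tok]) {
            ops <- c(ops, list(c(m$start[i], tok$end[e_tok + 1L])))
          }
          if (length(idx) > 1L) {
            ops <- c(ops, list(c(tok$start[s_tok + 1L], m$end[i])),
                     list(c(m$start[i], tok$end[e_tok - 1L])))
          }
          if (!length(ops)) next
          new <- ops[[sample.int(length(ops), 1L)]]
          other <- m[-i, , drop = FALSE]
          crash <- any(other$start < new[2] & other$end > new[1] &
                         !(other$start >= new[1] & other$end <= new[2]) &
                         !(other$start <= new[1] & other$end >= new[2]))
          if (!crash) { m$start[i] <- new[1]; m$end[i] <- new[2] }
        }
        m$surface <- substring(doc$text, m$start + 1L, m$end)
      }
      if (!is.null(sp$emit_classes)) {
        m <- m[m$class %in% sp$emit_classes, , drop = FALSE]
      }
      sidx <- mention_sentence(m, doc$sentences)
      lapply(seq_len(n_sent), function(s) {
        mentions_to_bio(sentence_tokens(doc, s),
                        m[which(sidx == s), , drop = FALSE])
      })
    })
    names(streams) <- names(noise_spec)
    lapply(seq_len(n_sent), function(s) lapply(streams, `[[`, s))
  })
}
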