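# Learn-to-rank hypothesis resolution: unambiguous tokens keep the agreed
# label; each ambiguous segment becomes a ranking query whose candidates (one
# tag assignment per labeler) are scored by a pairwise-trained linear ranker,
# and the top candidate's tags are emitted.

# summary class of a candidate tag assignment: the highest-priority entity
# class present, or "O" for an all-O assignment
summary_class <- function(tags, priority) {
  cls <- setdiff(unique(tag_class(tags)), "O")
  if (!length(cls)) return("O")
  cls[which.min(priority_rank(cls, priority))]
}

# 1-based index of the first entity token in a tag assignment (Inf if none)
first_entity_pos <- function(tags) {
  i <- which(tags != "O")
  if (length(i)) i[1] else Inf
}

#' Build ranked candidate lists for learn-to-rank training
#'
#' For each ambiguous segment (one query), each labeler's tag assignment over
#' the segment is a candidate, ranked against the gold annotation by three
#' heuristic rules: candidates whose proposed entity spans all agree exactly
#' (class and extent) with gold spans -- including a tag assignment identical
#' to the gold labels -- receive the highest rank; candidates whose entity
#' tokens partially overlap the gold entity tokens receive the second rank;
#' candidates with no overlap receive the lowest rank. Within the first two
#' ranks, candidates whose match starts further to the left rank higher
#' (processing is left to right); residual ties are broken by source name.
#'
#' @param hyps named list of labeler tag vectors for one sentence.
#' @param gold_tags gold BIO tags for the sentence.
#' @param report ambiguity report from [detect_ambiguity()]; recomputed when
#'   omitted.
#' @return A data.frame with one row per (query, candidate): columns `query`,
#'   `seg_start`, `seg_end`, `source`, `rank_group` (1 exact, 2 partial,
#'   3 none), `rank` (total order within the query, 1 best) and `tags`
#'   (list-column of segment tag assignments). Queries with no candidates are
#'   dropped with a warning.
#' @export
build_rank_lists <- function(hyps, gold_tags, report = NULL) {
  check_candidate_set(hyps)
  if (is.null(report)) report <- detect_ambiguity(hyps)
  out <- list()
  for (q in seq_len(nrow(report$segments))) {
    seg <- report$segments$start[q]:report$segments$end[q]
    gseg <- repair_bio(gold_tags[seg])
    srcs <- sort_c(names(hyps))
    if (!length(srcs)) {
      warning("query ", q, " has no candidates; dropped", call. = FALSE)
      next
    }
    cand <- lapply(srcs, function(nm) repair_bio(hyps[[nm]][seg]))
    gspan <- tag_spans(gseg)
    gkey <- paste(gspan$class, gspan$s, gspan$e)
    grp <- vapply(cand, function(tg) {
      cs <- tag_spans(tg)
      exact <- identical(tg, gseg) ||
        (nrow(cs) > 0L && all(paste(cs$class, cs$s, cs$e) %in% gkey))
      if (exact) {
        1L
      } else if (any(tg != "O" & gseg != "O")) {
        2L
      } else {
        3L
      }
    }, integer(1))
    pos <- vapply(cand, first_entity_pos, numeric(1))
    ord <- order(grp, ifelse(grp <= 2L, pos, 0), srcs)
    rk <- integer(length(ord)); rk[ord] <- seq_along(ord)
    out[[length(out) + 1L]] <- data.frame(
      query = q, seg_start = report$segments$start[q],
      seg_end = report$segments$end[q], source = srcs, rank_group = grp,
      rank = rk, tags = I(cand), stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(query = integer(), seg_start = integer(),
                      seg_end = integer(), source = character(),
                      rank_group = integer(), rank = integer(),
                      tags = I(list()), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# feature vector (character set) for one candidate in one segment; the
# candidate's summary class is crossed with segment/context words and with
# every labeler's summary class so a linear ranker can prefer a class in a
# given lexical context
ltr_candidate_features <- function(words, hyps, seg_start, seg_end, cand_tags,
                                   source, priority, window = 2L) {
  n <- length(words)
  cl <- summary_class(cand_tags, priority)
  ctx <- unique(words[max(1L, seg_start - window):min(n, seg_end + window)])
  lab <- vapply(hyps, function(h) {
    summary_class(h[seg_start:seg_end], priority)
  }, character(1))
  votes <- sum(lab == cl)
  c(paste0("cls=", cl),
    paste0("cls=", cl, "|src=", source),
    paste0("cls=", cl, "|w=", ctx),
    paste0("cls=", cl, "|lab:", names(lab), "=", lab),
    paste0("cls=", cl, "|votes=", votes))
}

#' Train the learn-to-rank resolver
#'
#' Pairwise large-margin ranking by the classic reduction to a binary linear
#' SVM on feature-difference vectors: for every query and every candidate
#' pair where `a` outranks `b` (by rank group, then the left-position rule),
#' the constraint `score(a) > score(b)` becomes the training pair
#' `(f(a) - f(b), +1)` / `(f(b) - f(a), -1)`. The quadratic program is solved
#' by a linear-kernel C-classification SVM with fixed cost; the learned
#' weight vector scores candidates at inference.
#'
#' @param docs list of training `pheno_document`s.
#' @param candsets per-document candidate sets (as in [train_me_resolver()]).
#' @param priority priority order used for candidate summary classes.
#' @param window context half-width for candidate features.
#' @param cost SVM cost parameter C.
#' @return A `pheno_ltr_resolver` model.
#' @export
train_ltr <- function(docs, candsets, priority = default_priority(),
                      window = 2L, cost = 1) {
  stopifnot(length(docs) == length(candsets))
  sources <- names(candsets[[1]][[1]])
  feats_a <- list(); feats_b <- list()
  for (d in seq_along(docs)) {
    doc <- docs[[d]]
    gold <- document_gold_bio(doc)
    for (s in seq_len(nrow(doc$sentences))) {
      words <- tolower(sentence_tokens(doc, s)$text)
      hyps <- align_streams(candsets[[d]][[s]], sources, length(words))
      rl <- build_rank_lists(hyps, gold[[s]])
      for (q in unique(rl$query)) {
        rq <- rl[rl$query == q, , drop = FALSE]
        fq <- lapply(seq_len(nrow(rq)), function(i) {
          ltr_candidate_features(words, hyps, rq$seg_start[i], rq$seg_end[i],
                                 rq$tags[[i]], rq$source[i], priority, window)
        })
        # pairs ordered by rank group then left position (not the residual
        # source tie-break, which carries no signal)
        key <- rq$rank_group + 1e-3 * pmin(
          vapply(rq$tags, first_entity_pos, numeric(1)), 999)
        for (i in seq_len(nrow(rq))) {
          for (j in seq_len(nrow(rq))) {
            if (key[i] < key[j] && !identical(fq[[i]], fq[[j]])) {
              feats_a[[length(feats_a) + 1L]] <- fq[[i]]
              feats_b[[length(feats_b) + 1L]] <- fq[[j]]
            }
          }
        }
      }
    }
  }
  model <- structure(list(w = NULL, feat_index = NULL, priority = priority,
                          window = window, sources = sources, cost = cost),
                     class = "pheno_ltr_resolver")
  if (!length(feats_a)) {
    warning("no ranking pairs in training data; LTR model has zero weights",
            call. = FALSE)
    return(model)
  }
  feat_names <- sort_c(unique(unlist(c(feats_a, feats_b), use.names = FALSE)))
  fi <- stats::setNames(seq_along(feat_names), feat_names)
  vec <- function(f) {
    v <- numeric(length(fi))
    v[fi[f]] <- 1
    v
  }
  D <- t(vapply(seq_along(feats_a),
                function(i) vec(feats_a[[i]]) - vec(feats_b[[i]]),
                numeric(length(fi))))
  X <- rbind(D, -D)
  yy <- factor(c(rep("pos", nrow(D)), rep("neg", nrow(D))),
               levels = c("neg", "pos"))
  sv <- e1071::svm(x = X, y = yy, kernel = "linear", cost = cost,
                   scale = FALSE, type = "C-classification")
  w <- as.numeric(t(sv$coefs) %*% sv$SV)
  if (mean(D %*% w) < 0) w <- -w       # orient: higher rank => higher score
  model$w <- stats::setNames(w, feat_names)
  model$feat_index <- fi
  model
}

#' @export
print.pheno_ltr_resolver <- function(x, ...) {
  cat(sprintf("<pheno_ltr_resolver: %d feature(s), cost %g>\n",
              length(x$w), x$cost))
  invisible(x)
}

#' Resolve one document with the learn-to-rank resolver
#'
#' Unambiguous tokens are fixed to the agreed labels with no further
#' processing; in each ambiguous segment every labeler's tag assignment is
#' scored by the learned linear function and the top-scoring candidate's
#' tags are emitted (ties broken by source name). Features unseen at
#' training time are ignored.
#'
#' @param model a `pheno_ltr_resolver`.
#' @param doc a `pheno_document`.
#' @param candset the document's candidate sets.
#' @return List of per-sentence BIO tag vectors.
#' @export
resolve_ltr <- function(model, doc, candset) {
  lapply(seq_len(nrow(doc$sentences)), function(s) {
    words <- tolower(sentence_tokens(doc, s)$text)
    hyps <- align_streams(candset[[s]], model$sources, length(words))
    rep_ <- detect_ambiguity(hyps)
    tags <- rep_$agreed
    for (q in seq_len(nrow(rep_$segments))) {
      a <- rep_$segments$start[q]; b <- rep_$segments$end[q]
      srcs <- sort_c(names(hyps))
      cand <- lapply(srcs, function(nm) repair_bio(hyps[[nm]][a:b]))
      scores <- vapply(seq_along(cand), function(i) {
        f <- ltr_candidate_features(words, hyps, a, b, cand[[i]], srcs[i],
                                    model$priority, model$window)
        if (is.null(model$w)) 0 else sum(model$w[intersect(f, names(model$w))])
      }, numeric(1))
      tags[a:b] <- cand[[which.max(scores)]]
    }
    repair_bio(tags)
  })
}
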