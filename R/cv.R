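#' k-fold cross-validation of a configured system
#'
#' Documents (abstracts) are the fold unit, so no abstract contributes to
#' both training and testing. Documents are partitioned into `k` near-equal
#' folds with a seeded shuffle; for each fold the system is trained on the
#' other folds and tags the held-out documents. TP/FP/FN counts are pooled
#' over all folds before computing precision/recall/F, i.e. results are
#' collected from every testing partition and scored against the reference
#' standard as one set.
#'
#' @param docs list of `pheno_document`s (at least `k`).
#' @param config a `pheno_config`.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold shuffle.
#' @param mode matching mode, `"partial"` (default) or `"exact"`.
#' @return A `pheno_cv` object: fold assignment, per-document outputs
#'   (predicted and gold mentions), pooled counts, per-class and
#'   micro-averaged PRF.
#' @export
cross_validate <- function(docs, config, k = 10L, seed = 1L,
                           mode = c("partial", "exact")) {
  mode <- match.arg(mode)
  n <- length(docs)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (n < k) {
    stop("corpus has ", n, " documents, fewer than k = ", k, call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  per_doc <- vector("list", n)
  for (f in seq_len(k)) {
    system <- train_system(docs[fold != f], config)
    for (i in which(fold == f)) {
      res <- tag_document(system, docs[[i]])
      per_doc[[i]] <- list(id = docs[[i]]$id, fold = f,
                           gold = docs[[i]]$gold, pred = res$mentions,
                           tags = res$tags)
    }
  }
  classes <- sort_c(unique(unlist(lapply(per_doc, function(x) {
    c(x$gold$class, x$pred$class)
  }))))
  counts <- Reduce(function(acc, x) {
    cc <- match_mentions(x$gold, x$pred, mode, classes)
    acc$TP <- acc$TP + cc$TP; acc$FP <- acc$FP + cc$FP; acc$FN <- acc$FN + cc$FN
    acc
  }, per_doc,
  data.frame(class = classes, TP = 0L, FP = 0L, FN = 0L,
             stringsAsFactors = FALSE))
  structure(list(fold = fold, per_doc = per_doc, counts = counts,
                 prf = compute_prf(counts), micro = micro_average(counts),
                 mode = mode, seed = seed, k = k, config = config),
            class = "pheno_cv")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' @export
print.pheno_cv <- function(x, ...) {
  cat(sprintf("<pheno_cv: %d-fold, %s matching, micro-F %.1f>\n", x$k,
              x$mode, 100 * x$micro$f1))
  print(cbind(x$counts, round(100 * x$prf[, c("precision", "recall", "f1")], 1)))
  invisible(x)
}

#' Per-sentence evaluation units of a cross-validation run
#'
#' Splits each document's gold and predicted mentions by sentence, producing
#' the aligned per-sentence outputs consumed by [approx_randomization()].
#'
#' @param cv a `pheno_cv`.
#' @param docs the document list the run was computed on (same order).
#' @return A list with parallel lists `gold` and `pred`, one mention table
#'   per sentence over all documents.
#' @export
cv_sentence_outputs <- function(cv, docs) {
  gold <- list(); pred <- list()
  for (i in seq_along(docs)) {
    doc <- docs[[i]]
    gs <- mention_sentence(cv$per_doc[[i]]$gold, doc$sentences)
    ps <- mention_sentence(cv$per_doc[[i]]$pred, doc$sentences)
    for (s in seq_len(nrow(doc$sentences))) {
      gold[[length(gold) + 1L]] <-
        cv$per_doc[[i]]$gold[which(gs == s), , drop = FALSE]
      pred[[length(pred) + 1L]] <-
        cv$per_doc[[i]]$pred[which(ps == s), , drop = FALSE]
    }
  }
  list(gold = gold, pred = pred)
}

#' Evaluate performance on unique mentions only
#'
#' A test mention is unique when its normalized surface/class pair never
#' occurs as a gold mention in the training partition of its fold. Gold is
#' restricted to unique mentions; predictions are restricted to those
#' overlapping the position of at least one unique gold mention, so
#' predictions answering non-unique mentions are not penalized. The unique
#' rate is the percentage of gold mentions that are unique.
#'
#' @param cv a `pheno_cv`.
#' @param docs the document list the run was computed on.
#' @param mode matching mode; defaults to the run's mode.
#' @return A list with `counts`, `prf`, `micro` (restricted evaluation) and
#'   `unique_rate` (per class, percent).
#' @export
unique_mention_eval <- function(cv, docs, mode = cv$mode) {
  n <- length(docs)
  key <- function(m) paste(normalize_term(m$surface), m$class, sep = "\r")
  fold_train_keys <- lapply(seq_len(cv$k), function(f) {
    unique(unlist(lapply(which(cv$fold != f), function(i) {
      key(docs[[i]]$gold)
    })))
  })
  classes <- sort_c(unique(unlist(lapply(cv$per_doc, function(x) {
    c(x$gold$class, x$pred$class)
  }))))
  counts <- data.frame(class = classes, TP = 0L, FP = 0L, FN = 0L,
                       stringsAsFactors = FALSE)
  tot_gold <- stats::setNames(rep(0L, length(classes)), classes)
  uni_gold <- tot_gold
  for (i in seq_len(n)) {
    g <- cv$per_doc[[i]]$gold
    p <- cv$per_doc[[i]]$pred
    uniq <- !(key(g) %in% fold_train_keys[[cv$fold[i]]])
    tg <- table(factor(g$class, classes))
    ug <- table(factor(g$class[uniq], classes))
    tot_gold <- tot_gold + as.integer(tg)
    uni_gold <- uni_gold + as.integer(ug)
    gu <- g[uniq, , drop = FALSE]
    keep_p <- vapply(seq_len(nrow(p)), function(j) {
      any(gu$start < p$end[j] & gu$end > p$start[j])
    }, logical(1))
    cc <- match_mentions(gu, p[keep_p, , drop = FALSE], mode, classes)
    counts$TP <- counts$TP + cc$TP
    counts$FP <- counts$FP + cc$FP
    counts$FN <- counts$FN + cc$FN
  }
  list(counts = counts, prf = compute_prf(counts),
       micro = micro_average(counts),
       unique_rate = ifelse(tot_gold > 0, 100 * uni_gold / tot_gold, NA_real_))
}
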