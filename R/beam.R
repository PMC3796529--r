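#' Beam-search decoding over a per-position scorer
#'
#' Breadth-first decoding that keeps the `k` highest-scoring tag prefixes at
#' each position; the score of a sequence is the sum of per-position
#' log-probabilities supplied by `logprob_fn`, which receives the position
#' and the prefix decoded so far (so previous-tag features are available).
#' Complexity is linear in sentence length times labels times `k`. Ties are
#' broken deterministically: equal-scoring prefixes are ordered by the label
#' order of the newly appended tag, then by the order of beam insertion; the
#' final winner among equal-scoring complete sequences is the
#' lexicographically smallest tag sequence (in `labels` order).
#'
#' @param n number of positions.
#' @param labels label inventory, in tie-break order.
#' @param logprob_fn `function(position, prev_tags)` returning a named vector
#'   of log-probabilities over `labels`.
#' @param k beam width, a positive integer.
#' @return Character vector of `n` tags with attribute `score` (total log
#'   probability).
#' @export
beam_search <- function(n, labels, logprob_fn, k = 3L) {
  stopifnot(k >= 1L)
  if (n == 0L) return(structure(character(), score = 0))
  items <- list(list(tags = character(), score = 0))
  for (pos in seq_len(n)) {
    cand_tags <- list(); cand_score <- numeric(); cand_lab <- integer()
    cand_parent <- integer()
    for (pi in seq_along(items)) {
      lp <- logprob_fn(pos, items[[pi]]$tags)
      for (li in seq_along(labels)) {
        cand_tags[[length(cand_tags) + 1L]] <- c(items[[pi]]$tags, labels[li])
        cand_score <- c(cand_score, items[[pi]]$score + lp[[labels[li]]])
        cand_lab <- c(cand_lab, li)
        cand_parent <- c(cand_parent, pi)
      }
    }
    ord <- order(-cand_score, cand_lab, cand_parent)
    take <- ord[seq_len(min(k, length(ord)))]
    items <- lapply(take, function(i) list(tags = cand_tags[[i]],
                                           score = cand_score[i]))
  }
  scores <- vapply(items, `[[`, 0, "score")
  best <- which(scores == max(scores))
  if (length(best) > 1L) {
    seqs <- vapply(items[best], function(it) {
      paste(sprintf("%03d", match(it$tags, labels)), collapse = " ")
    }, character(1))
    best <- best[order(seqs)[1L]]
  }
  structure(items[[best[1L]]]$tags, score = scores[best[1L]])
}

#' Exhaustive decoding oracle
#'
#' Enumerates every tag sequence and returns the true maximum-score sequence
#' under the same scoring and tie rule as [beam_search()] (lexicographically
#' smallest among maxima, in `labels` order). Intended as a test oracle for
#' beam search; refuses search spaces above `max_space`.
#'
#' @inheritParams beam_search
#' @param max_space maximum number of sequences to enumerate.
#' @return Character vector of `n` tags with attribute `score`.
#' @export
exhaustive_search <- function(n, labels, logprob_fn, max_space = 1e6) {
  if (n == 0L) return(structure(character(), score = 0))
  if (length(labels)^n > max_space) {
    stop("search space ", length(labels), "^", n, " exceeds max_space",
         call. = FALSE)
  }
  grid <- expand.grid(rep(list(seq_along(labels)), n))[, n:1, drop = FALSE]
  best_tags <- NULL; best_score <- -Inf
  for (r in seq_len(nrow(grid))) {
    tags <- labels[as.integer(grid[r, ])]
    score <- 0
    for (pos in seq_len(n)) {
      score <- score + logprob_fn(pos, tags[seq_len(pos - 1L)])[[tags[pos]]]
    }
    if (score > best_score) { best_score <- score; best_tags <- tags }
  }
  structure(best_tags, score = best_score)
}
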