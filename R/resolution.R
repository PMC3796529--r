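# Hypothesis resolution: combining the BIO hypotheses of several labelers
# (in the reference configuration, 7: rule matching, five per-class
# dictionaries, and the maximum-entropy tagger) into one final sequence.

# validate a candidate set: named list of equal-length tag vectors
check_candidate_set <- function(hyps) {
  if (!length(hyps)) stop("empty candidate set", call. = FALSE)
  if (is.null(names(hyps)) || any(!nzchar(names(hyps))) ||
      anyDuplicated(names(hyps))) {
    stop("candidate set hypotheses must have unique source names",
         call. = FALSE)
  }
  n <- unique(lengths(hyps))
  if (length(n) != 1L) {
    stop("hypotheses have differing lengths: ",
         paste(lengths(hyps), collapse = ", "), call. = FALSE)
  }
  invisible(hyps)
}

# token-index entity spans (1-based inclusive) of one tag sequence
tag_spans <- function(tags) {
  tags <- repair_bio(tags)
  starts <- which(startsWith(tags, "B-"))
  if (!length(starts)) {
    return(data.frame(class = character(), s = integer(), e = integer(),
                      stringsAsFactors = FALSE))
  }
  cls <- tag_class(tags)
  ends <- vapply(starts, function(i) {
    j <- i
    while (j < length(tags) && startsWith(tags[j + 1L], "I-") &&
           cls[j + 1L] == cls[i]) j <- j + 1L
    j
  }, integer(1))
  data.frame(class = cls[starts], s = starts, e = ends,
             stringsAsFactors = FALSE)
}

# encode token-index spans back to BIO (spans must be non-overlapping)
spans_to_tags <- function(spans, n) {
  tags <- rep("O", n)
  for (i in seq_len(nrow(spans))) {
    idx <- spans$s[i]:spans$e[i]
    tags[idx] <- c(paste0("B-", spans$class[i]),
                   rep(paste0("I-", spans$class[i]), length(idx) - 1L))
  }
  tags
}

#' Detect ambiguous and unambiguous tokens across labeler hypotheses
#'
#' A token is ambiguous when at least two distinct non-`O` tags are proposed
#' for it; an abstaining labeler's `O` does not create a conflict, so a lone
#' entity proposal against silent labelers is unambiguous and the agreed
#' label is that entity tag (`O` only when nobody proposes anything).
#' Maximal runs of ambiguous tokens are extended to the boundaries of every
#' entity span that overlaps them (iterated to a fixpoint), yielding
#' non-overlapping ambiguous segments: the units over which re-ranking
#' operates.
#'
#' @param hyps named list of BIO tag vectors, one per labeler, all the same
#'   length.
#' @return A list with `ambiguous` (logical per token), `segments`
#'   (data.frame `start`, `end`, 1-based inclusive token indices) and
#'   `agreed` (character per token: the agreed tag for unambiguous tokens,
#'   `NA` inside ambiguous segments).
#' @export
detect_ambiguity <- function(hyps) {
  check_candidate_set(hyps)
  n <- length(hyps[[1]])
  tagm <- do.call(rbind, hyps)             # sources x tokens
  ambiguous <- logical(n)
  agreed <- rep("O", n)
  for (j in seq_len(n)) {
    non_o <- unique(tagm[, j][tagm[, j] != "O"])
    if (length(non_o) >= 2L) {
      ambiguous[j] <- TRUE
    } else if (length(non_o) == 1L) {
      agreed[j] <- non_o
    }
  }
  all_spans <- do.call(rbind, lapply(hyps, tag_spans))
  segments <- data.frame(start = integer(), end = integer())
  if (any(ambiguous)) {
    r <- rle(ambiguous)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    segs <- data.frame(start = starts[r$values], end = ends[r$values])
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(segs))) {
        ovl <- all_spans$s <= segs$end[i] & all_spans$e >= segs$start[i]
        if (any(ovl)) {
          ns <- min(segs$start[i], all_spans$s[ovl])
          ne <- max(segs$end[i], all_spans$e[ovl])
          if (ns < segs$start[i] || ne > segs$end[i]) {
            segs$start[i] <- ns; segs$end[i] <- ne; changed <- TRUE
          }
        }
      }
      # merge overlapping/duplicated segments
      segs <- segs[order(segs$start, segs$end), , drop = FALSE]
      keep <- rep(TRUE, nrow(segs))
      for (i in seq_len(nrow(segs))[-1]) {
        prev <- max(which(keep[seq_len(i - 1L)]))
        if (segs$start[i] <= segs$end[prev]) {
          segs$end[prev] <- max(segs$end[prev], segs$end[i])
          keep[i] <- FALSE; changed <- TRUE
        }
      }
      segs <- segs[keep, , drop = FALSE]
      if (!changed) break
    }
    segments <- segs
    for (i in seq_len(nrow(segs))) agreed[segs$start[i]:segs$end[i]] <- NA
  }
  rownames(segments) <- NULL
  list(ambiguous = ambiguous, segments = segments, agreed = agreed)
}

#' Priority-list hypothesis resolution
#'
#' Merges all labeler hypotheses by three staged rules collapsed into one
#' fixpoint: (1) union -- every entity span proposed by at least one labeler
#' is a candidate and the non-entity label `O` never outranks an entity
#' (recall-maximizing); (2) embedding -- a span fully inside another keeps
#' only the containing span when the container's class has higher priority
#' (phenotype over embedded gene); (3) boundary conflicts -- overlapping
#' spans merge into one span covering their union, labeled with the
#' highest-priority participating class. The fixpoint rule implementing all
#' three: while any two candidate spans overlap, replace them by the covering
#' span labeled with the higher-priority class. The result is re-encoded as
#' well-formed BIO and the operation is idempotent.
#'
#' @param hyps named list of BIO tag vectors (one per labeler).
#' @param priority character vector of entity classes, highest priority
#'   first; `O` is implicitly last. Defaults to [default_priority()].
#' @return Character vector of BIO tags (source `"priority"`).
#' @export
resolve_priority <- function(hyps, priority = default_priority()) {
  check_candidate_set(hyps)
  n <- length(hyps[[1]])
  spans <- unique(do.call(rbind, lapply(hyps, tag_spans)))
  if (!nrow(spans)) return(structure(rep("O", n), source = "priority"))
  check_priority(priority, unique(spans$class))
  repeat {
    spans <- spans[order(spans$s, spans$e,
                         priority_rank(spans$class, priority)), , drop = FALSE]
    merged <- FALSE
    for (i in seq_len(nrow(spans) - 1L)) {
      for (j in (i + 1L):nrow(spans)) {
        if (spans$s[j] > spans$e[i]) break
        # overlap: covering span, higher-priority class
        cls <- if (priority_rank(spans$class[i], priority) <=
                   priority_rank(spans$class[j], priority)) {
          spans$class[i]
        } else {
          spans$class[j]
        }
        spans$s[i] <- min(spans$s[i], spans$s[j])
        spans$e[i] <- max(spans$e[i], spans$e[j])
        spans$class[i] <- cls
        spans <- spans[-j, , drop = FALSE]
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  structure(spans_to_tags(spans, n), source = "priority")
}
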