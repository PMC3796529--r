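#' BIO tag inventory for a set of entity classes
#'
#' @param classes character vector of entity-class codes.
#' @return Character vector `O, B-<X>, I-<X>, ...` in a deterministic order.
#' @export
bio_tags <- function(classes = entity_classes()) {
  cls <- sort_c(classes)
  c("O", as.vector(rbind(paste0("B-", cls), paste0("I-", cls))))
}

# class carried by a BIO tag ("O" for the outside label)
tag_class <- function(tags) {
  ifelse(tags == "O", "O", substr(tags, 3L, nchar(tags)))
}

#' Repair a BIO tag sequence to well-formedness
#'
#' An `I-X` tag following `O`, the sequence start, or a tag of a different
#' class is rewritten to `B-X`. This is the standard recall-preserving repair:
#' dangling continuations become new mentions rather than being discarded.
#'
#' @param tags character vector of BIO tags.
#' @return Repaired character vector of the same length.
#' @export
#' @examples
#' repair_bio(c("O", "I-PH", "I-PH"))
repair_bio <- function(tags) {
  n <- length(tags)
  if (n == 0L) return(tags)
  cls <- tag_class(tags)
  for (i in seq_len(n)) {
    if (startsWith(tags[i], "I-")) {
      ok <- i > 1L && cls[i - 1L] == cls[i]
      if (!ok) tags[i] <- paste0("B-", cls[i])
    }
  }
  tags
}

# TRUE iff tags are well-formed BIO (no dangling I-X)
is_wellformed_bio <- function(tags) {
  identical(tags, repair_bio(tags))
}

#' Construct a mention table
#'
#' Mentions are rows of `(class, start, end, surface)` with 0-based half-open
#' character offsets, the convention of BRAT standoff annotation.
#'
#' @param class entity-class codes.
#' @param start,end integer character offsets, 0-based half-open.
#' @param surface surface strings (optional; filled from `text` if given).
#' @param text optional document text used to fill/validate surfaces.
#' @return A `data.frame` with columns `class`, `start`, `end`, `surface`.
#' @export
mentions <- function(class = character(), start = integer(), end = integer(),
                     surface = NULL, text = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start >= end)) stop("mention spans must satisfy start < end", call. = FALSE)
  if (is.null(surface)) {
    if (!is.null(text) && length(start)) {
      surface <- substring(text, start + 1L, end)
    } else {
      surface <- rep(NA_character_, length(class))
    }
  }
  data.frame(class = as.character(class), start = start, end = end,
             surface = as.character(surface), stringsAsFactors = FALSE)
}

empty_mentions <- function() mentions()

# drop mentions strictly contained in another mention (outermost wins; BIO
# cannot express nesting). Identical spans are not containment.
outermost_mentions <- function(m) {
  if (nrow(m) < 2L) return(m)
  contained <- vapply(seq_len(nrow(m)), function(i) {
    any(m$start <= m$start[i] & m$end >= m$end[i] &
          (m$end - m$start) > (m$end[i] - m$start[i]))
  }, logical(1))
  m[!contained, , drop = FALSE]
}

#' Encode mentions as a BIO tag sequence over sentence tokens
#'
#' Tokens overlapping a mention receive `B-X` at the mention start and `I-X`
#' after it; all other tokens receive `O`. Nested mentions are flattened to
#' the outermost span (e.g. a gene mention embedded inside a phenotype mention
#' contributes nothing to the tags). Overlapping same-class mentions are
#' rejected, as are mentions extending beyond the token span of the sentence.
#'
#' @param tokens data.frame of token spans with columns `start`, `end`
#'   (0-based half-open character offsets).
#' @param m mention table (see [mentions()]); offsets in the same coordinate
#'   system as `tokens`.
#' @return Character vector of BIO tags, one per token.
#' @export
#' @examples
#' toks <- data.frame(start = c(0L, 8L, 15L), end = c(7L, 14L, 29L))
#' m <- mentions("PH", 8L, 29L)
#' mentions_to_bio(toks, m)
mentions_to_bio <- function(tokens, m) {
  tags <- rep("O", nrow(tokens))
  if (is.null(m) || nrow(m) == 0L) return(tags)
  lo <- min(tokens$start)
  hi <- max(tokens$end)
  out <- m$start < lo | m$end > hi
  if (any(out)) {
    stop("mention(s) outside the sentence token span: ",
         paste(m$surface[out], collapse = "; "), call. = FALSE)
  }
  m <- outermost_mentions(m)
  m <- m[order(m$start, -m$end), , drop = FALSE]
  for (i in seq_len(nrow(m))) {
    same <- which(m$class == m$class[i])
    same <- same[same != i]
    if (any(m$start[same] < m$end[i] & m$end[same] > m$start[i])) {
      stop("overlapping same-class mentions are not allowed: ", m$surface[i],
           call. = FALSE)
    }
  }
  for (i in seq_len(nrow(m))) {
    hit <- which(tokens$start < m$end[i] & tokens$end > m$start[i])
    if (!length(hit)) next
    if (any(tags[hit] != "O")) {
      stop("overlapping mentions of different classes cannot be BIO-encoded: ",
           m$surface[i], call. = FALSE)
    }
    tags[hit] <- c(paste0("B-", m$class[i]),
                   rep(paste0("I-", m$class[i]), length(hit) - 1L))
  }
  tags
}

#' Decode a BIO tag sequence into mentions
#'
#' Maximal `B-X (I-X)*` runs become mentions spanning from the first token's
#' start to the last token's end. Ill-formed input is repaired first (see
#' [repair_bio()]). For non-nested gold annotation this is the exact inverse
#' of [mentions_to_bio()].
#'
#' @param tags character vector of BIO tags, one per token.
#' @param tokens token span data.frame (columns `start`, `end`).
#' @param text optional text used to fill mention surfaces.
#' @return A mention table.
#' @export
bio_to_mentions <- function(tags, tokens, text = NULL) {
  stopifnot(length(tags) == nrow(tokens))
  tags <- repair_bio(tags)
  starts <- which(startsWith(tags, "B-"))
  if (!length(starts)) return(empty_mentions())
  cls <- tag_class(tags)
  ends <- vapply(starts, function(i) {
    j <- i
    while (j < length(tags) && startsWith(tags[j + 1L], "I-") &&
           cls[j + 1L] == cls[i]) {
      j <- j + 1L
    }
    j
  }, integer(1))
  mentions(class = cls[starts], start = tokens$start[starts],
           end = tokens$end[ends], text = text)
}
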