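#' Match predicted against gold mentions
#'
#' Greedy one-to-one matching with per-class pools, left to right: a
#' prediction is a true positive iff it pairs with a so-far-unmatched gold
#' mention of the same class whose character span overlaps it (mode
#' `"partial"`) or equals it exactly (mode `"exact"`). Unmatched predictions
#' are false positives, unmatched gold mentions false negatives; each gold
#' mention matches at most one prediction, so a single long prediction never
#' scores against several gold mentions.
#'
#' @param gold,pred mention tables (see [mentions()]).
#' @param mode `"partial"` or `"exact"`.
#' @param classes classes to tally; defaults to all classes present.
#' @return An `EvalCounts` data.frame: one row per class with `TP`, `FP`,
#'   `FN`, plus the matching mode as an attribute.
#' @export
#' @examples
#' g <- mentions("PH", 7, 23, "cleft lip/palate")
#' p <- mentions("PH", 0, 17, "median cleft lip/")
#' match_mentions(g, p, "partial")
match_mentions <- function(gold, pred, mode = c("partial", "exact"),
                           classes = NULL) {
  mode <- match.arg(mode)
  if (is.null(classes)) {
    classes <- sort_c(unique(c(gold$class, pred$class)))
  }
  counts <- data.frame(class = as.character(classes),
                       TP = integer(length(classes)),
                       FP = integer(length(classes)),
                       FN = integer(length(classes)),
                       stringsAsFactors = FALSE)
  for (ci in seq_along(classes)) {
    g <- gold[gold$class == classes[ci], , drop = FALSE]
    p <- pred[pred$class == classes[ci], , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    p <- p[order(p$start, p$end), , drop = FALSE]
    taken <- rep(FALSE, nrow(g))
    tp <- 0L
    for (i in seq_len(nrow(p))) {
      hit <- if (mode == "exact") {
        which(!taken & g$start == p$start[i] & g$end == p$end[i])
      } else {
        which(!taken & g$start < p$end[i] & g$end > p$start[i])
      }
      if (length(hit)) {
        taken[hit[1]] <- TRUE
        tp <- tp + 1L
      }
    }
    counts$TP[ci] <- tp
    counts$FP[ci] <- nrow(p) - tp
    counts$FN[ci] <- nrow(g) - tp
  }
  attr(counts, "mode") <- mode
  counts
}

#' Precision, recall and F1 from TP/FP/FN counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, and F1 is the harmonic mean
#' `2PR / (P + R)`. Any zero denominator (including `TP = 0`) yields 0.
#' Values are on the `[0, 1]` scale; multiply by 100 for the conventional
#' percentage reporting.
#'
#' @param counts an `EvalCounts` data.frame (columns `TP`, `FP`, `FN`; a
#'   `class` column is carried through when present).
#' @return data.frame with columns `precision`, `recall`, `f1` (and `class`).
#' @export
compute_prf <- function(counts) {
  p <- ifelse(counts$TP + counts$FP > 0, counts$TP / (counts$TP + counts$FP), 0)
  r <- ifelse(counts$TP + counts$FN > 0, counts$TP / (counts$TP + counts$FN), 0)
  f <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  out <- data.frame(precision = p, recall = r, f1 = f)
  if (!is.null(counts$class)) out <- cbind(class = counts$class, out)
  out
}

#' Micro-averaged precision, recall and F1
#'
#' Sums TP/FP/FN over all classes before applying [compute_prf()].
#'
#' @param counts an `EvalCounts` data.frame.
#' @return One-row data.frame with `precision`, `recall`, `f1`.
#' @export
micro_average <- function(counts) {
  compute_prf(data.frame(TP = sum(counts$TP), FP = sum(counts$FP),
                         FN = sum(counts$FN)))
}
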