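#' Approximate-randomization significance test between two systems
#'
#' Tests whether system A's micro-averaged F-score exceeds system B's by more
#' than chance. The observed statistic is `delta = F_A - F_B` computed from
#' per-sentence TP/FP/FN counts pooled over all sentences. Each repetition
#' builds two pseudo-systems by independently swapping the paired outputs of
#' every sentence between A and B with probability 1/2 and recomputes the
#' pseudo-delta; the p-value is the fraction of repetitions whose
#' pseudo-delta is at least the observed delta. With `exhaustive = TRUE` all
#' `2^n` swap assignments are enumerated instead of sampled (refused above
#' 20 sentences).
#'
#' @param outputs_a,outputs_b lists of predicted mention tables, one per
#'   sentence, aligned with `gold`.
#' @param gold list of gold mention tables, one per sentence.
#' @param reps number of repetitions R (default 1000).
#' @param seed integer seed for the swap draws.
#' @param mode matching mode for the per-sentence counts.
#' @param exhaustive enumerate all swap assignments instead of sampling.
#' @return A list with `delta`, `p_value`, `reps` (assignments evaluated),
#'   `seed` and `mode`.
#' @export
approx_randomization <- function(outputs_a, outputs_b, gold, reps = 1000L,
                                 seed = 1L, mode = c("partial", "exact"),
                                 exhaustive = FALSE) {
  mode <- match.arg(mode)
  n <- length(gold)
  if (length(outputs_a) != n || length(outputs_b) != n) {
    stop("systems A and B must be evaluated on the same ", n, " sentences",
         call. = FALSE)
  }
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  micro_counts <- function(out) {
    t(vapply(seq_len(n), function(i) {
      cc <- match_mentions(gold[[i]], out[[i]], mode)
      c(TP = sum(cc$TP), FP = sum(cc$FP), FN = sum(cc$FN))
    }, c(TP = 0, FP = 0, FN = 0)))
  }
  ca <- micro_counts(outputs_a)
  cb <- micro_counts(outputs_b)
  fscore <- function(tp, fp, fn) {
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  f_of <- function(cnt) fscore(as.numeric(cnt[1]), as.numeric(cnt[2]),
                               as.numeric(cnt[3]))
  delta <- f_of(colSums(ca)) - f_of(colSums(cb))
  if (exhaustive) {
    if (n > 20L) {
      stop("exhaustive enumeration refused for ", n, " > 20 sentences",
           call. = FALSE)
    }
    masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
    reps_used <- nrow(masks)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    masks <- matrix(stats::runif(reps * n) < 0.5, nrow = reps)
    reps_used <- reps
  }
  pseudo <- vapply(seq_len(reps_used), function(r) {
    m <- masks[r, ]
    pa <- colSums(ca[!m, , drop = FALSE]) + colSums(cb[m, , drop = FALSE])
    pb <- colSums(cb[!m, , drop = FALSE]) + colSums(ca[m, , drop = FALSE])
    f_of(pa) - f_of(pb)
  }, numeric(1))
  p <- sum(pseudo >= delta - 1e-12) / reps_used
  list(delta = delta, p_value = p, reps = reps_used, seed = seed, mode = mode)
}
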