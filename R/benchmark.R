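#' Synthetic resolver-comparison experiment
#'
#' Generates a seeded synthetic corpus in which a controlled fraction of
#' mentions is drawn from a vocabulary shared between the phenotype and
#' disease classes, with the gold class signalled only by a cue token after
#' the mention. Both per-class dictionaries fire on such mentions, producing
#' class-context-dependent ambiguity that a fixed priority list must always
#' resolve the same way while a context-aware ranker can learn the cue. The
#' experiment trains on half the documents and evaluates partial-match
#' micro-F on the other half for three resolution strategies:
#'
#' * `priority`: the priority list over the clean dictionary streams;
#' * `ltr`: the learn-to-rank resolver trained on the same clean streams;
#' * `me_heavy`: the maximum-entropy resolver run in a degraded
#'   configuration whose hypothesis streams carry heavy synthetic noise
#'   (recall loss, phenotype/disease confusion, boundary jitter), emulating
#'   a resolution stage fed by unreliable labelers.
#'
#' @param seed integer seed controlling corpus, noise and training.
#' @param n_docs number of documents (split half train, half test).
#' @param sentences_per_doc sentences per document.
#' @param ambiguous_rate expected shared-vocabulary mentions per sentence.
#' @param heavy_noise noise parameters for the degraded configuration:
#'   list with `drop`, `confusion` (symmetric PH/DS rate) and `jitter`.
#' @return A data.frame with columns `resolver` and `micro_f` (percent),
#'   plus attribute `n_test_docs`.
#' @export
resolver_benchmark <- function(seed, n_docs = 30L, sentences_per_doc = 3L,
                               ambiguous_rate = 0.7,
                               heavy_noise = list(drop = 0.45,
                                                  confusion = 0.4,
                                                  jitter = 0.25)) {
  g <- gen_corpus(n_docs = n_docs, sentences_per_doc = sentences_per_doc,
                  seed = seed, nesting_prob = 0,
                  ambiguous = list(rate = ambiguous_rate))
  idx_train <- seq_len(floor(n_docs / 2))
  idx_test <- setdiff(seq_len(n_docs), idx_train)
  cfg <- ner_config(lexicons = unname(g$lexicons), use_tagger = FALSE)
  cands <- lapply(g$docs, make_candidate_sets, config = cfg)

  eval_micro <- function(pred_tags_by_doc, idx) {
    counts <- NULL
    for (j in seq_along(idx)) {
      doc <- g$docs[[idx[j]]]
      pred <- document_bio_to_mentions(doc, pred_tags_by_doc[[j]])
      cc <- match_mentions(doc$gold, pred, "partial")
      cc <- data.frame(TP = sum(cc$TP), FP = sum(cc$FP), FN = sum(cc$FN))
      counts <- if (is.null(counts)) cc else counts + cc
    }
    100 * micro_average(counts)$f1
  }

  # priority list over the clean dictionary streams
  f_pl <- eval_micro(lapply(idx_test, function(i) {
    lapply(cands[[i]], resolve_priority, priority = cfg$priority)
  }), idx_test)

  # learn-to-rank over the same streams
  ltr <- train_ltr(g$docs[idx_train], cands[idx_train],
                   priority = cfg$priority)
  f_ltr <- eval_micro(lapply(idx_test, function(i) {
    resolve_ltr(ltr, g$docs[[i]], cands[[i]])
  }), idx_test)

  # maximum-entropy resolver in the heavy-noise configuration
  noise <- lapply(stats::setNames(nm = paste0("noisy", 1:5)), function(nm) {
    list(drop = heavy_noise$drop,
         confusion = list(PH = c(DS = heavy_noise$confusion),
                          DS = c(PH = heavy_noise$confusion)),
         jitter = heavy_noise$jitter)
  })
  noisy <- gen_labeler_outputs(g$docs, noise, seed = seed + 1L)
  me <- train_me_resolver(g$docs[idx_train], noisy[idx_train], maxit = 300)
  f_me <- eval_micro(lapply(idx_test, function(i) {
    resolve_me(me, g$docs[[i]], noisy[[i]])
  }), idx_test)

  structure(data.frame(resolver = c("ltr", "priority", "me_heavy"),
                       micro_f = c(f_ltr, f_pl, f_me),
                       stringsAsFactors = FALSE),
            n_test_docs = length(idx_test))
}
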