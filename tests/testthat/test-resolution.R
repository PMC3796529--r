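test_that("ambiguity detection separates conflicts from lone proposals", {
  # disjoint proposals from different labelers: no conflict, entities kept
  hyps <- list(l1 = c("B-PH", "I-PH", "O", "O", "O"),
               l2 = c("O", "O", "O", "B-GG", "I-GG"),
               l3 = rep("O", 5))
  rep1 <- detect_ambiguity(hyps)
  expect_false(any(rep1$ambiguous))
  expect_equal(nrow(rep1$segments), 0)
  expect_identical(rep1$agreed, c("B-PH", "I-PH", "O", "B-GG", "I-GG"))

  # several classes proposed for one token: ambiguous
  hyps2 <- list(l1 = c("B-PH", "O"), l2 = c("B-GG", "O"),
                l3 = c("O", "O"), l4 = c("B-AN", "O"))
  rep2 <- detect_ambiguity(hyps2)
  expect_true(rep2$ambiguous[1])
  expect_false(rep2$ambiguous[2])
  expect_equal(nrow(rep2$segments), 1)

  # full agreement: empty report
  agree <- list(l1 = c("B-DS", "O"), l2 = c("B-DS", "O"))
  expect_equal(nrow(detect_ambiguity(agree)$segments), 0)
})

test_that("ambiguous segments extend to participating span boundaries", {
  # conflict on token 2 only, but l1's span covers tokens 1-3
  hyps <- list(l1 = c("B-PH", "I-PH", "I-PH"),
               l2 = c("B-PH", "B-GG", "I-PH"))
  rep_ <- detect_ambiguity(hyps)
  expect_equal(rep_$segments$start, 1)
  expect_equal(rep_$segments$end, 3)
})

test_that("candidate sets are validated", {
  expect_error(detect_ambiguity(list()), "empty")
  expect_error(detect_ambiguity(list(a = "O", b = c("O", "O"))), "lengths")
  expect_error(detect_ambiguity(list(c("O"), c("O"))), "source names")
})

test_that("priority resolution reproduces the staged merge rules", {
  # partial overlap [AB]GG + [BC]PH merges into [ABC] labeled PH
  hyps <- list(gg = c("B-GG", "I-GG", "O"), ph = c("O", "B-PH", "I-PH"))
  expect_identical(as.character(resolve_priority(hyps)),
                   c("B-PH", "I-PH", "I-PH"))

  # GG fully embedded in PH keeps only the containing phenotype
  hyps2 <- list(ph = c("B-PH", "I-PH", "I-PH"), gg = c("O", "B-GG", "O"))
  expect_identical(as.character(resolve_priority(hyps2)),
                   c("B-PH", "I-PH", "I-PH"))

  # a single firing labeler passes through
  hyps3 <- list(only = c("O", "B-CD", "O"))
  expect_identical(as.character(resolve_priority(hyps3)), c("O", "B-CD", "O"))

  # DS outranks PH; PH outranks GG (two-hypothesis fixtures)
  expect_identical(
    as.character(resolve_priority(list(a = c("B-DS", "I-DS"),
                                       b = c("B-PH", "I-PH")))),
    c("B-DS", "I-DS"))
  expect_identical(
    as.character(resolve_priority(list(a = c("B-GG", "I-GG"),
                                       b = c("B-PH", "I-PH")))),
    c("B-PH", "I-PH"))
})

test_that("priority resolution is idempotent and never demotes to O", {
  set.seed(9)
  for (i in 1:300) {
    n <- sample(2:12, 1)
    hyps <- random_candidate_set(n)
    out <- as.character(resolve_priority(hyps))
    expect_true(phenoner:::is_wellformed_bio(out))
    # idempotence: feeding the output back as a lone hypothesis
    expect_identical(as.character(resolve_priority(list(final = out))), out)
    # union rule: a token proposed as entity by anyone stays an entity
    proposed <- Reduce(`|`, lapply(hyps, function(h) h != "O"))
    expect_true(all(out[proposed] != "O"))
  }
})

test_that("rank lists implement the three rules and the left tie-break", {
  gold <- c("B-PH", "I-PH", "O")
  hyps <- list(exact = c("B-PH", "I-PH", "O"),
               overlap = c("O", "B-GG", "I-GG"),
               silent = c("O", "O", "O"))
  rl <- build_rank_lists(hyps, gold)
  expect_equal(nrow(rl), 3)
  expect_identical(rl$rank[match(c("exact", "overlap", "silent"), rl$source)],
                   c(1L, 2L, 3L))
  expect_identical(rl$rank_group[match(c("exact", "overlap", "silent"),
                                       rl$source)], c(1L, 2L, 3L))

  # two exact-class matches at different offsets: leftmost ranks higher
  gold2 <- c("B-DS", "O", "B-DS")
  hyps2 <- list(right = c("O", "O", "B-DS"),
                left = c("B-DS", "O", "O"),
                o1 = c("B-PH", "I-PH", "I-PH"))  # one segment over all tokens
  rl2 <- build_rank_lists(hyps2, gold2)
  expect_lt(rl2$rank[rl2$source == "left"], rl2$rank[rl2$source == "right"])

  # identical candidates: one query, same rank group, retained
  same <- list(a = c("B-PH", "O"), b = c("B-PH", "O"), c = c("B-DS", "O"))
  rl3 <- build_rank_lists(same, c("B-PH", "O"))
  expect_equal(length(unique(rl3$query)), 1)
  expect_identical(sort(rl3$rank_group[rl3$source %in% c("a", "b")]),
                   c(1L, 1L))
})

test_that("LTR training separates separable rank lists", {
  # context word decides PH vs DS; dictionaries always disagree
  mk <- function(cue, cl, id) {
    tok_doc(c("f1", "ambw1", "ambw2", cue, "f2"),
            list(list(class = cl, from = 2, to = 3)), id)
  }
  docs <- c(lapply(1:6, function(i) mk("cueph", "PH", paste0("p", i))),
            lapply(1:6, function(i) mk("cueds", "DS", paste0("d", i))))
  cands <- lapply(docs, function(d) {
    list(list(dict_PH = c("O", "B-PH", "I-PH", "O", "O"),
              dict_DS = c("O", "B-DS", "I-DS", "O", "O"),
              dict_GG = rep("O", 5)))
  })
  m <- train_ltr(docs, cands)
  expect_false(is.null(m$w))
  # resolution follows the cue on unseen documents
  t1 <- resolve_ltr(m, mk("cueph", "PH", "x"), cands[[1]])
  expect_identical(t1[[1]][2:3], c("B-PH", "I-PH"))
  t2 <- resolve_ltr(m, mk("cueds", "DS", "y"), cands[[1]])
  expect_identical(t2[[1]][2:3], c("B-DS", "I-DS"))
})

test_that("a lone candidate in a segment is returned unchanged", {
  d <- tok_doc(c("f1", "phw1", "f2"), list(list(class = "PH", from = 2, to = 2)))
  cands <- list(list(a = c("O", "B-PH", "O"), b = c("O", "B-DS", "O")))
  m <- structure(list(w = NULL, feat_index = NULL,
                      priority = default_priority(), window = 2L,
                      sources = c("a", "b"), cost = 1),
                 class = "pheno_ltr_resolver")
  # with zero weights the tie falls to the alphabetically first source
  out <- resolve_ltr(m, d, cands)
  expect_identical(out[[1]][2], "B-PH")
  # truly unambiguous tokens are fixed without any model
  cands2 <- list(list(a = c("O", "B-PH", "O"), b = rep("O", 3)))
  expect_identical(resolve_ltr(m, d, cands2)[[1]], c("O", "B-PH", "O"))
})

test_that("ME resolver learns from hypothesis streams", {
  g <- gen_corpus(n_docs = 10, sentences_per_doc = 3, seed = 53,
                  nesting_prob = 0)
  # noiseless streams reproduce gold
  clean <- gen_labeler_outputs(g$docs, list(l1 = list(), l2 = list()), seed = 1)
  m <- train_me_resolver(g$docs[1:6], clean[1:6], maxit = 300)
  correct <- 0; total <- 0
  for (i in 7:10) {
    out <- resolve_me(m, g$docs[[i]], clean[[i]])
    gold <- document_gold_bio(g$docs[[i]])
    correct <- correct + sum(unlist(out) == unlist(gold))
    total <- total + length(unlist(gold))
  }
  expect_gte(correct / total, 0.99)
})

test_that("ME resolver outperforms a systematically wrong labeler", {
  g <- gen_corpus(n_docs = 12, sentences_per_doc = 3, seed = 59,
                  nesting_prob = 0)
  noise <- list(good1 = list(), good2 = list(),
                bad = list(confusion = list(PH = c(DS = 1))))
  cands <- gen_labeler_outputs(g$docs, noise, seed = 2)
  m <- train_me_resolver(g$docs[1:8], cands[1:8], maxit = 300)
  acc <- function(tags_by_doc, idx) {
    num <- 0; den <- 0
    for (j in seq_along(idx)) {
      gold <- unlist(document_gold_bio(g$docs[[idx[j]]]))
      num <- num + sum(unlist(tags_by_doc[[j]]) == gold)
      den <- den + length(gold)
    }
    num / den
  }
  idx <- 9:12
  res_acc <- acc(lapply(idx, function(i) resolve_me(m, g$docs[[i]], cands[[i]])), idx)
  bad_acc <- acc(lapply(idx, function(i) lapply(cands[[i]], `[[`, "bad")), idx)
  expect_gt(res_acc, bad_acc)
})

test_that("ablation disables exactly the named resource", {
  g <- gen_corpus(n_docs = 2, sentences_per_doc = 2, seed = 61)
  cfg <- ner_config(lexicons = unname(g$lexicons), use_tagger = FALSE)
  cut <- ablate(cfg, "synth_CD")
  cs0 <- make_candidate_sets(g$docs[[1]], cfg)
  cs1 <- make_candidate_sets(g$docs[[1]], cut)
  expect_true("dict_CD" %in% names(cs0[[1]]))
  expect_false("dict_CD" %in% names(cs1[[1]]))
  # other streams unchanged
  for (nm in setdiff(names(cs1[[1]]), "dict_CD")) {
    expect_identical(cs1[[1]][[nm]], cs0[[1]][[nm]])
  }
  # knock out then restore
  restored <- cut; restored$enabled["synth_CD"] <- TRUE
  expect_identical(restored, cfg)
  expect_error(ablate(cfg, "nope"), "registered")
})
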