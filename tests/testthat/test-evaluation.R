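test_that("partial matching accepts overlap; exact matching does not", {
  txt <- "median cleft lip/palate"
  gold <- mentions("PH", 7L, 23L, text = txt)      # "cleft lip/palate"
  pred <- mentions("PH", 0L, 16L, text = txt)      # "median cleft lip"
  cp <- match_mentions(gold, pred, "partial")
  expect_equal(c(sum(cp$TP), sum(cp$FP), sum(cp$FN)), c(1, 0, 0))
  ce <- match_mentions(gold, pred, "exact")
  expect_equal(c(sum(ce$TP), sum(ce$FP), sum(ce$FN)), c(0, 1, 1))

  # identical span, different class: FP + FN
  gold2 <- mentions("PH", 0L, 5L, "xxxxx")
  pred2 <- mentions("DS", 0L, 5L, "xxxxx")
  cc <- match_mentions(gold2, pred2, "partial")
  expect_equal(c(sum(cc$TP), sum(cc$FP), sum(cc$FN)), c(0, 1, 1))
})

test_that("matching is one-to-one and monotone in the matching mode", {
  set.seed(13)
  for (i in 1:200) {
    mk <- function(n) {
      if (n == 0) return(mentions())
      s <- sort(sample(0:30, n))
      mentions(sample(c("PH", "GG"), n, replace = TRUE), s,
               s + sample(1:6, n, replace = TRUE),
               surface = rep("x", n))
    }
    gold <- mk(sample(0:5, 1)); pred <- mk(sample(0:5, 1))
    cp <- match_mentions(gold, pred, "partial")
    ce <- match_mentions(gold, pred, "exact")
    expect_gte(sum(cp$TP), sum(ce$TP))
    for (j in seq_len(nrow(cp))) {
      expect_lte(cp$TP[j], min(sum(gold$class == cp$class[j]),
                               sum(pred$class == cp$class[j])))
    }
    # counts are consistent tallies
    expect_equal(sum(cp$TP) + sum(cp$FN), nrow(gold))
    expect_equal(sum(cp$TP) + sum(cp$FP), nrow(pred))
  }
})

test_that("greedy matching agrees with optimal bipartite matching when small", {
  # brute-force optimal one-to-one matching oracle over permutations
  oracle_tp <- function(gold, pred) {
    if (!nrow(gold) || !nrow(pred)) return(0L)
    ov <- outer(seq_len(nrow(pred)), seq_len(nrow(gold)),
                Vectorize(function(i, j) {
                  gold$class[j] == pred$class[i] &&
                    gold$start[j] < pred$end[i] && gold$end[j] > pred$start[i]
                }))
    best <- 0L
    perms <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    for (ord in perms(seq_len(nrow(pred)))) {
      taken <- rep(FALSE, nrow(gold)); tp <- 0L
      for (i in ord) {
        j <- which(ov[i, ] & !taken)
        if (length(j)) { taken[j[1]] <- TRUE; tp <- tp + 1L }
      }
      best <- max(best, tp)
    }
    best
  }
  set.seed(29)
  worse <- 0L
  for (i in 1:60) {
    n1 <- sample(1:3, 1); n2 <- sample(1:3, 1)
    s1 <- sample(0:12, n1); s2 <- sample(0:12, n2)
    gold <- mentions(rep("PH", n1), s1, s1 + sample(1:5, n1, replace = TRUE),
                     surface = rep("x", n1))
    pred <- mentions(rep("PH", n2), s2, s2 + sample(1:5, n2, replace = TRUE),
                     surface = rep("x", n2))
    greedy <- sum(match_mentions(gold, pred, "partial")$TP)
    opt <- oracle_tp(gold, pred)
    expect_lte(greedy, opt)    # greedy never overcounts
    if (greedy < opt) worse <- worse + 1L
  }
  # left-to-right greedy with interval overlap is optimal in practice here
  expect_lte(worse, 3)
})

test_that("precision, recall and F follow the harmonic-mean identities", {
  p1 <- compute_prf(data.frame(TP = 10, FP = 0, FN = 0))
  expect_equal(unlist(p1), c(precision = 1, recall = 1, f1 = 1))
  p2 <- compute_prf(data.frame(TP = 1, FP = 1, FN = 3))
  expect_equal(unlist(p2), c(precision = 0.5, recall = 0.25, f1 = 1 / 3))
  expect_equal(unlist(compute_prf(data.frame(TP = 0, FP = 0, FN = 0))),
               c(precision = 0, recall = 0, f1 = 0))
})

test_that("micro-average pools counts before the ratio", {
  counts <- data.frame(class = c("A", "B"), TP = c(1, 0), FP = c(0, 1),
                       FN = c(0, 1))
  expect_equal(micro_average(counts)$f1, 0.5)
  one <- data.frame(class = "A", TP = 3, FP = 1, FN = 2)
  expect_equal(micro_average(one)$f1, compute_prf(one)$f1)
  zero <- data.frame(class = c("A", "B"), TP = 0, FP = 0, FN = 0)
  expect_equal(micro_average(zero)$f1, 0)
})

test_that("cross-validation partitions documents and pools counts", {
  g <- gen_corpus(n_docs = 6, sentences_per_doc = 2, seed = 67)
  cfg <- ner_config(lexicons = unname(g$lexicons), use_tagger = FALSE)
  cv <- cross_validate(g$docs, cfg, k = 2, seed = 3)
  expect_equal(sort(table(cv$fold)), sort(table(c(1, 1, 1, 2, 2, 2))))
  # every document tested exactly once
  expect_equal(length(cv$per_doc), 6)
  expect_false(any(vapply(cv$per_doc, is.null, logical(1))))
  # same seed, same folds; different seed reshuffles eventually
  cv2 <- cross_validate(g$docs, cfg, k = 2, seed = 3)
  expect_identical(cv$fold, cv2$fold)
  # pooled counts equal the sum of per-document counts
  total <- Reduce(`+`, lapply(cv$per_doc, function(x) {
    cc <- match_mentions(x$gold, x$pred, "partial", cv$counts$class)
    cc[, c("TP", "FP", "FN")]
  }))
  expect_equal(cv$counts[, c("TP", "FP", "FN")], total)
  expect_error(cross_validate(g$docs[1:3], cfg, k = 10), "fewer than k")
})

test_that("unique-mention analysis counts surface/class novelty per fold", {
  mk <- function(id, term, cl) tok_doc(c("f1", term, "f2"),
                                       list(list(class = cl, from = 2, to = 2)),
                                       id)
  mk2 <- function(id, uniq) tok_doc(
    c("f1", "shared", "f2", uniq, "f3"),
    list(list(class = "PH", from = 2, to = 2),
         list(class = "PH", from = 4, to = 4)), id)
  # every document holds "shared" plus a document-unique term, so under any
  # 2+2 fold split half the test gold is seen in training and half is not
  docs <- list(mk2("a1", "u1"), mk2("a2", "u2"), mk2("a3", "u3"),
               mk2("a4", "u4"))
  cfg <- ner_config(lexicons = list(make_lexicon(
    c("shared", paste0("u", 1:4)), "PH")), use_tagger = FALSE)
  cv <- cross_validate(docs, cfg, k = 2, seed = 5)
  ue <- unique_mention_eval(cv, docs)
  expect_equal(unname(ue$unique_rate["PH"]), 50)
  expect_equal(ue$micro$f1, 1)  # dictionaries recover the unique mentions

  # fully disjoint train/test vocabularies: rate 100
  docs2 <- list(mk("c1", "t1", "PH"), mk("c2", "t2", "PH"),
                mk("c3", "t3", "PH"), mk("c4", "t4", "PH"))
  cfg2 <- ner_config(lexicons = list(make_lexicon(paste0("t", 1:4), "PH")),
                     use_tagger = FALSE)
  cv2 <- cross_validate(docs2, cfg2, k = 2, seed = 5)
  expect_equal(unname(unique_mention_eval(cv2, docs2)$unique_rate["PH"]), 100)

  # identical vocabulary everywhere: rate 0
  docs3 <- list(mk("d1", "t1", "PH"), mk("d2", "t1", "PH"),
                mk("d3", "t1", "PH"), mk("d4", "t1", "PH"))
  cv3 <- cross_validate(docs3, cfg2, k = 2, seed = 5)
  expect_equal(unname(unique_mention_eval(cv3, docs3)$unique_rate["PH"]), 0)
})

test_that("randomization test: identical systems give p = 1, delta flips sign", {
  g <- gen_corpus(n_docs = 4, sentences_per_doc = 3, seed = 71)
  cfg <- ner_config(lexicons = unname(g$lexicons), use_tagger = FALSE)
  cv <- cross_validate(g$docs, cfg, k = 2, seed = 1)
  out <- cv_sentence_outputs(cv, g$docs)
  res <- approx_randomization(out$pred, out$pred, out$gold, reps = 50, seed = 2)
  expect_equal(res$delta, 0)
  expect_equal(res$p_value, 1)

  # degrade system B by dropping all predictions in half the sentences
  predB <- out$pred
  for (i in seq(1, length(predB), by = 2)) predB[[i]] <- mentions()
  ra <- approx_randomization(out$pred, predB, out$gold, reps = 100, seed = 2)
  rb <- approx_randomization(predB, out$pred, out$gold, reps = 100, seed = 2)
  expect_equal(ra$delta, -rb$delta)
  expect_error(approx_randomization(out$pred[-1], predB, out$gold),
               "same")
})
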