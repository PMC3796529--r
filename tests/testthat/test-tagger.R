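test_that("feature extraction pads boundaries and is deterministic", {
  words <- c("high", "ige", "levels")
  aux <- list(species = c("O", "O", "O"))
  f0 <- extract_features(words, aux, 1, character(), window = 2)
  expect_true("w-1=<s>" %in% f0)
  expect_true("w-2=<s>" %in% f0)
  expect_true("w+1=ige" %in% f0)
  expect_true(any(startsWith(f0, "aux:species:")))
  expect_identical(f0, extract_features(words, aux, 1, character(), window = 2))

  f3 <- extract_features(words, aux, 3, c("B-PH", "I-PH"), window = 2)
  expect_true("t-1=I-PH" %in% f3)
  expect_true("t-2t-1=B-PH_I-PH" %in% f3)
  expect_true("w+1=</s>" %in% f3)
})

test_that("training on a separable corpus memorizes it; runs are identical", {
  g <- gen_corpus(n_docs = 8, sentences_per_doc = 3, seed = 41,
                  nesting_prob = 0)
  m1 <- train_tagger(g$docs, maxit = 300)
  m2 <- train_tagger(g$docs, maxit = 300)
  expect_identical(m1$maxent$W, m2$maxent$W)

  correct <- 0; total <- 0
  for (d in g$docs) {
    gold <- document_gold_bio(d)
    for (s in seq_len(nrow(d$sentences))) {
      pred <- beam_decode(m1, d, s, k = 3)
      correct <- correct + sum(pred == gold[[s]])
      total <- total + length(gold[[s]])
    }
  }
  expect_gte(correct / total, 0.99)
})

test_that("a single-label corpus yields a degenerate always-O model", {
  docs <- list(ner_document("a", "nothing to see here."),
               ner_document("b", "still nothing at all."))
  m <- train_tagger(docs)
  expect_identical(m$maxent$labels, "O")
  expect_identical(as.character(beam_decode(m, docs[[1]], 1)), rep("O", 5))
  expect_warning(train_tagger(docs, classes = c("PH")), "no training instances")
})

test_that("per-position scores are normalized probabilities", {
  g <- gen_corpus(n_docs = 4, sentences_per_doc = 2, seed = 43)
  m <- train_tagger(g$docs, maxit = 200)
  sc <- phenoner:::tagger_scorer(m, g$docs[[1]], 1)
  for (pos in 1:3) {
    lp <- sc(pos, rep("O", pos - 1))
    expect_equal(sum(exp(lp)), 1, tolerance = 1e-9)
  }
})

test_that("beam search equals greedy at K=1 and the oracle when saturated", {
  set.seed(17)
  labels <- c("B-PH", "I-PH", "O")
  for (i in 1:40) {
    n <- sample(1:4, 1)
    sc <- random_scorer(n, labels)
    b1 <- beam_search(n, labels, sc, k = 1)
    # independent greedy trace
    greedy <- character(0)
    for (pos in seq_len(n)) {
      lp <- sc(pos, greedy)
      best <- which(lp == max(lp))
      greedy <- c(greedy, labels[best[1]])
    }
    expect_identical(as.character(b1), greedy)

    bsat <- beam_search(n, labels, sc, k = length(labels)^n)
    ex <- exhaustive_search(n, labels, sc)
    expect_identical(as.character(bsat), as.character(ex))
    expect_equal(attr(bsat, "score"), attr(ex, "score"))
  }
})

test_that("beam and exhaustive tagger decoding agree on trained models", {
  docs <- list(
    tok_doc(c("f1", "phw1", "phw2", "f2"), list(list(class = "PH", from = 2, to = 3)), "a"),
    tok_doc(c("f3", "phw1", "phw2", "f1"), list(list(class = "PH", from = 2, to = 3)), "b"),
    tok_doc(c("f2", "f4", "f1", "f3"), list(), "c"))
  m <- train_tagger(docs, maxit = 200)
  for (d in docs) {
    k_sat <- length(m$maxent$labels)^4    # 3 labels, 4 tokens
    bd <- beam_decode(m, d, 1, k = k_sat)
    ed <- exhaustive_decode(m, d, 1)
    expect_identical(as.character(bd), as.character(ed))
    expect_equal(attr(bd, "score"), attr(ed, "score"))
  }
})

test_that("a one-token sentence decodes to the argmax label for any K", {
  labels <- c("B-PH", "O")
  sc <- function(pos, prev) c("B-PH" = log(0.8), "O" = log(0.2))
  for (k in c(1, 3, 10)) {
    expect_identical(as.character(beam_search(1, labels, sc, k = k)), "B-PH")
  }
  expect_identical(as.character(exhaustive_search(0, labels, sc)), character())
  expect_error(exhaustive_search(30, labels, sc), "max_space")
})

test_that("score ties break identically in beam and exhaustive search", {
  labels <- c("A", "B")
  sc <- function(pos, prev) c(A = log(0.5), B = log(0.5))
  b <- beam_search(3, labels, sc, k = 8)
  ex <- exhaustive_search(3, labels, sc)
  expect_identical(as.character(b), c("A", "A", "A"))
  expect_identical(as.character(ex), c("A", "A", "A"))
})
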