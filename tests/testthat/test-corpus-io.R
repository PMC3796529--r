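test_that("segment_and_tokenize splits punctuation and reconstructs offsets", {
  tz <- segment_and_tokenize("IgE levels rose.")
  expect_equal(nrow(tz$sentences), 1)
  expect_identical(tz$tokens$text, c("IgE", "levels", "rose", "."))

  expect_equal(nrow(segment_and_tokenize("")$sentences), 0)

  tz2 <- segment_and_tokenize("One done. Two fun.")
  expect_equal(nrow(tz2$sentences), 2)
  expect_equal(tz2$tokens$sentence, c(1, 1, 1, 2, 2, 2))

  # offsets reconstruct every token; tokens never cross sentence bounds
  txt <- "Toll-like receptor/IL-1R pathways rose, then fell. Crohn's disease."
  tz3 <- segment_and_tokenize(txt)
  expect_identical(substring(txt, tz3$tokens$start + 1, tz3$tokens$end),
                   tz3$tokens$text)
  for (i in seq_len(nrow(tz3$tokens))) {
    s <- tz3$tokens$sentence[i]
    expect_true(tz3$tokens$start[i] >= tz3$sentences$start[s])
    expect_true(tz3$tokens$end[i] <= tz3$sentences$end[s])
  }
  expect_true("Toll-like" %in% tz3$tokens$text)   # hyphenated token intact
  expect_true("," %in% tz3$tokens$text)
})

test_that("read_brat parses entity lines and validates surfaces", {
  txt <- "high IgE levels were seen."
  d <- read_brat(txt, "T1\tPH 0 15\thigh IgE levels")
  expect_equal(nrow(d$gold), 1)
  expect_identical(d$gold$class, "PH")
  expect_identical(d$gold$surface, "high IgE levels")

  expect_equal(nrow(read_brat(txt, "")$gold), 0)
  expect_equal(nrow(read_brat(txt, character())$gold), 0)

  expect_error(read_brat(txt, "T1\tPH 0 15\thigh IgE level"),
               "T1")
  expect_error(read_brat(txt, "T1\tPH zero 15\thigh IgE levels"),
               "line 1")
  # relation and note lines are ignored
  d2 <- read_brat(txt, c("T1\tPH 0 15\thigh IgE levels",
                         "R1\tFoo Arg1:T1 Arg2:T1", "#1\tNote x"))
  expect_equal(nrow(d2$gold), 1)
  expect_warning(read_brat(txt, "T1\tZZ 0 4\thigh"), "outside the inventory")
})

test_that("BRAT round trip is lossless for the entity layer", {
  g <- gen_corpus(n_docs = 5, sentences_per_doc = 3, seed = 31)
  for (d in g$docs) {
    back <- read_brat(d$text, write_brat(d), id = d$id)
    expect_identical(back$gold, d$gold)
  }
  d <- g$docs[[1]]
  expect_equal(length(strsplit(write_brat(d), "\n")[[1]]), nrow(d$gold))
  expect_identical(write_brat(ner_document("e", "no entities here.")), "")

  # corpus-level file round trip through the real readers
  dir <- withr::local_tempdir()
  write_brat_corpus(g$docs, dir)
  back <- read_brat_corpus(dir)
  expect_equal(length(back), length(g$docs))
  expect_identical(back[[2]]$gold, g$docs[[2]]$gold)
})

test_that("abbreviation definitions are detected and expanded", {
  txt <- "The non-obese diabetic (NOD) mouse was used. NOD mice were fed."
  ab <- detect_abbreviations(txt)
  expect_equal(nrow(ab), 1)
  expect_identical(ab$short, "NOD")
  expect_identical(ab$long, "non-obese diabetic")

  d <- ner_document("a", txt)
  d2 <- expand_abbreviations(d)
  expect_match(d2$text, "used. non-obese diabetic mice were fed", fixed = TRUE)
  # the definition site itself is untouched
  expect_match(d2$text, "non-obese diabetic (NOD) mouse", fixed = TRUE)

  # no parentheses, or a short form never reused: document unchanged
  plain <- ner_document("b", "no abbreviations at all here.")
  expect_identical(expand_abbreviations(plain)$text, plain$text)
  once <- ner_document("c", "the tumor necrosis factor (TNF) was high.")
  expect_identical(expand_abbreviations(once)$text, once$text)
})

test_that("abbreviation expansion remaps or skips mention offsets", {
  txt <- "non-obese diabetic (NOD) mouse was used. NOD mice were fed."
  g <- mentions(c("OR", "OR"), c(41L, 0L), c(49L, 30L), text = txt)
  d <- ner_document("a", txt, gold = g)
  d2 <- expand_abbreviations(d)
  m <- d2$gold[order(d2$gold$start), ]
  expect_identical(m$surface[2], "non-obese diabetic mice")
  expect_identical(m$surface[1], "non-obese diabetic (NOD) mouse")

  # a replacement that would split a mention is skipped with a warning
  g2 <- mentions("OR", 43L, 49L, text = txt)   # "D mice" splits the SF
  d3 <- ner_document("b", txt, gold = g2)
  expect_warning(d4 <- expand_abbreviations(d3), "split a mention")
  expect_identical(d4$text, txt)
})

test_that("CoNLL export carries tokens, aux streams and gold BIO", {
  d <- tok_doc(c("high", "IgE", "levels"),
               list(list(class = "PH", from = 1, to = 3)))
  d$aux <- list(pos = c("JJ", "NN", "NNS"))
  tab <- document_to_conll(d)
  expect_identical(tab$gold, c("B-PH", "I-PH", "I-PH"))
  expect_identical(tab$pos, c("JJ", "NN", "NNS"))
})
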