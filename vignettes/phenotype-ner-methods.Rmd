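---
title: "Hybrid phenotype-candidate NER: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid phenotype-candidate NER: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoner)
```

## The task and the model

Phenotype descriptions ("high IgE levels", "absent ankle reflexes") are
compositional: an affected entity plus a quality. No single terminology
covers them, which is why `phenoner` treats phenotype-candidate recognition
as an ensemble problem. Several independent labelers each propose a BIO tag
sequence per sentence, and a resolution stage combines the conflicting
hypotheses into one final sequence. Six entity classes are recognized by
default: phenotype candidate (PH), gene/gene product (GG), disease (DS),
organism (OR), anatomy (AN) and chemical/drug (CD).

The labelers are:

1. **Per-class dictionary matchers** (`dict_label()`): longest-string
   matching of token n-grams against a lexicon, case-insensitive and
   plural-normalized on both sides. One stream per entity class, built from
   the union of the enabled lexicons of that class.
2. **A modifier-composition rule labeler** (`rule_label()`): head terms
   (anatomy, gene, disease/process vocabularies) matched by dictionary are
   extended over contiguous modifier-list tokens (quality and abnormality
   words); any span that actually extends is relabeled PH. This reconstructs
   staged rule-matching over domain vocabularies without an external
   concept-mapping service; the labeler interface is pluggable, so such a
   service could be substituted stream-for-stream.
3. **A maximum-entropy sequence tagger** (`train_tagger()` /
   `beam_decode()`): per-token multinomial logistic classification over
   lexical and contextual features, decoded with beam search.

### The maximum-entropy tagger

Each token position is classified over the observed BIO label inventory from
binary indicator features: the focus word, context words in a window of
±2, one feature per auxiliary tag stream per window slot (part-of-speech
tags, species tags, or the output of any externally trained tagger supplied
as a per-token stream), the previous tag and previous-2-tag bigram, and a
bias. Weights are the L2-regularized maximum-likelihood solution, obtained
with L-BFGS on the exact negative log-likelihood and gradient; training is
deterministic. Decoding is beam search with width `K` (default 3): the `K`
best tag prefixes by summed log-probability are kept per position, which is
linear in sentence length × labels × `K`, trading the optimality guarantee
of dynamic programming for cheap conditioning on previous predicted tags.
`exhaustive_decode()` enumerates the full search space and serves as the
decoding oracle in the tests; beam scores are non-decreasing in `K` on all
tested instances and equal the oracle at saturated width. Ties are broken
lexicographically in label order, then by beam-insertion order, so decoding
is reproducible bit for bit.

### Hypothesis resolution

Three interchangeable strategies (`--resolver {priority,me,ltr}`):

* **Priority list** (`resolve_priority()`). A fixed total order over
  classes, `DS > PH > GG > AN > CD > OR > O` by default. Only fragments of
  an order are forced by the domain analysis (PH outranks an embedded GG,
  DS outranks PH, entity proposals always outrank O, organisms never
  contain gene names); the rest of the default is our completion and is a
  configuration item. The three staged merge rules — union of all proposed
  spans, containment resolved in favour of a higher-priority container,
  overlap merged into the covering span under the highest-priority class —
  collapse into one fixpoint rule (merge any overlapping pair into the
  covering span with the higher-priority class), which makes the operation
  idempotent by construction and never demotes a proposed entity token
  to O.
* **Maximum-entropy re-labeling** (`train_me_resolver()` /
  `resolve_me()`). Every token is re-classified by a second-stage
  maximum-entropy model whose features are the current word, context words,
  and each labeler's tag at every window slot, beam-decoded like the base
  tagger. No ambiguity screening is applied: the sequence model itself
  arbitrates.
* **Learn-to-rank** (`train_ltr()` / `resolve_ltr()`). Tokens on which at
  most one distinct non-O tag is proposed are fixed immediately (an
  abstaining labeler's O is not a conflict). Maximal runs of conflicting
  tokens, extended to the boundaries of every overlapping proposed span,
  form ambiguous segments; each segment is a ranking query whose candidates
  are the labelers' tag assignments. Training ranks candidates by three
  rules — exact span/class agreement with gold first, partial overlap
  second, no overlap last, with earlier-starting matches preferred inside
  the first two ranks — and fits a pairwise linear large-margin ranker by
  the classic reduction to a binary SVM on feature-difference vectors. At
  inference the top-scoring candidate's tags are emitted. Candidate
  features cross the candidate's summary class with segment/context words
  and with each labeler's vote, which is what lets the ranker learn, for
  instance, that "phenotypes" in the right context favours PH over DS where
  the priority list must always answer DS.

When a learned resolver is trained inside cross-validation, the tagger
stream over the training partition is *cross-fitted* (3 internal folds by
default): each slice is tagged by a model trained on the other slices.
Training the resolver on resubstituted tagger output would present it with
unrealistically accurate label features and leak gold information.

## Evaluation machinery

`match_mentions()` scores per class with greedy left-to-right one-to-one
matching: a prediction is correct if it pairs with an unmatched gold
mention of the same class whose span overlaps it (partial mode) or equals
it (exact mode). One-to-one pairing stops a single long prediction from
matching several gold mentions; the greedy pairing is compared against a
brute-force optimal matcher in the tests and never overcounts. Precision,
recall and F1 follow the usual definitions with zero denominators mapped
to 0; micro-averages pool TP/FP/FN across classes before the ratios.
Partial-match scores are an upper bound on exact-match scores by
construction, and both are reported.

`cross_validate()` partitions at the document level (a whole abstract is
either training or test, preventing within-abstract leakage), trains per
fold, and pools counts over all folds before computing PRF.
`unique_mention_eval()` restricts scoring to test mentions whose
normalized surface/class pair never occurs in the fold's training gold;
predictions not overlapping any unique mention are excluded rather than
counted as false positives, a declared choice since the restriction rule
for predictions is not forced by the task definition.

`approx_randomization()` compares two systems by the difference in
micro-F. Under the null that systems are exchangeable, each sentence's two
outputs can be swapped; every repetition swaps each sentence independently
with probability 1/2 and recomputes the pseudo-difference, and the p-value
is the fraction of repetitions reaching the observed difference (R = 1000
by default, seeded; all 2^n assignments are enumerated on request for
small n). We read the procedure as a *paired* shuffle — the two outputs for
a sentence travel together — which keeps the per-sentence pairing intact;
p-values under simulated exchangeable nulls are approximately uniform. The
conventional significance threshold in this literature is p ≤ 0.05; the
package reports p and leaves the threshold to the caller.

## The synthetic-data generator

Real phenotype corpora require licensed ontologies and curated abstracts,
so the test bed is synthetic (`gen_corpus()`): template token streams, not
natural language, with per-class term vocabularies over disjoint token
pools, mention lengths `1 + Poisson(mean − 1)` with a phenotype mean of 3
tokens and shorter means for the other classes (matching the structure of
real corpus statistics, where phenotypes average about three tokens and
classes like chemicals run much shorter), optional embedding of single-token
gene mentions inside phenotype mentions, and lexicons holding a configurable
fraction of the vocabulary. An optional shared PH/DS vocabulary with a cue
token after each such mention creates class-context-dependent ambiguity: both
dictionaries fire, and only context identifies the gold class.
`gen_labeler_outputs()` derives noisy hypothesis streams from gold (recall
loss, class confusion, boundary jitter) at controlled rates. Everything is
reproducible from a mandatory seed.

What the generator does *not* emulate: natural word order and syntax,
surface variation between lexicon entry and mention (the real reason
dictionary recall is hard), discontinuous mentions, and realistic
class-imbalance profiles. Passing tests therefore demonstrate correctness
of the algorithms and the claimed orderings under controlled conditions,
not performance on real biomedical text.

`resolver_benchmark()` packages the resolver comparison: on corpora with
50% shared-vocabulary ambiguity it evaluates the priority list and the
learn-to-rank resolver on clean dictionary streams, and the
maximum-entropy resolver in a degraded configuration whose streams carry
heavy noise (45% recall loss, 40% PH/DS confusion, 25% boundary jitter).
The qualitative outcome — learn-to-rank at or above the priority list,
both above the heavy-noise maximum-entropy configuration — mirrors the
ordering reported for the three strategies on real data, without asserting
any real-corpus numbers.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `beam_k` | 3 | beam width; 1 = greedy, saturated = exact search |
| `window` | 2 | context half-width for all feature templates |
| `lambda` | 0.01 | L2 strength of the maximum-entropy fits |
| `ltr_cost` | 1 | SVM cost C of the pairwise ranker |
| `crossfit_folds` | 3 | internal folds for cross-fitted tagger streams |
| `k` (CV) | 10 | cross-validation folds, documents as fold unit |
| `reps` | 1000 | randomization repetitions R |
| `priority` | DS>PH>GG>AN>CD>OR | conflict order, O implicitly last |

The regularization strength and the ranker cost are fixed defaults exposed
in the configuration; the toolkit defaults used in the original experiments
are not recoverable, so these are declared choices, not inferred ones.

## Numerical and degenerate-input choices

* Character offsets are 0-based half-open throughout, the BRAT standoff
  convention.
* Ill-formed BIO (a dangling `I-X`) is repaired to `B-X` — the
  recall-preserving CoNLL convention — before any decoding result or
  labeler stream is consumed.
* Nested gold mentions are kept in the mention layer but flattened to the
  outermost span for BIO, which cannot express nesting.
* A single-label training corpus yields a degenerate model that predicts
  that label everywhere; a configured class absent from training triggers a
  warning, not an error.
* The plural normalizer is a string-matching key, not a linguistic claim:
  `ies→y`; `es` stripped after `x/z/ch/sh/ss`; otherwise a final `s` is
  stripped from words longer than three characters not ending in `ss`
  (so "metaphyses" maps to "metaphyse", deliberately).
* Abbreviation expansion (Schwartz–Hearst-style character alignment,
  parenthesis-adjacent definitions) is available but off by default:
  replacing short forms rewrites offsets, and a replacement that would
  split a mention boundary is skipped with a warning rather than guessed.
* Sentence segmentation is a deterministic rule (terminator run followed by
  whitespace); it will split "E. coli" style abbreviations wrongly, which
  we accept in exchange for reproducibility. The tokenizer is pluggable.

## Problem sizes used by the test suite

The suite runs entirely on generated data: decoding oracle equivalence on
500 random models (≤4 tokens, 3 labels, exhaustive enumeration as oracle),
dictionary-oracle equivalence on 1000 random lexicon/sentence pairs,
priority-merge invariants on 1000 random candidate sets, the resolver
ordering over 10 seeds of 30-document corpora, randomization-test
calibration over 200 simulated nulls at R = 200, and an end-to-end
12-document pipeline in which complete lexicon coverage with zero noise
yields exact-match micro-F of 1.0. These sizes were chosen so the whole
suite documents the claimed properties while remaining quick to run on a
laptop.

## Known limitations

Discontinuous mentions are out of scope; cross-sentence mentions are
rejected at document construction. The rule labeler is a reconstruction of
modifier-plus-head composition, not a client for any concept-mapping
service. Grounding of recognized candidates to ontology terms
(post-composition) is downstream work and not part of this package.
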