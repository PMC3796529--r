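# System configuration and pipeline assembly: which labelers run, how their
# hypotheses are resolved, and resource ablation.

#' Configure an NER system
#'
#' A configuration names the resources (lexicons and auxiliary tag streams),
#' the labelers built from them (per-class dictionary streams from the union
#' of enabled lexicons of each class, the modifier-composition rule labeler,
#' and the maximum-entropy tagger), and the resolution strategy.
#'
#' @param lexicons list of `pheno_lexicon` objects (source names must be
#'   unique).
#' @param modifiers character vector of modifier terms for the rule labeler
#'   (empty disables it).
#' @param rule_head_classes classes whose lexicons serve as rule-labeler
#'   heads.
#' @param use_tagger run the maximum-entropy base tagger.
#' @param aux_streams auxiliary stream names the tagger may use (`NULL` =
#'   all present in the documents).
#' @param resolver `"priority"`, `"me"` or `"ltr"`.
#' @param priority priority order (see [default_priority()]).
#' @param beam_k beam width for all beam-search decoding (default 3).
#' @param window feature window half-width for tagger and resolvers.
#' @param lambda L2 strength for maximum-entropy fits.
#' @param maxit optimizer iteration cap.
#' @param ltr_cost SVM cost for the learn-to-rank resolver.
#' @param crossfit_folds internal folds used to cross-fit the tagger stream
#'   when training a learned resolver (predictions on held-out slices of the
#'   training partition, so the resolver never sees resubstituted tagger
#'   output).
#' @return A `pheno_config`.
#' @export
ner_config <- function(lexicons = list(), modifiers = character(),
                       rule_head_classes = c("AN", "GG", "DS"),
                       use_tagger = TRUE, aux_streams = NULL,
                       resolver = c("priority", "me", "ltr"),
                       priority = default_priority(), beam_k = 3L,
                       window = 2L, lambda = 0.01, maxit = 500,
                       ltr_cost = 1, crossfit_folds = 3L) {
  resolver <- match.arg(resolver)
  srcs <- vapply(lexicons, `[[`, character(1), "source")
  if (anyDuplicated(srcs)) {
    stop("lexicon source names must be unique", call. = FALSE)
  }
  names(lexicons) <- srcs
  enabled <- stats::setNames(rep(TRUE, length(srcs)), srcs)
  structure(list(lexicons = lexicons, enabled = enabled,
                 modifiers = modifiers,
                 rule_head_classes = rule_head_classes,
                 use_tagger = use_tagger, aux_streams = aux_streams,
                 resolver = resolver, priority = priority,
                 beam_k = as.integer(beam_k), window = as.integer(window),
                 lambda = lambda, maxit = maxit, ltr_cost = ltr_cost,
                 crossfit_folds = as.integer(crossfit_folds)),
            class = "pheno_config")
}

#' Knock out a resource from a configuration
#'
#' Disables one registered resource -- a lexicon (by source name), the rule
#' labeler (`"rule"`), the base tagger (`"me_bs"`), or an auxiliary stream
#' name -- leaving everything else unchanged. Used for ablation studies that
#' measure each resource's contribution per entity class.
#'
#' @param config a `pheno_config`.
#' @param resource_name a registered resource name.
#' @return The modified configuration.
#' @export
ablate <- function(config, resource_name) {
  registered <- c(names(config$enabled), "rule", "me_bs",
                  config$aux_streams)
  if (!resource_name %in% registered) {
    stop("unknown resource '", resource_name, "'; registered: ",
         paste(registered, collapse = ", "), call. = FALSE)
  }
  if (resource_name %in% names(config$enabled)) {
    config$enabled[[resource_name]] <- FALSE
  } else if (resource_name == "rule") {
    config$modifiers <- character()
  } else if (resource_name == "me_bs") {
    config$use_tagger <- FALSE
  } else {
    config$aux_streams <- setdiff(config$aux_streams, resource_name)
  }
  config
}

# enabled lexicons, merged per entity class into one dictionary each
class_dictionaries <- function(config) {
  lex <- config$lexicons[names(config$enabled)[config$enabled]]
  if (!length(lex)) return(list())
  cls <- vapply(lex, `[[`, character(1), "entity_class")
  out <- list()
  for (cl in sort_c(unique(cls))) {
    entries <- unlist(lapply(lex[cls == cl], `[[`, "entries"),
                      use.names = FALSE)
    out[[cl]] <- structure(list(entity_class = cl,
                                entries = unique(entries),
                                source = paste0("dict_", cl),
                                max_len = max(lengths(
                                  strsplit(unique(entries), " ", fixed = TRUE)))),
                           class = "pheno_lexicon")
  }
  out
}

#' Compute the labeler hypothesis streams for one document
#'
#' Runs every enabled labeler: one dictionary stream per entity class
#' (`dict_<class>`), the rule labeler (`rule`), and -- when a trained tagger
#' is supplied -- the beam-decoded tagger stream (`me_bs`).
#'
#' @param doc a `pheno_document`.
#' @param config a `pheno_config`.
#' @param tagger optional trained `pheno_tagger`.
#' @return A candidate set: list with one named list of tag vectors per
#'   sentence.
#' @export
make_candidate_sets <- function(doc, config, tagger = NULL) {
  dicts <- class_dictionaries(config)
  heads <- Filter(function(l) l$entity_class %in% config$rule_head_classes,
                  dicts)
  me <- if (!is.null(tagger) && config$use_tagger) {
    tag_document_bio(tagger, doc, config$beam_k)
  }
  lapply(seq_len(nrow(doc$sentences)), function(s) {
    words <- sentence_tokens(doc, s)$text
    hyps <- list()
    if (!is.null(me)) hyps$me_bs <- me[[s]]
    if (length(config$modifiers) && length(heads)) {
      hyps$rule <- as.character(rule_label(words, config$modifiers, heads))
    }
    for (cl in names(dicts)) {
      hyps[[paste0("dict_", cl)]] <- as.character(dict_label(words, dicts[[cl]]))
    }
    hyps
  })
}

#' Train a full NER system
#'
#' Trains the base tagger (when enabled) on the training documents and, for
#' the learned resolution strategies, trains the resolver on labeler streams
#' in which the tagger's output is cross-fitted: the training partition is
#' split into `crossfit_folds` slices and each slice is tagged by a tagger
#' trained on the remaining slices, so the resolver sees realistically noisy
#' tagger labels. Dictionary and rule streams are deterministic and used
#' directly.
#'
#' @param docs list of training `pheno_document`s.
#' @param config a `pheno_config`.
#' @return A `pheno_system` (configuration plus trained models).
#' @export
train_system <- function(docs, config) {
  tagger <- if (config$use_tagger) {
    train_tagger(docs, window = config$window, lambda = config$lambda,
                 maxit = config$maxit, aux_streams = config$aux_streams)
  }
  resolver_model <- NULL
  if (config$resolver %in% c("me", "ltr")) {
    candsets <- crossfit_candidate_sets(docs, config)
    resolver_model <- if (config$resolver == "me") {
      train_me_resolver(docs, candsets, window = config$window,
                        lambda = config$lambda, maxit = config$maxit)
    } else {
      train_ltr(docs, candsets, priority = config$priority,
                window = config$window, cost = config$ltr_cost)
    }
  }
  structure(list(config = config, tagger = tagger,
                 resolver_model = resolver_model),
            class = "pheno_system")
}

# candidate sets over training docs with the me_bs stream cross-fitted
crossfit_candidate_sets <- function(docs, config) {
  n <- length(docs)
  if (!config$use_tagger || n < 2L) {
    return(lapply(docs, make_candidate_sets, config = config,
                  tagger = if (config$use_tagger && n >= 1L)
                    train_tagger(docs, window = config$window,
                                 lambda = config$lambda, maxit = config$maxit,
                                 aux_streams = config$aux_streams)))
  }
  kf <- min(config$crossfit_folds, n)
  fold <- ((seq_len(n) - 1L) %% kf) + 1L
  out <- vector("list", n)
  for (f in seq_len(kf)) {
    tr <- docs[fold != f]
    tg <- train_tagger(tr, window = config$window, lambda = config$lambda,
                       maxit = config$maxit, aux_streams = config$aux_streams)
    for (i in which(fold == f)) {
      out[[i]] <- make_candidate_sets(docs[[i]], config, tg)
    }
  }
  out
}

#' Tag a document with a trained system
#'
#' Computes all labeler streams and resolves them with the configured
#' strategy.
#'
#' @param system a `pheno_system`.
#' @param doc a `pheno_document`.
#' @return A list with `tags` (per-sentence final BIO) and `mentions`
#'   (decoded mention table with document offsets).
#' @export
tag_document <- function(system, doc) {
  cs <- make_candidate_sets(doc, system$config, system$tagger)
  tags <- switch(system$config$resolver,
    priority = lapply(cs, function(h) {
      if (length(h)) {
        as.character(resolve_priority(h, system$config$priority))
      } else {
        character()
      }
    }),
    me = resolve_me(system$resolver_model, doc, cs, system$config$beam_k),
    ltr = resolve_ltr(system$resolver_model, doc, cs))
  # sentences with no labelers at all resolve to all-O
  tags <- lapply(seq_along(tags), function(s) {
    n <- sum(doc$tokens$sentence == s)
    if (length(tags[[s]]) != n) rep("O", n) else tags[[s]]
  })
  list(tags = tags, mentions = document_bio_to_mentions(doc, tags))
}
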