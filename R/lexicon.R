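#' Deterministic plural normalization
#'
#' A small rule-based singularizer applied to every token before dictionary
#' lookup, on both the lexicon and the text side. Rules, in order: final
#' `ies` becomes `y`; final `es` is stripped after `x`, `z`, `ch`, `sh` or
#' `ss`; otherwise a final `s` is stripped when the word is longer than three
#' characters and does not end in `ss`. The output is a string-matching key,
#' not a linguistic claim (`metaphyses` maps to `metaphyse`).
#'
#' @param x character vector of single tokens.
#' @return Character vector of normalized tokens.
#' @export
#' @examples
#' normalize_plural(c("kidneys", "boxes", "bodies", "asthma"))
normalize_plural <- function(x) {
  out <- x
  n <- nchar(out)
  ies <- n > 3L & endsWith(out, "ies")
  out[ies] <- paste0(substr(out[ies], 1L, n[ies] - 3L), "y")
  rest <- !ies
  es <- rest & grepl("(x|z|ch|sh|ss)es$", out)
  out[es] <- substr(out[es], 1L, nchar(out[es]) - 2L)
  rest <- rest & !es
  s <- rest & n > 3L & endsWith(out, "s") & !endsWith(out, "ss")
  out[s] <- substr(out[s], 1L, nchar(out[s]) - 1L)
  out
}

# normalization shared by lexicon entries and text: lower-case, tokenize on
# whitespace, plural-normalize each word, join with single spaces
normalize_term <- function(terms) {
  vapply(strsplit(tolower(trimws(terms)), "[[:space:]]+"), function(w) {
    paste(normalize_plural(w), collapse = " ")
  }, character(1))
}

#' Build a lexicon from a set of terms
#'
#' @param terms character vector of terms (and synonyms, already flattened).
#' @param entity_class the entity class the lexicon labels.
#' @param source a name for the resource (e.g. `"HPO"`, `"Jochem"`).
#' @return A `pheno_lexicon`: entity class, normalized entry set, source name.
#' @export
make_lexicon <- function(terms, entity_class, source = entity_class) {
  terms <- terms[!is.na(terms) & nzchar(trimws(terms))]
  if (!length(terms)) {
    stop("lexicon '", source, "' has no terms; a dictionary labeler without ",
         "entries is a configuration mistake", call. = FALSE)
  }
  entries <- unique(normalize_term(terms))
  structure(list(entity_class = entity_class, entries = entries,
                 source = source,
                 max_len = max(lengths(strsplit(entries, " ", fixed = TRUE)))),
            class = "pheno_lexicon")
}

#' @export
print.pheno_lexicon <- function(x, ...) {
  cat(sprintf("<pheno_lexicon '%s' (%s): %d entries>\n", x$source,
              x$entity_class, length(x$entries)))
  invisible(x)
}

#' Load a lexicon from a term list file
#'
#' Accepts plain text (one term per line), TSV (term followed by synonym
#' columns) and OBO stanzas (every `name:` and `synonym:` line inside
#' `[Term]` stanzas; synonym values are the quoted strings). Terms and
#' synonyms are flattened into one entry set, case-folded, plural-normalized
#' and de-duplicated.
#'
#' @param path file path, or a character vector of lines via `lines`.
#' @param entity_class entity class of the lexicon.
#' @param format `"auto"` (by extension/content), `"plain"`, `"tsv"` or
#'   `"obo"`.
#' @param source resource name; defaults to the file base name.
#' @param lines character vector of lines, as an alternative to `path`.
#' @return A `pheno_lexicon`.
#' @export
load_lexicon <- function(path = NULL, entity_class,
                         format = c("auto", "plain", "tsv", "obo"),
                         source = NULL, lines = NULL) {
  format <- match.arg(format)
  if (is.null(lines)) {
    if (is.null(source)) source <- sub("\\.[^.]*$", "", basename(path))
    lines <- readLines(path, warn = FALSE)
  }
  if (is.null(source)) source <- entity_class
  if (format == "auto") {
    format <- if (any(grepl("^\\[Term\\]", lines))) {
      "obo"
    } else if (any(grepl("\t", lines, fixed = TRUE))) {
      "tsv"
    } else {
      "plain"
    }
  }
  terms <- switch(format,
    plain = lines,
    tsv = unlist(strsplit(lines, "\t", fixed = TRUE)),
    obo = {
      in_term <- FALSE
      out <- character()
      for (line in lines) {
        line <- trimws(line)
        if (startsWith(line, "[")) { in_term <- identical(line, "[Term]"); next }
        if (!in_term) next
        if (startsWith(line, "name:")) {
          out <- c(out, trimws(sub("^name:", "", line)))
        } else if (startsWith(line, "synonym:")) {
          q <- regmatches(line, regexpr('"[^"]*"', line))
          if (length(q)) out <- c(out, substr(q, 2L, nchar(q) - 1L))
        }
      }
      out
    })
  make_lexicon(terms, entity_class, source)
}

#' Dictionary labeler: longest-string matching against a lexicon
#'
#' Scans the sentence left to right; at each position the longest token
#' n-gram whose normalized join is a lexicon entry is emitted as a
#' `B-X (I-X)*` span and scanning resumes after it (leftmost-longest,
#' non-overlapping -- standard gazetteer semantics). All other tokens are
#' `O`. Matching is case-insensitive on plural-normalized token joins.
#'
#' @param token_text character vector of token surfaces for one sentence.
#' @param lexicon a `pheno_lexicon`.
#' @return Character vector of BIO tags with source attribute set to the
#'   lexicon's source name.
#' @export
#' @examples
#' lex <- make_lexicon("ileal mucosa", "AN", "BTO")
#' dict_label(c("the", "ileal", "mucosa"), lex)
dict_label <- function(token_text, lexicon) {
  n <- length(token_text)
  tags <- rep("O", n)
  if (n && length(lexicon$entries)) {
    norm <- normalize_term(token_text)
    i <- 1L
    while (i <= n) {
      matched <- 0L
      for (len in seq(min(lexicon$max_len, n - i + 1L), 1L)) {
        key <- paste(norm[i:(i + len - 1L)], collapse = " ")
        if (key %in% lexicon$entries) { matched <- len; break }
      }
      if (matched) {
        tags[i] <- paste0("B-", lexicon$entity_class)
        if (matched > 1L) {
          tags[(i + 1L):(i + matched - 1L)] <- paste0("I-", lexicon$entity_class)
        }
        i <- i + matched
      } else {
        i <- i + 1L
      }
    }
  }
  structure(tags, source = lexicon$source)
}

#' Rule labeler: modifier composition over head lexicons
#'
#' Reconstructs staged modifier-plus-head phenotype composition: (1) head
#' terms (anatomy, gene, disease/process vocabularies) are matched with
#' [dict_label()]; (2) each head match is extended over contiguous
#' neighbouring tokens found in the modifier list (quality and abnormality
#' words such as "high", "abnormal", "levels"), on both sides of the head;
#' (3) every span that actually extended is relabeled as a phenotype
#' candidate (PH). By default unextended head matches are not emitted, so the
#' labeler proposes PH spans only; set `emit = "all"` to also pass through
#' bare head matches under their own class.
#'
#' @param token_text character vector of token surfaces for one sentence.
#' @param modifier_list character vector of modifier terms (single tokens).
#' @param head_lexicons list of `pheno_lexicon` objects supplying head terms.
#' @param emit `"ph"` (default) or `"all"`.
#' @param phenotype_class class assigned to composed spans, default `"PH"`.
#' @return Character vector of BIO tags (source `"rule"`).
#' @export
#' @examples
#' heads <- list(make_lexicon("IgE", "GG"))
#' rule_label(c("high", "IgE", "levels"), c("high", "level"), heads)
rule_label <- function(token_text, modifier_list, head_lexicons,
                       emit = c("ph", "all"), phenotype_class = "PH") {
  emit <- match.arg(emit)
  n <- length(token_text)
  tags <- rep("O", n)
  if (n == 0L || !length(head_lexicons)) {
    return(structure(tags, source = "rule"))
  }
  if (!length(modifier_list)) {
    stop("rule labeler requires a non-empty modifier list", call. = FALSE)
  }
  mods <- unique(normalize_term(modifier_list))
  is_mod <- normalize_term(token_text) %in% mods
  spans <- list()
  for (lex in head_lexicons) {
    ht <- dict_label(token_text, lex)
    hm <- bio_to_mentions(ht, data.frame(start = seq_len(n) - 1L,
                                         end = seq_len(n)))
    for (k in seq_len(nrow(hm))) {
      s <- hm$start[k] + 1L; e <- hm$end[k]        # token indices
      s2 <- s; e2 <- e
      while (s2 > 1L && is_mod[s2 - 1L]) s2 <- s2 - 1L
      while (e2 < n && is_mod[e2 + 1L]) e2 <- e2 + 1L
      spans[[length(spans) + 1L]] <- list(
        s = s2, e = e2, extended = (s2 < s || e2 > e),
        class = if (s2 < s || e2 > e) phenotype_class else lex$entity_class)
    }
  }
  if (emit == "ph") spans <- Filter(function(x) x$extended, spans)
  # later (longer, PH) spans overwrite; write unextended first so composed
  # PH spans win overlaps
  spans <- spans[order(vapply(spans, function(x) x$extended, logical(1)))]
  for (sp in spans) {
    tags[sp$s:sp$e] <- c(paste0("B-", sp$class),
                         rep(paste0("I-", sp$class), sp$e - sp$s))
  }
  structure(repair_bio(tags), source = "rule")
}
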