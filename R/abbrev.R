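#' Detect abbreviation definitions
#'
#' Finds `(short form)` definitions whose long form immediately precedes the
#' parenthesis, using character alignment in the Schwartz-Hearst style: the
#' short form's characters must appear in order in the candidate long form,
#' scanning right to left, with the first character anchored at the start of
#' a word. Short forms are 2-10 characters, contain a letter, and span at
#' most two words.
#'
#' @param text document text.
#' @return data.frame with columns `short`, `long`, `sf_start`, `sf_end`,
#'   `lf_start`, `lf_end` (0-based half-open offsets; `sf_*` cover the short
#'   form inside the parentheses).
#' @export
detect_abbreviations <- function(text) {
  out <- data.frame(short = character(), long = character(),
                    sf_start = integer(), sf_end = integer(),
                    lf_start = integer(), lf_end = integer(),
                    stringsAsFactors = FALSE)
  m <- gregexpr("\\(([^()]+)\\)", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(out)
  for (k in seq_along(m)) {
    open0 <- as.integer(m[k]) - 1L                     # 0-based "(" offset
    inner <- substring(text, m[k] + 1L, m[k] + attr(m, "match.length")[k] - 2L)
    sf <- trimws(inner)
    if (nchar(sf) < 2L || nchar(sf) > 10L) next
    if (!grepl("[A-Za-z]", sf)) next
    if (lengths(regmatches(sf, gregexpr("[[:space:]]+", sf))) > 1L) next
    if (!grepl("^[A-Za-z0-9]", sf)) next
    before <- substring(text, 1L, open0)
    lf <- find_long_form(sf, before)
    if (is.null(lf)) next
    sf_start <- open0 + 1L + (nchar(inner) - nchar(sub("^[[:space:]]+", "", inner)))
    out <- rbind(out, data.frame(
      short = sf, long = lf$long, sf_start = sf_start,
      sf_end = sf_start + nchar(sf), lf_start = lf$start,
      lf_end = lf$end, stringsAsFactors = FALSE))
  }
  out
}

# Schwartz-Hearst best-long-form search over the text preceding "(".
# Returns NULL or list(long, start, end) with 0-based half-open offsets.
find_long_form <- function(sf, before) {
  before <- sub("[[:space:]]+$", "", before)
  if (!nzchar(before)) return(NULL)
  # candidate window: last min(|sf|+5, 2*|sf|) words
  max_words <- min(nchar(sf) + 5L, 2L * nchar(sf))
  wm <- gregexpr("[^[:space:]]+", before, perl = TRUE)[[1]]
  if (wm[1] == -1L) return(NULL)
  nw <- length(wm)
  first_w <- max(1L, nw - max_words + 1L)
  cand_start <- as.integer(wm[first_w]) - 1L           # 0-based
  cand <- substring(before, cand_start + 1L, nchar(before))
  s_chars <- strsplit(tolower(sf), "")[[1]]
  l_chars <- strsplit(tolower(cand), "")[[1]]
  si <- length(s_chars); li <- length(l_chars)
  while (si >= 1L) {
    ch <- s_chars[si]
    if (!grepl("[a-z0-9]", ch)) { si <- si - 1L; next }
    while (li >= 1L &&
           (l_chars[li] != ch ||
            (si == 1L && li > 1L && grepl("[a-z0-9]", l_chars[li - 1L])))) {
      li <- li - 1L
    }
    if (li < 1L) return(NULL)
    si <- si - 1L; li <- li - 1L
  }
  start <- cand_start + li
  long <- substring(before, start + 1L, nchar(before))
  if (!nzchar(trimws(long)) || tolower(long) == tolower(sf)) return(NULL)
  list(long = long, start = start, end = nchar(before))
}

#' Expand abbreviations in a document
#'
#' For each detected `(short form)` definition, later standalone occurrences
#' of the short form are replaced by the long form, and gold mention offsets
#' are remapped to the rewritten text. A replacement that would split a
#' mention boundary (the mention overlaps the replaced region without fully
#' containing it) is skipped with a document-level warning. Auxiliary token
#' streams are dropped because the token count changes.
#'
#' @param doc a `pheno_document`.
#' @return A new `pheno_document` over the rewritten text (the same document
#'   when nothing was replaced).
#' @export
expand_abbreviations <- function(doc) {
  pairs <- detect_abbreviations(doc$text)
  if (!nrow(pairs)) return(doc)
  repl <- data.frame(start = integer(), end = integer(), text = character(),
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    pat <- paste0("(?<![A-Za-z0-9])", gsub("([][{}()*+?.\\^$|-])", "\\\\\\1",
                                           pairs$short[i]), "(?![A-Za-z0-9])")
    occ <- gregexpr(pat, doc$text, perl = TRUE)[[1]]
    if (occ[1] == -1L) next
    st <- as.integer(occ) - 1L
    en <- st + attr(occ, "match.length")
    keep <- st >= pairs$sf_end[i] + 1L                 # after ")" of definition
    if (!any(keep)) next
    repl <- rbind(repl, data.frame(start = st[keep], end = en[keep],
                                   text = pairs$long[i],
                                   stringsAsFactors = FALSE))
  }
  if (!nrow(repl)) return(doc)
  repl <- repl[order(repl$start), , drop = FALSE]
  # drop overlapping replacements (first wins), then replacements that would
  # split a mention boundary
  keep <- rep(TRUE, nrow(repl))
  last_end <- -1L
  for (i in seq_len(nrow(repl))) {
    if (repl$start[i] < last_end) { keep[i] <- FALSE; next }
    last_end <- repl$end[i]
  }
  repl <- repl[keep, , drop = FALSE]
  g <- doc$gold
  ok <- vapply(seq_len(nrow(repl)), function(i) {
    ovl <- g$start < repl$end[i] & g$end > repl$start[i]
    covers <- g$start <= repl$start[i] & g$end >= repl$end[i]
    if (any(ovl & !covers)) {
      warning("document '", doc$id, "': replacement of '",
              substring(doc$text, repl$start[i] + 1L, repl$end[i]),
              "' at ", repl$start[i], " would split a mention; skipped",
              call. = FALSE)
      return(FALSE)
    }
    TRUE
  }, logical(1))
  repl <- repl[ok, , drop = FALSE]
  if (!nrow(repl)) return(doc)

  delta <- nchar(repl$text) - (repl$end - repl$start)
  shift <- function(p) {
    p + vapply(p, function(x) sum(delta[repl$end <= x]), numeric(1))
  }
  pieces <- character(0)
  cursor <- 0L
  for (i in seq_len(nrow(repl))) {
    pieces <- c(pieces, substring(doc$text, cursor + 1L, repl$start[i]),
                repl$text[i])
    cursor <- repl$end[i]
  }
  new_text <- paste0(paste(pieces, collapse = ""),
                     substring(doc$text, cursor + 1L, nchar(doc$text)))
  new_gold <- if (nrow(g)) {
    mentions(g$class, shift(g$start), shift(g$end), text = new_text)
  } else {
    g
  }
  if (length(doc$aux)) {
    warning("document '", doc$id, "': auxiliary streams dropped during ",
            "abbreviation expansion", call. = FALSE)
  }
  ner_document(doc$id, new_text, gold = new_gold)
}
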