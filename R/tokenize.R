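#' Sentence segmentation and tokenization
#'
#' A deterministic rule-based segmenter/tokenizer. Sentences end at a run of
#' `.`, `!` or `?` followed by whitespace (the punctuation stays with the
#' sentence to its left); the final sentence ends at the end of text. Tokens
#' are maximal alphanumeric runs -- hyphens, apostrophes and underscores are
#' kept inside words so biomedical tokens like `Toll-like` or `Crohn's`
#' survive intact -- and every other non-space character is a single-character
#' token, so punctuation is split from words. All offsets are 0-based
#' half-open character offsets into the original text, so slicing the text
#' with them reconstructs every token exactly.
#'
#' @param text a single string.
#' @return A list with `sentences` (data.frame `start`, `end`) and `tokens`
#'   (data.frame `sentence`, `start`, `end`, `text`); `sentence` is the
#'   1-based index of the containing sentence.
#' @export
#' @examples
#' segment_and_tokenize("IgE levels rose.")
segment_and_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- list(
    sentences = data.frame(start = integer(), end = integer()),
    tokens = data.frame(sentence = integer(), start = integer(),
                        end = integer(), text = character(),
                        stringsAsFactors = FALSE))
  if (is.na(text) || !nzchar(trimws(text))) return(empty)

  # sentence boundaries: end offset of each terminator run followed by space
  m <- gregexpr("[.!?]+(?=[[:space:]])", text, perl = TRUE)[[1]]
  cuts <- if (m[1] == -1L) integer() else as.integer(m) + attr(m, "match.length") - 1L
  bounds <- c(0L, cuts, nchar(text))
  sent <- data.frame(start = integer(), end = integer())
  for (i in seq_len(length(bounds) - 1L)) {
    s <- bounds[i]; e <- bounds[i + 1L]
    seg <- substring(text, s + 1L, e)
    lead <- nchar(seg) - nchar(sub("^[[:space:]]+", "", seg))
    trail <- nchar(seg) - nchar(sub("[[:space:]]+$", "", seg))
    s <- s + lead; e <- e - trail
    if (e > s) sent <- rbind(sent, data.frame(start = s, end = e))
  }
  if (!nrow(sent)) return(empty)

  tok_re <- "[A-Za-z0-9]+(?:['_-][A-Za-z0-9]+)*|[^A-Za-z0-9[:space:]]"
  toks <- lapply(seq_len(nrow(sent)), function(i) {
    seg <- substring(text, sent$start[i] + 1L, sent$end[i])
    mm <- gregexpr(tok_re, seg, perl = TRUE)[[1]]
    if (mm[1] == -1L) {
      return(data.frame(sentence = integer(), start = integer(),
                        end = integer(), text = character(),
                        stringsAsFactors = FALSE))
    }
    st <- sent$start[i] + as.integer(mm) - 1L
    en <- st + attr(mm, "match.length")
    data.frame(sentence = i, start = st, end = en,
               text = substring(text, st + 1L, en), stringsAsFactors = FALSE)
  })
  list(sentences = sent, tokens = do.call(rbind, toks))
}
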