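#' Read a BRAT standoff document
#'
#' Parses the entity layer (`T` lines) of a BRAT `.ann` file against its
#' `.txt` content. Entity lines have the form
#' `Tid<TAB>Class start end<TAB>surface`. Non-entity annotation lines
#' (relations `R`, events `E`, attributes `A`/`M`, notes `#`) are ignored.
#' Each record's surface text must equal the text slice at
#' `[start, end)`; mismatches raise a validation error naming the offending
#' annotation ids. Entity classes outside `classes` are kept but reported via
#' a warning rather than silently dropped. Discontinuous spans (offsets
#' containing `;`) are unsupported and reported.
#'
#' @param text_content document text (single string).
#' @param ann_content annotation content: a single string or character vector
#'   of lines.
#' @param id document id.
#' @param classes expected entity-class inventory (for reporting only).
#' @param ... passed to [ner_document()] (e.g. `tokenizer`).
#' @return A `pheno_document`.
#' @export
read_brat <- function(text_content, ann_content, id = "doc",
                      classes = entity_classes(), ...) {
  lines <- if (length(ann_content) == 1L) {
    strsplit(ann_content, "\n", fixed = TRUE)[[1]]
  } else {
    ann_content
  }
  lines <- lines[nzchar(trimws(lines))]
  recs <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!startsWith(line, "T")) next
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop("malformed BRAT entity line ", ln, ": ", line, call. = FALSE)
    }
    mid <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
    if (grepl(";", parts[2], fixed = TRUE)) {
      warning("discontinuous span at line ", ln, " (", parts[1],
              ") is unsupported; skipped", call. = FALSE)
      next
    }
    if (length(mid) != 3L || anyNA(suppressWarnings(as.integer(mid[2:3])))) {
      stop("malformed BRAT entity line ", ln, ": ", line, call. = FALSE)
    }
    recs[[length(recs) + 1L]] <- data.frame(
      tid = parts[1], class = mid[1], start = as.integer(mid[2]),
      end = as.integer(mid[3]), surface = parts[3], stringsAsFactors = FALSE)
  }
  if (length(recs)) {
    recs <- do.call(rbind, recs)
    slice <- substring(text_content, recs$start + 1L, recs$end)
    bad <- which(slice != recs$surface)
    if (length(bad)) {
      stop("surface/text mismatch for annotation(s) ",
           paste(recs$tid[bad], collapse = ", "), " in document '", id,
           "': expected '", paste(recs$surface[bad], collapse = "', '"),
           "' got '", paste(slice[bad], collapse = "', '"), "'",
           call. = FALSE)
    }
    unknown <- setdiff(unique(recs$class), classes)
    if (length(unknown)) {
      warning("document '", id, "' contains classes outside the inventory: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    gold <- mentions(recs$class, recs$start, recs$end, recs$surface)
  } else {
    gold <- empty_mentions()
  }
  ner_document(id, text_content, gold = gold, ...)
}

#' Write the entity layer of a document as BRAT standoff annotation
#'
#' The inverse of [read_brat()]: `read_brat(text, write_brat(doc))` reproduces
#' the document's mention set exactly.
#'
#' @param doc a `pheno_document`.
#' @return A single string of `T` lines (empty string when the document has
#'   no mentions).
#' @export
write_brat <- function(doc) {
  m <- doc$gold
  if (!nrow(m)) return("")
  paste(sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(m)), m$class, m$start,
                m$end, m$surface), collapse = "\n")
}

#' Read a directory of BRAT `.txt`/`.ann` pairs
#'
#' @param dir directory containing matched `<id>.txt` / `<id>.ann` files.
#' @param ... passed to [read_brat()].
#' @return A list of `pheno_document`s, ordered by file name.
#' @export
read_brat_corpus <- function(dir, ...) {
  txts <- sort_c(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  lapply(txts, function(f) {
    annf <- sub("\\.txt$", ".ann", f)
    ann <- if (file.exists(annf)) readLines(annf, warn = FALSE) else character()
    read_brat(paste(readLines(f, warn = FALSE), collapse = "\n"), ann,
              id = sub("\\.txt$", "", basename(f)), ...)
  })
}

#' Write a corpus as BRAT `.txt`/`.ann` pairs
#'
#' @param docs list of `pheno_document`s.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of `.txt` paths written.
#' @export
write_brat_corpus <- function(docs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(docs, function(d) {
    txt <- file.path(dir, paste0(d$id, ".txt"))
    writeLines(d$text, txt, sep = "")
    writeLines(write_brat(d), file.path(dir, paste0(d$id, ".ann")))
    txt
  }, character(1))
  invisible(paths)
}
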