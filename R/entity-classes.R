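#' Entity-class inventory
#'
#' The six entity classes recognized by default: phenotype candidate (PH),
#' gene/gene product (GG), disease (DS), organism (OR), anatomy (AN) and
#' chemical/drug (CD). The non-entity label `"O"` is reserved and is never an
#' entity class. The inventory is a plain character vector so configurations
#' can extend it.
#'
#' @return Character vector of entity-class codes.
#' @export
#' @examples
#' entity_classes()
entity_classes <- function() {
  c("PH", "GG", "DS", "OR", "AN", "CD")
}

#' Default priority order over entity classes
#'
#' A total order used by the priority-list resolver: classes earlier in the
#' vector outrank later ones, and the non-entity label `O` always ranks last
#' (it is implicit and must not appear in the vector). The default order
#' `DS > PH > GG > AN > CD > OR` extends the documented fragments (DS over PH,
#' PH over GG, entity classes over O, organisms never containing gene names)
#' to a full order; it is a configuration item, not a fixed rule.
#'
#' @param classes character vector of entity classes the order must cover.
#' @return Character vector: a permutation of `classes`.
#' @export
default_priority <- function(classes = entity_classes()) {
  base <- c("DS", "PH", "GG", "AN", "CD", "OR")
  c(base[base %in% classes], sort_c(setdiff(classes, base)))
}

check_priority <- function(priority, classes) {
  if (anyDuplicated(priority)) {
    stop("priority order contains duplicated classes", call. = FALSE)
  }
  if ("O" %in% priority) {
    stop("'O' is implicit (lowest) and must not appear in a priority order",
         call. = FALSE)
  }
  missing <- setdiff(classes, priority)
  if (length(missing)) {
    stop("priority order is missing classes: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(priority)
}

# rank of a class under a priority order; smaller = higher priority; O (or any
# unlisted label) ranks below every listed class
priority_rank <- function(class, priority) {
  r <- match(class, priority)
  r[is.na(r)] <- length(priority) + 1L
  r
}

# locale-independent sort used everywhere determinism matters
sort_c <- function(x) sort(x, method = "radix")
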